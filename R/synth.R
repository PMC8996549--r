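# Synthetic direct-sample and LIS-like populations with known ground truth.
#
# Healthy values are inverse-Box-Cox transforms of correlated Gaussian
# draws: per analyte, latent N(mu_z, sigma_z) parameters are moment-matched
# so the raw-scale healthy component hits a target mean/SD, and lambda is
# solved so it hits a target skewness. Pathological low/high components are
# positive-truncated Gaussians, univariate-independent given the component
# label. This keeps every downstream stage testable: Box-Cox recovers
# lambda, healthy quantiles have a closed form through the latent normal,
# and component labels are recorded per subject.

.bc_inv_vec <- function(z, lambda) {
  if (abs(lambda) < 1e-8) exp(z) else pmax(lambda * z + 1, 1e-12)^(1 / lambda)
}

.latent_grid <- function() {
  g <- .idri_env$latent_grid
  if (is.null(g)) {
    g <- stats::qnorm(stats::ppoints(4001))
    .idri_env$latent_grid <- g
  }
  g
}

# moment-match latent N(mu, sigma) so inv-Box-Cox(lambda) has the target
# raw-scale mean and sd (fixed-point iteration on a normal quantile grid)
latent_params <- function(mean, sd, lambda) {
  if (abs(lambda - 1) < 1e-12) return(list(mu = mean - 1, sigma = sd, lambda = 1))
  g <- .latent_grid()
  mu <- bc_transform(mean, lambda)
  sigma <- sd * mean^(lambda - 1)
  for (i in 1:200) {
    w <- .bc_inv_vec(mu + sigma * g, lambda)
    m <- mean(w); s <- stats::sd(w)
    if (abs(m - mean) < 1e-9 * mean && abs(s - sd) < 1e-9 * sd) break
    sigma <- sigma * sd / s
    mu <- mu + (mean - m) * mean^(lambda - 1)
  }
  list(mu = mu, sigma = sigma, lambda = lambda)
}

# skewness of the inv-Box-Cox population with moment-matched latent params
.population_skew <- function(mean, sd, lambda) {
  p <- latent_params(mean, sd, lambda)
  sample_skewness(.bc_inv_vec(p$mu + p$sigma * .latent_grid(), lambda))
}

# solve lambda so the healthy component has the target skewness
# (skewness decreases monotonically in lambda; lambda = 1 is symmetric)
lambda_for_skew <- function(mean, sd, skew) {
  if (abs(skew) < 0.02) return(1)
  f <- function(l) .population_skew(mean, sd, l) - skew
  lo <- 0; hi <- 1
  while (f(lo) < 0 && lo > -3) lo <- lo - 0.5
  if (f(lo) < 0) stop("target skewness unreachable for this mean/sd")
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Specify one synthetic stratum
#'
#' Describes an age/sex cell of the simulated population: the healthy
#' component per analyte (raw-scale mean, SD, and skewness, realized through
#' an inverse-Box-Cox latent normal), pathological low/high components
#' (positive-truncated Gaussians), mixing weights, the latent inter-analyte
#' correlation of the healthy triple, and the repeat-visit rate.
#'
#' When \code{low}/\code{high} are NULL they are derived from the healthy
#' component at \code{separation} healthy-SDs from its mean; the low mean is
#' floored at 30\% of the healthy mean (a concentration cannot go negative)
#' and its SD shrunk to keep the component positive.
#'
#' @param label,age_lo,age_hi,sex Stratum definition (see
#'   \code{\link{stratum_scheme}}).
#' @param healthy Named list per analyte: c(mean, sd, skewness).
#' @param weights c(low, healthy, high) mixing proportions, summing to 1.
#' @param corr 3x3 latent correlation of the healthy triple (unit diagonal,
#'   positive definite).
#' @param repeat_visit_rate Probability a LIS subject has a second visit.
#' @param low,high Optional named lists per analyte: c(mean, sd).
#' @param separation Component separation in healthy SDs (default 6).
#' @return Object of class \code{"stratum_spec"}.
#' @export
stratum_spec <- function(label, age_lo, age_hi, sex = "any", healthy,
                         weights = c(low = 0.2, healthy = 0.6, high = 0.2),
                         corr = NULL, repeat_visit_rate = 0.3,
                         low = NULL, high = NULL, separation = 6) {
  analytes <- names(healthy)
  if (is.null(analytes) || !length(analytes)) stop("healthy must be a named list")
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1")
  }
  k <- length(analytes)
  if (is.null(corr)) {
    corr <- matrix(0.5, k, k); diag(corr) <- 1
  }
  if (!isSymmetric(corr) || any(diag(corr) != 1) ||
      any(eigen(corr, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("corr must be symmetric positive-definite with unit diagonal")
  }
  comp <- list()
  for (a in analytes) {
    h <- healthy[[a]]
    m <- h[[1]]; s <- h[[2]]
    sk <- if (length(h) >= 3) h[[3]] else 0
    lam <- lambda_for_skew(m, s, sk)
    lp <- latent_params(m, s, lam)
    lo_comp <- if (!is.null(low)) low[[a]] else {
      lm <- max(m - separation * s, 0.3 * m)
      c(mean = lm, sd = min(1.5 * s, lm / 3))
    }
    hi_comp <- if (!is.null(high)) high[[a]] else {
      c(mean = m + separation * s, sd = 1.5 * s)
    }
    if (!(lo_comp[[1]] < m && m < hi_comp[[1]])) {
      stop("component means must be ordered low < healthy < high for ", a)
    }
    comp[[a]] <- list(healthy = c(mean = m, sd = s, skewness = sk),
                      lambda = lam, latent = lp,
                      low = lo_comp, high = hi_comp)
  }
  structure(list(label = label, age_lo = age_lo, age_hi = age_hi, sex = sex,
                 analytes = analytes, components = comp, weights = weights,
                 corr = corr, repeat_visit_rate = repeat_visit_rate),
            class = "stratum_spec")
}

#' @export
print.stratum_spec <- function(x, ...) {
  cat(sprintf("Stratum spec '%s' [%g, %g) years, sex %s\n", x$label,
              x$age_lo, x$age_hi, x$sex))
  for (a in x$analytes) {
    cc <- x$components[[a]]
    cat(sprintf("  %s: healthy %.4g (sd %.3g, skew %.2g, lambda %.3g); low %.4g (sd %.3g); high %.4g (sd %.3g)\n",
                a, cc$healthy[["mean"]], cc$healthy[["sd"]],
                cc$healthy[["skewness"]], cc$lambda,
                cc$low[["mean"]], cc$low[["sd"]],
                cc$high[["mean"]], cc$high[["sd"]]))
  }
  cat("  weights:", paste(sprintf("%s %.2g", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Default simulation specification
#'
#' The shipped stated world: four age/sex cells whose healthy creatinine and
#' urea components reproduce the published transferred direct-sample
#' means/SDs/skewness per stratum — creatinine 28.9 (5.6) skew 0.10 for
#' 1 to <6 years, 40.6 (5.6) skew 0.23 for 6 to <12 years, 60.8 (12.7) skew
#' 0.37 for boys and 52.2 (8.3) skew 0.08 for girls 12 to <17 years; urea
#' 4.33 (0.99) skew 0.43 everywhere. Uric acid is not published and uses
#' invented defaults (means 210/250/320/280 umol/L, SD 60-70, skew 0.3).
#' Pathological components sit 6 healthy-SDs from the healthy mean (low side
#' floored for positivity), mixed 20/60/20; latent correlation 0.5;
#' repeat-visit rate 0.3. All values are on the LIS (Beckman) scale.
#'
#' @return Named list of four \code{\link{stratum_spec}}s.
#' @export
default_simulation_spec <- function() {
  cached <- .idri_env$default_spec
  if (!is.null(cached)) return(cached)
  cells <- list(
    list(label = "1 to <6 years", lo = 1, hi = 6, sex = "any",
         creat = c(28.9, 5.6, 0.10), uric = c(210, 60, 0.3)),
    list(label = "6 to <12 years", lo = 6, hi = 12, sex = "any",
         creat = c(40.6, 5.6, 0.23), uric = c(250, 60, 0.3)),
    list(label = "12 to <17 years boys", lo = 12, hi = 17, sex = "male",
         creat = c(60.8, 12.7, 0.37), uric = c(320, 70, 0.3)),
    list(label = "12 to <17 years girls", lo = 12, hi = 17, sex = "female",
         creat = c(52.2, 8.3, 0.08), uric = c(280, 65, 0.3))
  )
  spec <- lapply(cells, function(cl) {
    stratum_spec(cl$label, cl$lo, cl$hi, cl$sex,
                 healthy = list(creatinine = cl$creat,
                                urea = c(4.33, 0.99, 0.43),
                                uric_acid = cl$uric))
  })
  names(spec) <- vapply(spec, function(s) s$label, "")
  .idri_env$default_spec <- spec
  spec
}

# exact healthy quantile through the latent normal (monotone transform)
healthy_quantile <- function(spec_stratum, analyte, p) {
  cc <- spec_stratum$components[[analyte]]
  .bc_inv_vec(stats::qnorm(p, cc$latent$mu, cc$latent$sigma), cc$lambda)
}

# positive-truncated normal by rejection (negligible rejection rates for the
# shipped components)
rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# draw n correlated healthy triples for one stratum (raw scale)
.draw_healthy <- function(spec, n) {
  k <- length(spec$analytes)
  z <- matrix(stats::rnorm(n * k), n, k) %*% chol(spec$corr)
  vals <- matrix(0, n, k, dimnames = list(NULL, spec$analytes))
  for (j in seq_len(k)) {
    cc <- spec$components[[spec$analytes[j]]]
    vals[, j] <- .bc_inv_vec(cc$latent$mu + cc$latent$sigma * z[, j], cc$lambda)
  }
  vals
}

.subject_frame <- function(ids, dates, ages, sexes, vals, source) {
  analytes <- colnames(vals)
  units <- analyte_units()
  do.call(rbind, lapply(seq_along(analytes), function(j) {
    a <- analytes[j]
    data.frame(subject_id = ids, collection_date = dates, age = ages,
               sex = sexes, analyte = a, value = vals[, j],
               units = unname(units[a]), source = source,
               stringsAsFactors = FALSE)
  }))
}

.truth_quantiles <- function(spec_list, p = c(0.025, 0.975)) {
  do.call(rbind, lapply(spec_list, function(sp) {
    do.call(rbind, lapply(sp$analytes, function(a) {
      q <- healthy_quantile(sp, a, p)
      data.frame(stratum = sp$label, analyte = a, p_lo = p[1], p_hi = p[2],
                 q_lo = q[1], q_hi = q[2], stringsAsFactors = FALSE)
    }))
  }))
}

#' Generate a direct (healthy reference) sample
#'
#' Draws only from each stratum's healthy component: ages uniform within the
#' cell, one visit per subject, correlated analyte triples through the latent
#' Gaussian. By default values are emitted on the source (Roche) platform
#' scale — the spec parameters describe the LIS (Beckman) scale, so the
#' shipped inverse transference maps are applied — which lets the pipeline
#' exercise transference; \code{platform = "beckman"} skips that.
#'
#' @param spec List of \code{\link{stratum_spec}}s, e.g.
#'   \code{\link{default_simulation_spec}}.
#' @param n_per_stratum Integer scalar or vector (recycled over strata),
#'   >= 100 each.
#' @param seed Integer seed; generation is deterministic given it.
#' @param platform "roche" (default; inverse-transferred) or "beckman".
#' @return List: \code{records} (canonical data.frame) and \code{truth}
#'   (subject component labels, exact healthy 2.5/97.5 quantiles per
#'   stratum/analyte on the Beckman scale, and the seed).
#' @export
generate_direct <- function(spec = default_simulation_spec(),
                            n_per_stratum = 1000L, seed = 1L,
                            platform = c("roche", "beckman")) {
  platform <- match.arg(platform)
  n_per_stratum <- rep_len(as.integer(n_per_stratum), length(spec))
  if (any(n_per_stratum < 100L)) stop("need n >= 100 per stratum")
  set.seed(seed)
  recs <- list(); labels <- list()
  counter <- 0L
  for (i in seq_along(spec)) {
    sp <- spec[[i]]; n <- n_per_stratum[i]
    ids <- sprintf("D%06d", counter + seq_len(n)); counter <- counter + n
    ages <- stats::runif(n, sp$age_lo, sp$age_hi)
    sexes <- if (sp$sex == "any") {
      sample(c("male", "female"), n, replace = TRUE)
    } else rep(sp$sex, n)
    dates <- as.Date("2017-01-01") + sample.int(730L, n, replace = TRUE) - 1L
    vals <- .draw_healthy(sp, n)
    recs[[i]] <- .subject_frame(ids, dates, ages, sexes, vals, "direct")
    labels[[i]] <- data.frame(subject_id = ids, stratum = sp$label,
                              component = "healthy", stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (platform == "roche") {
    inv <- lapply(default_transfer_maps(), invert_map)
    records <- suppressMessages(transfer_records(records, inv))
  }
  list(records = records,
       truth = list(labels = do.call(rbind, labels),
                    quantiles = .truth_quantiles(spec), seed = seed))
}

#' Generate an LIS-like mixed outpatient population
#'
#' Mixes each stratum's low/healthy/high components at the spec weights
#' (component label drawn once per subject, pathological analyte values
#' independent given the label), injects repeat visits (a later date with
#' multiplicative within-subject noise; deduplication must recover the
#' earliest record) and small fractions of missing and physically implausible
#' values to exercise the cleaning chain. Values are on the LIS (Beckman)
#' scale.
#'
#' @inheritParams generate_direct
#' @param missing_frac Fraction of records whose value is blanked (NA).
#' @param implausible_frac Fraction of records replaced by out-of-bounds
#'   values.
#' @param visit_noise_sd SD of the multiplicative log-normal within-subject
#'   noise on repeat visits.
#' @return List: \code{records} and \code{truth} (per-subject component
#'   label, healthy quantiles, seed).
#' @export
generate_lis <- function(spec = default_simulation_spec(),
                         n_per_stratum = 5000L, seed = 2L,
                         missing_frac = 0.005, implausible_frac = 0.002,
                         visit_noise_sd = 0.06) {
  n_per_stratum <- rep_len(as.integer(n_per_stratum), length(spec))
  if (any(n_per_stratum < 100L)) stop("need n >= 100 per stratum")
  set.seed(seed)
  recs <- list(); labels <- list()
  counter <- 0L
  for (i in seq_along(spec)) {
    sp <- spec[[i]]; n <- n_per_stratum[i]
    k <- length(sp$analytes)
    ids <- sprintf("L%06d", counter + seq_len(n)); counter <- counter + n
    ages <- stats::runif(n, sp$age_lo, sp$age_hi)
    sexes <- if (sp$sex == "any") {
      sample(c("male", "female"), n, replace = TRUE)
    } else rep(sp$sex, n)
    dates <- as.Date("2017-01-01") + sample.int(365L, n, replace = TRUE) - 1L
    comp <- sample(c("low", "healthy", "high"), n, replace = TRUE,
                   prob = sp$weights)
    vals <- .draw_healthy(sp, n)
    for (j in seq_len(k)) {
      a <- sp$analytes[j]
      for (cl in c("low", "high")) {
        sel <- comp == cl
        if (any(sel)) {
          cc <- sp$components[[a]][[cl]]
          vals[sel, j] <- rtnorm_pos(sum(sel), cc[["mean"]], cc[["sd"]])
        }
      }
    }
    base <- .subject_frame(ids, dates, ages, sexes, vals, "lis")
    # repeat visits: later date, value re-drawn with within-subject noise
    rep_sel <- stats::runif(n) < sp$repeat_visit_rate
    if (any(rep_sel)) {
      idx <- which(rep_sel)
      gap <- sample(30:250, length(idx), replace = TRUE)
      v2 <- vals[idx, , drop = FALSE] *
        matrix(exp(stats::rnorm(length(idx) * k, 0, visit_noise_sd)),
               length(idx), k)
      recs2 <- .subject_frame(ids[idx], dates[idx] + gap, ages[idx],
                              sexes[idx], v2, "lis")
      base <- rbind(base, recs2)
    }
    recs[[i]] <- base
    labels[[i]] <- data.frame(subject_id = ids, stratum = sp$label,
                              component = comp, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  m <- nrow(records)
  if (missing_frac > 0) {
    records$value[sample.int(m, round(missing_frac * m))] <- NA_real_
  }
  if (implausible_frac > 0) {
    hit <- sample.int(m, round(implausible_frac * m))
    records$value[hit] <- records$value[hit] * 1e4
  }
  list(records = records,
       truth = list(labels = do.call(rbind, labels),
                    quantiles = .truth_quantiles(spec), seed = seed))
}
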