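# Data-cleaning chain: deduplication to the earliest record, age filtering,
# plausibility bounds, per-stratum Box-Cox + Tukey outlier detection, the
# radical multi-analyte exclusion strategy, and a regression-tree
# reproduction of the age/sex partitioning.

#' Keep the earliest record per subject and analyte
#'
#' Repeatedly tested children are assumed to carry higher pathology risk, so
#' only the earliest record per (subject, analyte) is retained. Date ties are
#' broken by the lowest value, then input order. Idempotent.
#'
#' @param records Canonical record data.frame.
#' @return The deduplicated record data.frame.
#' @export
dedupe_earliest <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$subject_id, records$analyte,
               records$collection_date, records$value)
  r <- records[ord, , drop = FALSE]
  keep <- !duplicated(r[, c("subject_id", "analyte")])
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter records to an age window
#'
#' Keeps records with \code{lo <= age < hi} (half-open, decimal years).
#' Defaults to the study window of 1 to <17 years.
#'
#' @param records Canonical record data.frame.
#' @param lo,hi Age bounds in years; \code{lo >= hi} is an error.
#' @return Filtered record data.frame.
#' @export
filter_age <- function(records, lo = 1, hi = 17) {
  if (lo >= hi) stop("age filter requires lo < hi")
  out <- records[records$age >= lo & records$age < hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default physiologic plausibility bounds
#'
#' Values outside these bounds are treated as "extreme" and deleted before
#' any statistical step. The source workflow states the deletion but not the
#' thresholds; these generous defaults only remove physically implausible
#' entries and are fully configurable.
#'
#' @return Named list of c(lower, upper) bounds per analyte, analyte units.
#' @export
default_bounds <- function() {
  list(creatinine = c(1, 2000), urea = c(0.1, 100), uric_acid = c(10, 3000))
}

# ---- Box-Cox ---------------------------------------------------------------

bc_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

bc_inverse <- function(y, lambda) {
  if (abs(lambda) < 1e-8) exp(y) else {
    z <- lambda * y + 1
    ifelse(z > 0, z^(1 / lambda), NaN)
  }
}

#' Fit a Box-Cox transformation by maximum likelihood
#'
#' Estimates the power lambda of y = (x^lambda - 1)/lambda (log at lambda = 0)
#' that maximizes the profile log-likelihood of the Gaussian model on the
#' transformed data, over lambda in [-3, 3].
#'
#' @param x Positive numeric values (after \code{shift}); n >= 10.
#' @param shift Additive pre-shift applied before transforming (default 0).
#' @return Object of class \code{"boxcox"}: \code{lambda}, \code{loglik},
#'   \code{shift}.
#' @examples
#' fit <- boxcox_fit(exp(rnorm(500)))  # lambda near 0
#' @export
boxcox_fit <- function(x, shift = 0) {
  x <- x + shift
  if (any(!is.finite(x))) stop("non-finite values")
  if (any(x <= 0)) {
    stop("non-positive value(s); supply a positive 'shift' to make all values > 0")
  }
  if (length(x) < 10L) stop("Box-Cox fit needs n >= 10")
  n <- length(x)
  slx <- sum(log(x))
  prof <- function(lam) {
    y <- bc_transform(x, lam)
    v <- mean((y - mean(y))^2)
    -n / 2 * log(v) + (lam - 1) * slx
  }
  opt <- stats::optimize(prof, c(-3, 3), maximum = TRUE, tol = 1e-7)
  structure(list(lambda = opt$maximum, loglik = opt$objective, shift = shift),
            class = "boxcox")
}

#' @export
print.boxcox <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.4f (shift %g), profile loglik %.2f\n",
              x$lambda, x$shift, x$loglik))
  invisible(x)
}

#' Apply / invert a fitted Box-Cox transform
#'
#' @param fit A \code{\link{boxcox_fit}} object.
#' @param x Values on the raw scale.
#' @param y Values on the transformed scale.
#' @return Transformed (raw) values. The inverse returns NaN where the
#'   transformed value falls outside the image of the transform.
#' @export
bc_apply <- function(fit, x) bc_transform(x + fit$shift, fit$lambda)

#' @rdname bc_apply
#' @export
bc_invert <- function(fit, y) bc_inverse(y, fit$lambda) - fit$shift

# ---- Tukey fences ----------------------------------------------------------

#' Tukey-fence outlier detection
#'
#' Flags values strictly outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with quartiles
#' computed by linear interpolation (type 7) on the Box-Cox-transformed scale
#' when a fit is supplied, otherwise on the raw scale. Fences are reported on
#' both scales; a back-mapped fence outside the image of the transform is
#' -Inf/Inf.
#'
#' @param x Numeric values, n >= 4.
#' @param boxcox Optional \code{\link{boxcox_fit}} used to transform before
#'   computing fences.
#' @return Object of class \code{"tukey_fences"} with elements \code{mask}
#'   (logical, TRUE = outlier), \code{q1}, \code{q3}, \code{iqr},
#'   \code{lower}, \code{upper} (transformed scale) and \code{lower_raw},
#'   \code{upper_raw}.
#' @export
tukey_outliers <- function(x, boxcox = NULL) {
  if (length(x) < 4L) stop("Tukey fences need n >= 4 (quartiles undefined)")
  y <- if (is.null(boxcox)) x else bc_apply(boxcox, x)
  if (any(!is.finite(y))) stop("values not transformable under supplied Box-Cox fit")
  q <- stats::quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  if (is.null(boxcox)) {
    lower_raw <- lower; upper_raw <- upper
  } else {
    lower_raw <- bc_invert(boxcox, lower)
    upper_raw <- bc_invert(boxcox, upper)
    if (is.nan(lower_raw)) lower_raw <- -Inf
    if (is.nan(upper_raw)) upper_raw <- Inf
  }
  structure(list(mask = y < lower | y > upper,
                 q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = lower, upper = upper,
                 lower_raw = lower_raw, upper_raw = upper_raw,
                 transformed = !is.null(boxcox)),
            class = "tukey_fences")
}

#' @export
print.tukey_fences <- function(x, ...) {
  cat(sprintf("Tukey fences%s: [%.4g, %.4g] raw [%.4g, %.4g]; %d outlier(s)\n",
              if (x$transformed) " (Box-Cox scale)" else "",
              x$lower, x$upper, x$lower_raw, x$upper_raw, sum(x$mask)))
  invisible(x)
}

# ---- per-stratum outlier pass ----------------------------------------------

#' Flag outliers per stratum
#'
#' Within each stratum of \code{scheme}, screens normality by sample skewness
#' (|skewness| > \code{skew_threshold} triggers a Box-Cox transform, recorded
#' in the details) and flags Tukey-fence outliers on the working scale.
#' Strata with fewer than 4 records are left unflagged.
#'
#' @param records Canonical record data.frame (one analyte).
#' @param scheme \code{\link{stratum_scheme}} for that analyte.
#' @param skew_threshold Absolute skewness above which Box-Cox is applied.
#' @return List: \code{flags} (logical per row), \code{details} (data.frame
#'   per stratum: n, skewness, boxcox applied, lambda, raw fences, n_flagged).
#' @export
flag_outliers <- function(records, scheme, skew_threshold = 0.5) {
  labels <- assign_stratum(records$age, records$sex, scheme)
  flags <- rep(FALSE, nrow(records))
  rows <- list()
  for (lab in scheme$label) {
    idx <- which(!is.na(labels) & labels == lab)
    x <- records$value[idx]
    if (length(x) < 4L) {
      rows[[lab]] <- data.frame(label = lab, n = length(x), skewness = NA,
                                boxcox = FALSE, lambda = NA, lower = NA,
                                upper = NA, n_flagged = 0L)
      next
    }
    sk <- sample_skewness(x)
    use_bc <- is.finite(sk) && abs(sk) > skew_threshold && all(x > 0)
    fit <- if (use_bc) boxcox_fit(x) else NULL
    tf <- tukey_outliers(x, fit)
    flags[idx] <- tf$mask
    rows[[lab]] <- data.frame(label = lab, n = length(x), skewness = sk,
                              boxcox = use_bc,
                              lambda = if (use_bc) fit$lambda else NA_real_,
                              lower = tf$lower_raw, upper = tf$upper_raw,
                              n_flagged = sum(tf$mask))
  }
  details <- do.call(rbind, rows)
  rownames(details) <- NULL
  list(flags = flags, details = details)
}

#' Clean laboratory records
#'
#' The full cleaning chain: (1) delete missing and extreme values (outside
#' the plausibility \code{bounds}); (2) deduplicate to the earliest record
#' per subject and analyte; (3) keep ages in \code{age_range}; (4) per
#' analyte and stratum, detect Tukey-fence outliers on a Box-Cox-normalized
#' scale and remove them, either per analyte or radically (a subject flagged
#' in \emph{any} analyte is removed from \emph{all} analytes). No step ever
#' increases the record count.
#'
#' @param records Canonical record data.frame, possibly multiple analytes.
#' @param schemes Named list of \code{\link{stratum_scheme}}s per analyte;
#'   defaults to \code{\link{default_strata}} for each analyte present.
#' @param bounds Plausibility bounds, see \code{\link{default_bounds}}.
#' @param age_range Length-2 numeric, half-open age window in years.
#' @param skew_threshold Passed to \code{\link{flag_outliers}}.
#' @param strategy "per_analyte" (default) or "radical".
#' @return List of class \code{"cleaning_result"}: \code{records} (cleaned)
#'   and \code{report} (stage counts, per-stratum lambda/fences, and for the
#'   radical strategy the counts of flagged and partially observed subjects).
#' @export
clean_records <- function(records, schemes = NULL, bounds = default_bounds(),
                          age_range = c(1, 17), skew_threshold = 0.5,
                          strategy = c("per_analyte", "radical")) {
  strategy <- match.arg(strategy)
  analytes <- unique(records$analyte)
  if (is.null(schemes)) {
    schemes <- lapply(analytes, function(a) {
      if (a %in% c("creatinine", "urea", "uric_acid")) default_strata(a)
      else stratum_scheme(a, age_range[1], age_range[2])
    })
    names(schemes) <- analytes
  }
  counts <- c(input = nrow(records))

  ok <- is.finite(records$value)
  for (a in intersect(names(bounds), analytes)) {
    sel <- records$analyte == a
    ok[sel] <- ok[sel] & records$value[sel] >= bounds[[a]][1] &
      records$value[sel] <= bounds[[a]][2]
  }
  records <- records[ok, , drop = FALSE]
  counts["after_missing_extreme"] <- nrow(records)

  records <- dedupe_earliest(records)
  counts["after_dedup"] <- nrow(records)

  records <- filter_age(records, age_range[1], age_range[2])
  counts["after_age_filter"] <- nrow(records)

  flags <- rep(FALSE, nrow(records))
  details <- list()
  for (a in analytes) {
    sel <- which(records$analyte == a)
    if (!length(sel)) next
    fo <- flag_outliers(records[sel, , drop = FALSE], schemes[[a]], skew_threshold)
    flags[sel] <- fo$flags
    fo$details$analyte <- a
    details[[a]] <- fo$details
  }
  details <- do.call(rbind, details)
  rownames(details) <- NULL

  report <- list(counts = counts, strata = details, strategy = strategy)
  if (strategy == "radical") {
    flagged_subjects <- unique(records$subject_id[flags])
    drop <- records$subject_id %in% flagged_subjects
    have <- table(unique(records[, c("subject_id", "analyte")])$subject_id)
    report$n_flagged_subjects <- length(flagged_subjects)
    report$n_partial_subjects <- sum(have < length(analytes))
    records <- records[!drop, , drop = FALSE]
  } else {
    records <- records[!flags, , drop = FALSE]
  }
  rownames(records) <- NULL
  report$counts["after_outliers"] <- nrow(records)
  structure(list(records = records, report = report), class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat("Cleaning (", x$report$strategy, " outlier strategy)\n", sep = "")
  print(x$report$counts)
  invisible(x)
}

#' Radical multi-analyte exclusion
#'
#' Convenience wrapper: \code{\link{clean_records}} with
#' \code{strategy = "radical"}. A subject flagged as a Tukey outlier in any of
#' creatinine, urea, or uric acid is excluded from all analytes; subjects
#' missing an analyte are judged only on the evidence present.
#'
#' @inheritParams clean_records
#' @return See \code{\link{clean_records}}.
#' @export
radical_exclusion <- function(records, schemes = NULL, bounds = default_bounds(),
                              age_range = c(1, 17), skew_threshold = 0.5) {
  clean_records(records, schemes, bounds, age_range, skew_threshold,
                strategy = "radical")
}

# ---- age/sex partition tree -------------------------------------------------

#' Regression-tree age/sex partitioning
#'
#' Greedy binary splits on age with candidate cuts at integer years, each
#' split maximizing the within-leaf variance (SSE) reduction; after the age
#' tree is grown, a sex split is tested inside each terminal leaf and
#' retained when it reduces the leaf SSE by at least
#' \code{sex_gain_threshold} (relative). This reproduces the exploratory
#' partitioning step; published strata (\code{\link{default_strata}}) remain
#' the pipeline default.
#'
#' @param records Canonical record data.frame, one analyte, n >= 100.
#' @param max_leaves Maximum number of age leaves (>= 2).
#' @param min_leaf_frac Minimum fraction of records per leaf.
#' @param sex_gain_threshold Relative SSE reduction required to keep a sex
#'   split within a leaf.
#' @param cp Complexity threshold: a split must reduce the total SSE by at
#'   least this fraction of the root SSE, so noise-only data stay unsplit.
#' @param age_range Half-open modelling window, years.
#' @return Object of class \code{"age_tree"}: \code{cut_points}, a
#'   \code{leaves} data.frame (lo, hi, n, sex_split), and the greedy
#'   \code{trace} of split gains.
#' @export
age_partition_tree <- function(records, max_leaves = 4, min_leaf_frac = 0.05,
                               sex_gain_threshold = 0.05, cp = 0.01,
                               age_range = c(1, 17)) {
  if (max_leaves < 2) stop("max_leaves must be >= 2")
  v <- records$value; a <- records$age; sx <- records$sex
  n <- length(v)
  if (n < 100L) stop("tree partitioning needs n >= 100")
  sse <- function(idx) {
    if (length(idx) < 2L) return(0)
    x <- v[idx]
    sum((x - mean(x))^2)
  }
  leaves <- list(list(lo = age_range[1], hi = age_range[2], idx = seq_len(n)))
  trace <- list()
  min_n <- ceiling(min_leaf_frac * n)
  min_gain <- cp * sse(seq_len(n))
  while (length(leaves) < max_leaves) {
    best <- NULL
    for (li in seq_along(leaves)) {
      lf <- leaves[[li]]
      from <- ceiling(lf$lo + 1)
      to <- floor(lf$hi - 1)
      if (from > to) next
      cuts <- seq(from, to)
      cuts <- cuts[cuts > lf$lo & cuts < lf$hi]
      if (!length(cuts)) next
      s0 <- sse(lf$idx)
      for (cc in cuts) {
        left <- lf$idx[a[lf$idx] < cc]
        right <- lf$idx[a[lf$idx] >= cc]
        if (length(left) < min_n || length(right) < min_n) next
        gain <- s0 - sse(left) - sse(right)
        if (is.null(best) || gain > best$gain) {
          best <- list(leaf = li, cut = cc, gain = gain, left = left, right = right)
        }
      }
    }
    if (is.null(best) || best$gain < min_gain) break
    lf <- leaves[[best$leaf]]
    leaves[[best$leaf]] <- list(lo = lf$lo, hi = best$cut, idx = best$left)
    leaves[[length(leaves) + 1L]] <- list(lo = best$cut, hi = lf$hi, idx = best$right)
    trace[[length(trace) + 1L]] <- data.frame(cut = best$cut, gain = best$gain)
  }
  ord <- order(vapply(leaves, function(l) l$lo, 0))
  leaves <- leaves[ord]
  leaf_df <- do.call(rbind, lapply(leaves, function(lf) {
    sm <- lf$idx[sx[lf$idx] == "male"]
    sf <- lf$idx[sx[lf$idx] == "female"]
    s0 <- sse(lf$idx)
    rel_gain <- if (s0 > 0 && length(sm) >= 2 && length(sf) >= 2) {
      (s0 - sse(sm) - sse(sf)) / s0
    } else 0
    data.frame(lo = lf$lo, hi = lf$hi, n = length(lf$idx),
               sex_gain = rel_gain,
               sex_split = rel_gain >= sex_gain_threshold)
  }))
  structure(list(cut_points = sort(vapply(trace, function(t) t$cut, 0)),
                 leaves = leaf_df,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(cut = numeric(0), gain = numeric(0))),
            class = "age_tree")
}

#' @export
print.age_tree <- function(x, ...) {
  cat("Age partition tree: cuts at {", paste(x$cut_points, collapse = ", "),
      "}\n", sep = "")
  print(x$leaves, row.names = FALSE)
  invisible(x)
}
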