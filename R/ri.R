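# Nonparametric reference intervals with rank-based 90% confidence
# intervals, distribution summaries, and the bias-ratio comparison of
# indirect against direct limits.

# percentile by the CLSI-style rank formula r = p*(n+1), linear interpolation
np_limit <- function(sorted_x, p) {
  n <- length(sorted_x)
  r <- p * (n + 1)
  if (r <= 1) return(sorted_x[1])
  if (r >= n) return(sorted_x[n])
  f <- floor(r)
  sorted_x[f] + (r - f) * (sorted_x[f + 1] - sorted_x[f])
}

# distribution-free CI on the p-th percentile from order statistics:
# smallest rank window around r = p*(n+1) with binomial coverage >= conf.
# NULL when even the full range cannot reach the coverage.
np_rank_ci <- function(sorted_x, p, conf) {
  n <- length(sorted_x)
  r <- p * (n + 1)
  for (d in 0:n) {
    l <- max(1L, floor(r) - d)
    u <- min(n, ceiling(r) + d)
    cov <- stats::pbinom(u - 1L, n, p) - stats::pbinom(l - 1L, n, p)
    if (cov >= conf) return(c(sorted_x[l], sorted_x[u]))
    if (l == 1L && u == n) return(NULL)
  }
  NULL
}

#' Nonparametric reference interval with confidence intervals
#'
#' Reference limits are the 2.5th and 97.5th sample percentiles by the rank
#' formula r = p(n+1) with linear interpolation between order statistics.
#' Each limit carries a 90\% confidence interval from the distribution-free
#' rank (binomial) method; when the required ranks fall outside the sample,
#' the CI falls back to a seeded bootstrap percentile interval.
#'
#' @param values Numeric vector; n < 20 is an error, n < 120 warns (the
#'   nonparametric CI is unreliable below about 120 observations).
#' @param p_lo,p_hi Percentiles defining the interval (defaults 0.025/0.975).
#' @param conf Confidence level for the limit CIs (default 0.90).
#' @param n_boot Bootstrap resamples for the fallback CI.
#' @param boot_seed Seed for the bootstrap fallback only.
#' @return Object of class \code{"reference_interval"}: \code{n}, \code{ll},
#'   \code{ul}, \code{ll_ci}, \code{ul_ci}, \code{conf}, \code{p},
#'   \code{ci_method}.
#' @examples
#' ri <- reference_interval(rnorm(500, 50, 5))
#' @export
reference_interval <- function(values, p_lo = 0.025, p_hi = 0.975,
                               conf = 0.90, n_boot = 2000L, boot_seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20L) stop("reference interval needs n >= 20")
  if (n < 120L) warning("n < 120: nonparametric CI validity is marginal")
  xs <- sort(values)
  ll <- np_limit(xs, p_lo)
  ul <- np_limit(xs, p_hi)
  ll_ci <- np_rank_ci(xs, p_lo, conf)
  ul_ci <- np_rank_ci(xs, p_hi, conf)
  ci_method <- "rank"
  if (is.null(ll_ci) || is.null(ul_ci)) {
    ci_method <- "bootstrap"
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(boot_seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      bs <- sort(sample(values, n, replace = TRUE))
      c(np_limit(bs, p_lo), np_limit(bs, p_hi))
    }, numeric(2L))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    qs <- c((1 - conf) / 2, (1 + conf) / 2)
    if (is.null(ll_ci)) ll_ci <- stats::quantile(boot[1, ], qs, names = FALSE)
    if (is.null(ul_ci)) ul_ci <- stats::quantile(boot[2, ], qs, names = FALSE)
  }
  structure(list(n = n, ll = ll, ul = ul, ll_ci = ll_ci, ul_ci = ul_ci,
                 p = c(p_lo, p_hi), conf = conf, ci_method = ci_method,
                 method = "nonparametric"),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Nonparametric RI (n = %d): %s (%s, %s) to %s (%s, %s)  [%d%% CI, %s]\n",
    x$n, format(x$ll, digits = digits),
    format(x$ll_ci[1], digits = digits), format(x$ll_ci[2], digits = digits),
    format(x$ul, digits = digits),
    format(x$ul_ci[1], digits = digits), format(x$ul_ci[2], digits = digits),
    round(100 * x$conf), x$ci_method))
  invisible(x)
}

#' Distribution summary
#'
#' n, median, mean, SD (n-1 denominator), bias-corrected sample skewness and
#' bias-corrected excess kurtosis — the summary layout used to characterize
#' reference distributions.
#'
#' @param values Numeric vector, n >= 4.
#' @return One-row data.frame of class \code{"dist_summary"}.
#' @export
summarize_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("summary needs n >= 4")
  out <- data.frame(n = length(values),
                    median = stats::median(values),
                    mean = mean(values),
                    sd = stats::sd(values),
                    skewness = sample_skewness(values),
                    kurtosis = sample_kurtosis(values))
  class(out) <- c("dist_summary", "data.frame")
  out
}

#' Bias ratio of indirect vs direct reference limits
#'
#' The between-individual SD is taken as 1/3.92 of the direct RI width;
#' each limit's bias ratio is (indirect - direct) / sd_b, classified as
#' allowable (|ratio| <= 0.25), minimal (<= 0.375), or unacceptable.
#'
#' @param direct,indirect \code{\link{reference_interval}} objects, or any
#'   list with numeric \code{ll} and \code{ul}.
#' @return Object of class \code{"bias_assessment"}: \code{sd_b},
#'   \code{ratio_ll}, \code{ratio_ul}, \code{class_ll}, \code{class_ul}.
#' @examples
#' bias_ratio(list(ll = 2.62, ul = 6.50), list(ll = 2.53, ul = 6.06))
#' @export
bias_ratio <- function(direct, indirect) {
  width <- direct$ul - direct$ll
  if (!is.finite(width) || width <= 0) stop("direct RI width must be positive")
  sd_b <- width / 3.92
  r_ll <- (indirect$ll - direct$ll) / sd_b
  r_ul <- (indirect$ul - direct$ul) / sd_b
  classify <- function(r) {
    if (abs(r) <= 0.25) "allowable" else if (abs(r) <= 0.375) "minimal"
    else "unacceptable"
  }
  structure(list(sd_b = sd_b, ratio_ll = r_ll, ratio_ul = r_ul,
                 class_ll = classify(r_ll), class_ul = classify(r_ul)),
            class = "bias_assessment")
}

#' @export
print.bias_assessment <- function(x, ...) {
  cat(sprintf("Bias ratio (sd_b = %.4g): LL %.2f (%s), UL %.2f (%s)\n",
              x$sd_b, x$ratio_ll, x$class_ll, x$ratio_ul, x$class_ul))
  invisible(x)
}

#' Compare reference populations per stratum
#'
#' For each analyte stratum, computes the distribution summary, the
#' nonparametric RI, the bias assessment of every indirect population against
#' the direct one, and kernel-density curve coordinates for plotting. A
#' population missing in a stratum (or too small) yields an NA row with a
#' warning.
#'
#' @param populations Named list of record data.frames (one analyte); the
#'   first entry is treated as the direct (gold standard) population.
#' @param scheme \code{\link{stratum_scheme}} for the analyte.
#' @param conf Confidence level for limit CIs.
#' @param boot_seed Seed for any bootstrap CI fallback.
#' @return List of class \code{"ri_report"}: \code{summaries},
#'   \code{intervals}, \code{bias}, \code{densities} (all data.frames).
#' @export
compare_populations <- function(populations, scheme, conf = 0.90,
                                boot_seed = 1L) {
  stopifnot(length(populations) >= 2L, !is.null(names(populations)))
  direct_name <- names(populations)[1]
  summaries <- list(); intervals <- list(); bias <- list(); dens <- list()
  ri_by <- list()
  for (s in scheme$label) {
    for (nm in names(populations)) {
      pop <- populations[[nm]]
      lab <- assign_stratum(pop$age, pop$sex, scheme)
      x <- pop$value[!is.na(lab) & lab == s]
      key <- paste(s, nm)
      if (length(x) < 20L) {
        warning("population '", nm, "' missing/too small in stratum '", s, "'")
        summaries[[key]] <- data.frame(stratum = s, population = nm, n = length(x),
                                       median = NA, mean = NA, sd = NA,
                                       skewness = NA, kurtosis = NA)
        intervals[[key]] <- data.frame(stratum = s, population = nm, n = length(x),
                                       ll = NA, ll_lo = NA, ll_hi = NA,
                                       ul = NA, ul_lo = NA, ul_hi = NA)
        next
      }
      sm <- summarize_distribution(x)
      summaries[[key]] <- cbind(data.frame(stratum = s, population = nm), sm)
      ri <- suppressWarnings(reference_interval(x, conf = conf,
                                                boot_seed = boot_seed))
      ri_by[[key]] <- ri
      intervals[[key]] <- data.frame(stratum = s, population = nm, n = ri$n,
                                     ll = ri$ll, ll_lo = ri$ll_ci[1],
                                     ll_hi = ri$ll_ci[2], ul = ri$ul,
                                     ul_lo = ri$ul_ci[1], ul_hi = ri$ul_ci[2])
      d <- stats::density(x)
      dens[[key]] <- data.frame(stratum = s, population = nm, x = d$x, y = d$y)
    }
    dref <- ri_by[[paste(s, direct_name)]]
    if (is.null(dref)) next
    for (nm in setdiff(names(populations), direct_name)) {
      ri <- ri_by[[paste(s, nm)]]
      if (is.null(ri)) next
      b <- bias_ratio(dref, ri)
      bias[[paste(s, nm)]] <- data.frame(stratum = s, population = nm,
                                         sd_b = b$sd_b,
                                         ratio_ll = b$ratio_ll,
                                         class_ll = b$class_ll,
                                         ratio_ul = b$ratio_ul,
                                         class_ul = b$class_ul)
    }
  }
  bind <- function(l) {
    out <- do.call(rbind, l)
    if (!is.null(out)) rownames(out) <- NULL
    out
  }
  structure(list(summaries = bind(summaries), intervals = bind(intervals),
                 bias = bind(bias), densities = bind(dens)),
            class = "ri_report")
}

#' @export
print.ri_report <- function(x, digits = 3, ...) {
  cat("Reference intervals by population and stratum\n")
  print(x$intervals, digits = digits, row.names = FALSE)
  if (!is.null(x$bias)) {
    cat("\nBias ratios vs the direct population\n")
    b <- x$bias
    b$ratio_ll <- round(b$ratio_ll, 2)
    b$ratio_ul <- round(b$ratio_ul, 2)
    print(b, row.names = FALSE)
  }
  invisible(x)
}
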