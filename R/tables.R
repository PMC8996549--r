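# Published summary tables shipped as verification surfaces. They come from
# a published multicenter comparison of direct (PRINCE-style healthy cohort,
# Roche platform) and indirect (hospital LIS, Beckman platform) pediatric
# reference distributions; the package uses them to validate the shipped
# transference maps and the bias-ratio arithmetic. The underlying microdata
# are not public.

#' Published per-age-band means on both analyzer platforms
#'
#' Direct-cohort mean creatinine (per sex and one-year age band, 1 to <17
#' years) and urea (1 to <17 years) as printed on the original Roche scale
#' and after transference to the Beckman scale. Serves as the verification
#' surface for \code{\link{default_transfer_maps}}: both columns are printed
#' at 1 dp (creatinine) / 2 dp (urea), so reproduction is exact only for
#' rows whose transferred value is insensitive to the source's printed
#' rounding.
#'
#' @return data.frame: analyte, sex, age_lo, age_hi, mean_roche,
#'   mean_beckman, digits (printed decimals).
#' @export
platform_comparison_means <- function() {
  boys_roche <- c(25.0, 28.7, 32.6, 35.0, 37.1, 41.2, 42.0, 44.0, 46.1, 48.5,
                  49.1, 55.4, 59.9, 66.9, 75.6, 77.9)
  boys_beck  <- c(22.6, 26.1, 29.8, 32.0, 33.9, 37.8, 38.5, 40.4, 42.3, 44.6,
                  45.2, 51.1, 55.3, 61.9, 70.0, 72.2)
  girls_roche <- c(24.1, 28.9, 31.1, 34.6, 37.0, 40.2, 41.0, 43.1, 45.2, 45.4,
                   45.5, 51.3, 53.6, 55.9, 60.6, 61.9)
  girls_beck  <- c(21.8, 26.2, 28.4, 31.6, 33.9, 36.8, 37.6, 39.6, 41.5, 41.7,
                   41.8, 47.3, 49.4, 51.6, 56.0, 57.1)
  creat <- data.frame(
    analyte = "creatinine",
    sex = rep(c("male", "female"), each = 16L),
    age_lo = rep(1:16, 2L), age_hi = rep(2:17, 2L),
    mean_roche = c(boys_roche, girls_roche),
    mean_beckman = c(boys_beck, girls_beck),
    digits = 1L,
    stringsAsFactors = FALSE
  )
  urea <- data.frame(
    analyte = "urea", sex = c("male", "female"),
    age_lo = 1, age_hi = 17,
    mean_roche = c(4.44, 4.10), mean_beckman = c(4.50, 4.15),
    digits = 2L, stringsAsFactors = FALSE
  )
  rbind(creat, urea)
}

#' Published reference limits by method
#'
#' Lower (2.5th percentile) and upper (97.5th percentile) reference limits
#' per stratum for the transferred direct sample and for the GMM- and
#' SOM-partitioned LIS populations, under the default and the radical
#' outlier-detection strategies. Creatinine in umol/L, urea in mmol/L.
#'
#' @return data.frame: analyte, stratum, method, ll, ul.
#' @export
published_reference_limits <- function() {
  strata <- c("1 to <6 years", "6 to <12 years", "12 to <17 years boys",
              "12 to <17 years girls")
  methods <- c("direct", "gmm", "som", "gmm_radical", "som_radical")
  creat <- data.frame(
    analyte = "creatinine",
    stratum = rep(strata, each = 5L),
    method = rep(methods, 4L),
    ll = c(18.9, 19.2, 17.8, 19.4, 17.5,
           30.1, 28.1, 27.2, 28.5, 26.5,
           40.4, 39.6, 41.5, 38.0, 39.6,
           35.7, 34.0, 48.0, 35.1, 30.3),
    ul = c(39.5, 41.6, 39.8, 41.9, 49.6,
           52.6, 55.6, 63.8, 55.8, 66.3,
           87.2, 78.7, 87.6, 73.4, 83.9,
           68.6, 69.7, 77.7, 69.2, 83.5),
    stringsAsFactors = FALSE
  )
  urea <- data.frame(
    analyte = "urea", stratum = "1 to <17 years", method = methods,
    ll = c(2.62, 2.53, 2.54, 2.55, 2.45),
    ul = c(6.50, 6.06, 6.37, 6.05, 5.93),
    stringsAsFactors = FALSE
  )
  rbind(creat, urea)
}

#' Published bias ratios of indirect vs direct reference limits
#'
#' The signed ratio (indirect limit - direct limit) / sd_b, where sd_b is
#' 1/3.92 of the direct RI width, printed at 2 dp, for every indirect method
#' and stratum. Each cell is recomputable from
#' \code{\link{published_reference_limits}} via \code{\link{bias_ratio}}.
#'
#' @return data.frame: analyte, stratum, method, ratio_ll, ratio_ul.
#' @export
published_bias_ratios <- function() {
  strata <- c("1 to <6 years", "6 to <12 years", "12 to <17 years boys",
              "12 to <17 years girls")
  methods <- c("gmm", "som", "gmm_radical", "som_radical")
  creat <- data.frame(
    analyte = "creatinine",
    stratum = rep(strata, each = 4L),
    method = rep(methods, 4L),
    ratio_ll = c(0.06, -0.21, 0.10, -0.27,
                 -0.35, -0.51, -0.28, -0.63,
                 -0.07, 0.09, -0.20, -0.07,
                 -0.20, 1.47, -0.07, -0.64),
    ratio_ul = c(0.40, 0.06, 0.46, 1.92,
                 0.52, 1.95, 0.56, 2.39,
                 -0.71, 0.03, -1.16, -0.28,
                 0.13, 1.08, 0.07, 1.78),
    stringsAsFactors = FALSE
  )
  urea <- data.frame(
    analyte = "urea", stratum = "1 to <17 years", method = methods,
    ratio_ll = c(-0.09, -0.08, -0.07, -0.17),
    ratio_ul = c(-0.44, -0.13, -0.45, -0.58),
    stringsAsFactors = FALSE
  )
  rbind(creat, urea)
}
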