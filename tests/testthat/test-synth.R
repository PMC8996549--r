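test_that("generation is byte-identical under a fixed seed", {
  spec <- default_simulation_spec()
  a <- generate_lis(spec, 300, seed = 9)
  b <- generate_lis(spec, 300, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$labels, b$truth$labels)
  c1 <- generate_direct(spec, 200, seed = 9)
  c2 <- generate_direct(spec, 200, seed = 9)
  expect_identical(c1$records, c2$records)
})

test_that("stratum_spec validates its invariants", {
  h <- list(creatinine = c(40, 5, 0))
  expect_error(stratum_spec("x", 1, 6, healthy = h, weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  bad_corr <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(stratum_spec("x", 1, 6,
                            healthy = list(a = c(40, 5, 0), b = c(4, 1, 0)),
                            corr = bad_corr), "positive-definite")
  expect_error(stratum_spec("x", 1, 6, healthy = h,
                            low = list(creatinine = c(mean = 50, sd = 2))),
               "ordered")
  sp <- stratum_spec("x", 1, 6, healthy = h)
  expect_lt(sp$components$creatinine$low[["mean"]], 40)
  expect_gt(sp$components$creatinine$high[["mean"]], 40)
})

test_that("a symmetric healthy component reproduces its target moments", {
  # published transferred mean/SD for 6 to <12 years, no skew (lambda = 1)
  sp <- list(stratum_spec("6 to <12 years", 6, 12,
                          healthy = list(creatinine = c(40.6, 5.6, 0))))
  g <- generate_direct(sp, 4469, seed = 10, platform = "beckman")
  x <- g$records$value
  expect_lt(abs(mean(x) - 40.6) / 40.6, 0.02)   # mean within 2%
  expect_lt(abs(sd(x) - 5.6) / 5.6, 0.04)       # SD within 4%
})

test_that("skew targets are met and Box-Cox recovers the generator lambda", {
  spec <- default_simulation_spec()
  sp <- spec[["12 to <17 years boys"]]
  lam <- sp$components$creatinine$lambda
  expect_lt(lam, 1)  # right-skewed adolescent creatinine
  g <- generate_direct(list(sp), 5000, seed = 11, platform = "beckman")
  x <- g$records$value[g$records$analyte == "creatinine"]
  expect_lt(abs(indirectRI:::sample_skewness(x) - 0.37), 0.15)
  expect_lt(abs(boxcox_fit(x)$lambda - lam), 0.15)
})

test_that("ground-truth quantiles match a large-draw empirical oracle", {
  spec <- default_simulation_spec()
  sp <- spec[["1 to <6 years"]]
  cc <- sp$components$creatinine
  set.seed(12)
  draws <- indirectRI:::.bc_inv_vec(rnorm(1e6, cc$latent$mu, cc$latent$sigma),
                                    cc$lambda)
  emp <- quantile(draws, c(0.025, 0.975), names = FALSE)
  q <- subset(generate_direct(list(sp), 100, seed = 1)$truth$quantiles,
              analyte == "creatinine")
  expect_lt(abs(emp[1] - q$q_lo) / q$q_lo, 0.005)
  expect_lt(abs(emp[2] - q$q_hi) / q$q_hi, 0.005)
  # the generated healthy sample's percentiles agree with the ground truth
  big <- generate_direct(list(sp), 20000, seed = 13, platform = "beckman")
  x <- big$records$value[big$records$analyte == "creatinine"]
  expect_lt(abs(quantile(x, 0.025, names = FALSE) - q$q_lo) / q$q_lo, 0.02)
  expect_lt(abs(quantile(x, 0.975, names = FALSE) - q$q_hi) / q$q_hi, 0.02)
})

test_that("repeat visits inflate record counts and dedup removes them exactly", {
  sp <- list(stratum_spec("x", 1, 17,
                          healthy = list(creatinine = c(40, 5, 0),
                                         urea = c(4.3, 0.9, 0),
                                         uric_acid = c(250, 60, 0)),
                          repeat_visit_rate = 0.3))
  g <- generate_lis(sp, 10000, seed = 14, missing_frac = 0,
                    implausible_frac = 0)
  per_analyte <- table(g$records$analyte)
  # expected 13,000 records per analyte; 4 binomial SEs ~ 185
  expect_true(all(abs(per_analyte - 13000) < 200))
  dd <- dedupe_earliest(g$records)
  expect_equal(nrow(dd), 3L * 10000L)
  # repeats are strictly later, so dedup recovers the original first visit
  expect_true(all(table(dd$analyte) == 10000L))
})

test_that("zero contamination makes LIS and direct samples indistinguishable", {
  h <- list(creatinine = c(40.6, 5.6, 0.23))
  sp <- list(stratum_spec("x", 6, 12,
                          healthy = h,
                          weights = c(low = 0, healthy = 1, high = 0),
                          repeat_visit_rate = 0))
  lis <- generate_lis(sp, 5000, seed = 15, missing_frac = 0,
                      implausible_frac = 0)
  dir <- generate_direct(sp, 5000, seed = 16, platform = "beckman")
  ks <- suppressWarnings(
    ks.test(lis$records$value[lis$records$analyte == "creatinine"],
            dir$records$value[dir$records$analyte == "creatinine"]))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(lis$truth$labels$component == "healthy"))
})

test_that("healthy creatinine means increase across the age bands", {
  g <- generate_direct(default_simulation_spec(), 500, seed = 17,
                       platform = "beckman")
  r <- g$records[g$records$analyte == "creatinine", ]
  lab <- assign_stratum(r$age, r$sex, default_strata("creatinine"))
  m <- tapply(r$value, lab, mean)
  expect_lt(m[["1 to <6 years"]], m[["6 to <12 years"]])
  expect_lt(m[["6 to <12 years"]], m[["12 to <17 years boys"]])
})

test_that("injected missing and implausible values exercise the cleaning", {
  g <- generate_lis(default_simulation_spec(), 500, seed = 18,
                    missing_frac = 0.01, implausible_frac = 0.01)
  expect_gt(sum(is.na(g$records$value)), 0L)
  res <- clean_records(g$records)
  expect_false(anyNA(res$records$value))
  b <- default_bounds()
  for (a in names(b)) {
    v <- res$records$value[res$records$analyte == a]
    expect_true(all(v >= b[[a]][1] & v <= b[[a]][2]))
  }
})
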