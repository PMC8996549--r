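test_that("deduplication keeps the earliest record per subject and analyte", {
  ds <- make_records(c("A", "A", "B"), c(30, 28, 40),
                     date = as.Date(c("2017-03-01", "2017-08-01", "2017-05-05")))
  out <- dedupe_earliest(ds)
  expect_equal(nrow(out), 2L)
  expect_equal(out$value[out$subject_id == "A"], 30)
  expect_equal(out$collection_date[out$subject_id == "A"], as.Date("2017-03-01"))
  # all unique -> identity; idempotence
  uniq <- make_records(letters[1:5], 1:5)
  expect_equal(nrow(dedupe_earliest(uniq)), 5L)
  expect_identical(dedupe_earliest(out), out)
  # date tie broken by lowest value
  tie <- make_records(c("A", "A"), c(12, 9), date = as.Date("2017-01-01"))
  expect_equal(dedupe_earliest(tie)$value, 9)
})

test_that("deduplication matches a brute-force group-minimum oracle", {
  set.seed(7)
  n <- 1000L
  ds <- make_records(sample(sprintf("S%03d", 1:300), n, replace = TRUE),
                     value = round(runif(n, 20, 80), 1),
                     date = as.Date("2017-01-01") + sample.int(364L, n, TRUE))
  out <- dedupe_earliest(ds)
  expect_equal(nrow(out), length(unique(ds$subject_id)))
  oracle <- tapply(seq_len(n), ds$subject_id, function(i) {
    i[order(ds$collection_date[i], ds$value[i])][1]
  })
  oracle_dates <- ds$collection_date[oracle][order(names(oracle))]
  got_dates <- out$collection_date[order(out$subject_id)]
  expect_equal(got_dates, unname(oracle_dates))
})

test_that("age filter keeps the half-open window", {
  ds <- make_records(letters[1:4], 30, age = c(0.5, 1.0, 16.99, 17.0))
  out <- filter_age(ds)
  expect_setequal(out$age, c(1.0, 16.99))
  expect_equal(nrow(filter_age(ds[0, ])), 0L)
  expect_error(filter_age(ds, 5, 5), "lo < hi")
})

test_that("age filter keeps the analytic fraction of a uniform population", {
  set.seed(21)
  ds <- make_records(seq_len(10000), 30, age = runif(10000, 0, 20))
  frac <- nrow(filter_age(ds)) / 10000
  # true proportion 16/20 = 0.8; 4 binomial SEs ~ 0.016
  expect_lt(abs(frac - 0.8), 0.016)
})

test_that("Box-Cox MLE finds the generating transform", {
  set.seed(31)
  expect_lt(abs(boxcox_fit(exp(rnorm(5000)))$lambda), 0.1)      # lognormal
  x <- rnorm(5000, 50, 5)
  x <- x[x > 0]
  expect_lt(abs(boxcox_fit(x)$lambda - 1), 0.2)                 # already normal
  expect_error(boxcox_fit(c(-1, rep(2, 20))), "shift")
  expect_error(boxcox_fit(rep(1.5, 5)), "n >= 10")
})

test_that("Box-Cox lambda matches a dense grid-search oracle", {
  grid_best <- function(x) {
    n <- length(x); slx <- sum(log(x))
    lams <- seq(-3, 3, by = 1e-4)
    ll <- vapply(lams, function(l) {
      y <- if (abs(l) < 1e-8) log(x) else (x^l - 1) / l
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
    }, 0)
    lams[which.max(ll)]
  }
  set.seed(32)
  for (x in list(exp(rnorm(400, 3, 0.4)), rgamma(400, shape = 4, rate = 0.2))) {
    expect_lt(abs(boxcox_fit(x)$lambda - grid_best(x)), 2e-4)
  }
})

test_that("Tukey fences flag gross outliers and respect monotone transforms", {
  tf <- tukey_outliers(c(1:100, 1000))
  expect_equal(which(tf$mask), 101L)
  expect_false(any(tukey_outliers(rep(c(4, 5, 6), 10))$mask))
  expect_error(tukey_outliers(c(1, 2, 3)), "n >= 4")
  # flags on the transformed scale equal flags from back-mapped raw fences
  set.seed(33)
  x <- exp(rnorm(500, 2, 0.6))
  fit <- boxcox_fit(x)
  tf <- tukey_outliers(x, fit)
  expect_equal(tf$mask, x < tf$lower_raw | x > tf$upper_raw)
  # scale equivariance at lambda = 1 (raw scale)
  y <- rnorm(200, 10, 2)
  f1 <- tukey_outliers(y); f2 <- tukey_outliers(3 * y)
  expect_equal(f2$lower, 3 * f1$lower)
  expect_equal(f2$upper, 3 * f1$upper)
  expect_equal(f1$mask, f2$mask)
})

test_that("Tukey flag rate on a normal sample matches the nominal ~0.7%", {
  set.seed(34)
  rate <- mean(tukey_outliers(rnorm(10000))$mask)
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.010)
})

test_that("radical exclusion removes a flagged subject from all analytes", {
  set.seed(41)
  n <- 60L
  ids <- sprintf("S%02d", 1:n)
  ds <- rbind(
    make_records(ids, rnorm(n, 40, 4), analyte = "creatinine"),
    make_records(ids, rnorm(n, 4.3, 0.4), analyte = "urea"),
    make_records(ids, rnorm(n, 250, 25), analyte = "uric_acid")
  )
  planted <- c("S03", "S17", "S42")
  ds$value[ds$analyte == "uric_acid" & ds$subject_id %in% planted] <- 1500
  res <- radical_exclusion(ds)
  kept <- unique(res$records$subject_id)
  expect_false(any(planted %in% kept))
  expect_equal(sort(kept), sort(setdiff(ids, planted)))
  # every analyte lost exactly the planted subjects
  for (a in c("creatinine", "urea")) {
    expect_equal(sum(res$records$analyte == a), n - length(planted))
  }
  # nothing flagged -> identity
  clean <- rbind(make_records(ids, seq(38, 44, length.out = n)),
                 make_records(ids, seq(4, 4.6, length.out = n), analyte = "urea"),
                 make_records(ids, seq(240, 260, length.out = n),
                              analyte = "uric_acid"))
  res2 <- radical_exclusion(clean)
  expect_equal(nrow(res2$records), nrow(clean))
})

test_that("the cleaning chain never increases the record count", {
  lis <- generate_lis(n_per_stratum = 400, seed = 5)
  res <- clean_records(lis$records)
  cc <- res$report$counts
  expect_true(all(diff(cc) <= 0))
  expect_equal(unname(cc["input"]), nrow(lis$records))
  expect_equal(unname(cc["after_outliers"]), nrow(res$records))
})

test_that("the age tree recovers planted mean jumps", {
  set.seed(51)
  n <- 3000L
  age <- runif(n, 1, 17)
  mu <- ifelse(age < 6, 29, ifelse(age < 12, 41, 61))
  ds <- make_records(seq_len(n), rnorm(n, mu, 5), age = age,
                     sex = sample(c("male", "female"), n, TRUE))
  tree <- age_partition_tree(ds, max_leaves = 3)
  expect_equal(tree$cut_points, c(6, 12))
  # constant mean -> no cuts
  flat <- make_records(seq_len(500), rnorm(500, 40, 5), age = runif(500, 1, 17))
  expect_length(age_partition_tree(flat, max_leaves = 4)$cut_points, 0L)
  expect_error(age_partition_tree(ds, max_leaves = 1), "max_leaves")
})

test_that("a single planted jump matches the exhaustive single-split oracle", {
  set.seed(52)
  n <- 2000L
  age <- runif(n, 1, 17)
  ds <- make_records(seq_len(n), rnorm(n, ifelse(age < 9, 30, 55), 5), age = age)
  tree <- age_partition_tree(ds, max_leaves = 2)
  sse <- function(x) sum((x - mean(x))^2)
  gains <- vapply(2:16, function(cc) {
    sse(ds$value) - sse(ds$value[age < cc]) - sse(ds$value[age >= cc])
  }, 0)
  expect_equal(tree$cut_points, (2:16)[which.max(gains)])
  expect_equal(tree$cut_points, 9)
})

test_that("sex split is kept only where it explains variance", {
  set.seed(53)
  n <- 4000L
  age <- runif(n, 1, 17)
  sex <- sample(c("male", "female"), n, TRUE)
  mu <- ifelse(age < 12, 40, ifelse(sex == "male", 61, 52))
  ds <- make_records(seq_len(n), rnorm(n, mu, 5), age = age, sex = sex)
  tree <- age_partition_tree(ds, max_leaves = 2)
  expect_equal(tree$cut_points, 12)
  expect_false(tree$leaves$sex_split[1])
  expect_true(tree$leaves$sex_split[2])
})
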