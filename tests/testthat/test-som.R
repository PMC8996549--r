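# helper: a labelled 3-cluster triple along one axis, sep healthy-SDs apart
draw_triples <- function(n, sep = 6, seed = 1) {
  set.seed(seed)
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  shift <- (comp - 2) * sep
  x <- cbind(rnorm(n, 40 + shift * 5, 5),
             rnorm(n, 4.3 + shift * 0.4, 0.4),
             rnorm(n, 250 + shift * 25, 25))
  colnames(x) <- c("creatinine", "urea", "uric_acid")
  rownames(x) <- sprintf("S%05d", seq_len(n))
  list(x = x, comp = comp)
}

test_that("subject vectors require complete triples and match a set oracle", {
  ids <- sprintf("S%02d", 1:20)
  ds <- rbind(make_records(ids, rnorm(20, 40, 4), analyte = "creatinine"),
              make_records(ids[1:15], rnorm(15, 4.3, 0.4), analyte = "urea"),
              make_records(ids[3:20], rnorm(18, 250, 25), analyte = "uric_acid"))
  m <- som_vectors(ds)
  oracle <- Reduce(intersect, list(ids, ids[1:15], ids[3:20]))
  expect_setequal(rownames(m), oracle)
  expect_equal(attr(m, "n_dropped"), 20L - length(oracle))
  # all complete -> all kept
  full <- rbind(make_records(ids, 1, analyte = "creatinine"),
                make_records(ids, 2, analyte = "urea"),
                make_records(ids, 3, analyte = "uric_acid"))
  expect_equal(nrow(som_vectors(full)), 20L)
})

test_that("column scaling is exact and invertible", {
  m <- matrix(c(1, 2, 3, 4, 5,
                10, 30, 20, 50, 40,
                2.2, 2.4, 2.0, 2.6, 2.8), 5, 3)
  m <- rbind(m, m)  # n >= 10
  sc <- scale_columns(m)
  expect_equal(unname(colMeans(sc$x)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$x, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(sc$center, colMeans(m))
  expect_equal(sc$scale, apply(m, 2, sd))
  expect_equal(unscale_columns(sc), m, tolerance = 1e-12)
  m2 <- m; m2[, 2] <- 7
  expect_error(scale_columns(m2), "zero-variance")
})

test_that("PCA initialization lies on the first principal axis", {
  d <- draw_triples(2000, seed = 91)
  sc <- scale_columns(d$x)
  cb <- som_init_pca(sc$x)
  # PC1 direction from an independent eigendecomposition of the covariance
  ev <- eigen(cov(sc$x), symmetric = TRUE)$vectors[, 1]
  dir <- cb[3, ] - cb[1, ]
  dir <- dir / sqrt(sum(dir^2))
  expect_equal(abs(sum(dir * ev)), 1, tolerance = 1e-8)
  # middle node at the centroid; edges at +/- 2.5 SD of PC1 scores
  expect_equal(unname(cb[2, ]), unname(colMeans(sc$x)), tolerance = 1e-12)
  s1 <- prcomp(sc$x)$sdev[1]
  expect_equal(sqrt(sum((cb[3, ] - cb[2, ])^2)), 2.5 * s1, tolerance = 1e-8)
})

test_that("collinear data put the initial codebooks exactly on the line", {
  t <- seq(-3, 3, length.out = 50)
  x <- cbind(t, 2 * t, -t)
  cb <- som_init_pca(x)
  # each codebook must satisfy the same linear relations
  expect_equal(cb[, 2], 2 * cb[, 1], tolerance = 1e-10)
  expect_equal(cb[, 3], -cb[, 1], tolerance = 1e-10)
  expect_error(som_init_pca(matrix(1, 20, 3)), "rank-deficient")
})

test_that("zero-width kernel batch SOM equals Lloyd k-means from the same init", {
  d <- draw_triples(1000, seed = 92)
  sc <- scale_columns(d$x)
  init <- som_init_pca(sc$x)
  fit <- som_fit(sc$x, init = init, kernel_width = 0, max_iter = 200)
  km <- kmeans(sc$x, centers = init, algorithm = "Lloyd", iter.max = 200)
  expect_equal(unname(fit$codebooks), unname(km$centers), tolerance = 1e-8)
  expect_equal(unname(fit$assignments), unname(km$cluster))
  expect_true(fit$converged)
})

test_that("assignment accuracy reaches 99% at 6-SD separation", {
  d <- draw_triples(3000, sep = 6, seed = 93)
  sc <- scale_columns(d$x)
  fit <- som_fit(sc$x)
  # nodes are ordered along PC1 which may flip sign; align by best permutation
  perms <- list(1:3, 3:1)
  acc <- max(vapply(perms, function(p) mean(p[fit$assignments] == d$comp), 0))
  expect_gte(acc, 0.99)
})

test_that("an already-converged configuration makes zero reassignments", {
  d <- draw_triples(600, seed = 94)
  sc <- scale_columns(d$x)
  fit <- som_fit(sc$x, kernel_width = 0)
  refit <- som_fit(sc$x, init = fit$codebooks, kernel_width = 0)
  expect_true(refit$converged)
  expect_lte(refit$n_iter, 2L)
  expect_equal(refit$assignments, fit$assignments)
})

test_that("codebook PC1 projections stay ordered on separable data", {
  d <- draw_triples(2000, sep = 6, seed = 95)
  sc <- scale_columns(d$x)
  fit <- som_fit(sc$x)
  v1 <- prcomp(sc$x)$rotation[, 1]
  proj <- as.vector(fit$codebooks %*% v1)
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
})

test_that("the middle node is selected by codebook ordering and is central", {
  d <- draw_triples(3000, sep = 6, seed = 96)
  sc <- scale_columns(d$x)
  fit <- som_fit(sc$x)
  sel <- select_normal_node(fit)
  # recovers >= 90% of the generator's normal subjects
  normal_ids <- rownames(d$x)[d$comp == 2]
  expect_gte(mean(normal_ids %in% sel$subjects), 0.90)
  # selected subjects' raw creatinine mean lies between the other nodes'
  raw_mean <- function(node) mean(d$x[fit$assignments == node, "creatinine"])
  others <- setdiff(1:3, sel$node)
  mid <- raw_mean(sel$node)
  expect_true(mid > min(sapply(others, raw_mean)) &&
              mid < max(sapply(others, raw_mean)))
})

test_that("assignment never increases within-node distance once kernel is 0", {
  d <- draw_triples(800, seed = 97)
  sc <- scale_columns(d$x)
  init <- som_init_pca(sc$x)
  wss <- function(x, cb, asg) {
    sum(vapply(seq_len(nrow(cb)), function(j) {
      sum(sweep(x[asg == j, , drop = FALSE], 2, cb[j, ])^2)
    }, 0))
  }
  cb <- init
  prev <- Inf
  for (i in 1:10) {
    asg <- indirectRI:::.som_assign(sc$x, cb)
    w <- wss(sc$x, cb, asg)
    expect_lte(w, prev + 1e-10)
    prev <- w
    for (j in 1:3) if (any(asg == j)) cb[j, ] <- colMeans(sc$x[asg == j, , drop = FALSE])
    w2 <- wss(sc$x, cb, asg)
    expect_lte(w2, prev + 1e-10)
    prev <- w2
  }
})

test_that("empty nodes are held fixed with a warning", {
  set.seed(98)
  x <- matrix(rnorm(300), 100, 3)
  init <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(100, 100, 100))
  expect_warning(fit <- som_fit(x, init = init, kernel_width = 0),
                 "empty node")
  expect_equal(unname(fit$codebooks[3, ]), c(100, 100, 100))
})
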