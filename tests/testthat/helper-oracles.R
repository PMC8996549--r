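# Test helpers: independent oracles and fixture builders.

# Quick record-set builder with sensible defaults.
make_records <- function(subject_id, value, age = 5, sex = "male",
                         analyte = "creatinine",
                         date = as.Date("2017-01-01"), source = "lis") {
  n <- max(length(subject_id), length(value), length(age), length(date))
  data.frame(
    subject_id = rep_len(as.character(subject_id), n),
    collection_date = rep_len(date, n),
    age = rep_len(age, n),
    sex = rep_len(sex, n),
    analyte = rep_len(analyte, n),
    value = rep_len(value, n),
    units = rep_len(unname(analyte_units()[rep_len(analyte, n)]), n),
    source = rep_len(source, n),
    stringsAsFactors = FALSE
  )
}

# Independent slow EM for a 3-component univariate normal mixture: naive
# per-component density arithmetic, no log-space shortcuts. Same convergence
# semantics as gmm_fit (relative log-likelihood change).
ref_em <- function(x, means, sds, weights, tol = 1e-8, max_iter = 500) {
  n <- length(x)
  ll_prev <- -Inf
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    dens <- matrix(0, n, 3)
    for (k in 1:3) {
      dens[, k] <- weights[k] *
        exp(-(x - means[k])^2 / (2 * sds[k]^2)) / sqrt(2 * pi * sds[k]^2)
    }
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    if (it > 1 && abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12)) break
    ll_prev <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    weights <- nk / n
    for (k in 1:3) {
      means[k] <- sum(resp[, k] * x) / nk[k]
      sds[k] <- sqrt(sum(resp[, k] * (x - means[k])^2) / nk[k])
    }
  }
  ord <- order(means)
  list(weights = weights[ord], means = means[ord], sds = sds[ord],
       loglik = ll, n_iter = it)
}

# log-likelihood of a parameter set, computed independently
mix_loglik <- function(x, means, sds, weights) {
  dens <- 0
  for (k in seq_along(means)) {
    dens <- dens + weights[k] * stats::dnorm(x, means[k], sds[k])
  }
  sum(log(dens))
}

# draw a labelled 3-component 1-D mixture
draw_mixture <- function(n, means, sds, weights, seed) {
  set.seed(seed)
  comp <- sample.int(3L, n, replace = TRUE, prob = weights)
  list(x = stats::rnorm(n, means[comp], sds[comp]), comp = comp)
}
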