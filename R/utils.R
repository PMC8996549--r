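# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise log(sum(exp(m))) without overflow; m is a numeric matrix
row_log_sum_exp <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}

# bias-corrected sample skewness (G1)
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# bias-corrected excess kurtosis (G2)
sample_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  g2 <- mean((x - m)^4) / s2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}
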