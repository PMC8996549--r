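# Three-component univariate Gaussian mixture fitted by EM, initialized from
# a direct reference sample: component means start at the direct sample's
# quartiles, component SDs at its SD, weights at equal thirds. The middle
# fitted component is read as the "potential healthy" cluster; the outer two
# as pathologically low / high.

#' Mixture starting values from a direct reference sample
#'
#' Means are the lower quartile, median, and upper quartile (type-7 linear
#' interpolation) of the transferred direct sample; all three SDs start at
#' the sample SD; weights start equal.
#'
#' @param direct_values Numeric vector, n >= 20, non-degenerate.
#' @param weights Starting mixing proportions (default equal thirds).
#' @return Object of class \code{"gmm_init"}: \code{means}, \code{sds},
#'   \code{weights}.
#' @export
gmm_init <- function(direct_values, weights = rep(1 / 3, 3)) {
  if (length(direct_values) < 20L) stop("initialization needs n >= 20")
  s <- stats::sd(direct_values)
  if (!is.finite(s) || s <= 0) stop("degenerate sample: zero standard deviation")
  m <- stats::quantile(direct_values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (any(diff(m) <= 0)) stop("sample quartiles are not strictly increasing")
  if (length(weights) != 3L || any(weights <= 0)) stop("need 3 positive weights")
  structure(list(means = m, sds = rep(s, 3L), weights = weights / sum(weights)),
            class = "gmm_init")
}

#' @export
print.gmm_init <- function(x, ...) {
  cat("GMM initialization\n  means:", format(x$means, digits = 5),
      "\n  sds:  ", format(x$sds, digits = 5),
      "\n  weights:", format(x$weights, digits = 4), "\n")
  invisible(x)
}

#' Fit a 3-component Gaussian mixture by EM
#'
#' Alternates the E-step (posterior responsibilities under the current
#' weights, means, and SDs, computed in log space) and the M-step (weighted
#' moment updates) until the relative log-likelihood change falls below
#' \code{tol} or \code{max_iter} is reached. Components are reordered by
#' increasing mean on return, so results are invariant to permutations of the
#' initialization. A component SD falling below \code{sd_floor} is clamped
#' with a warning rather than being allowed to collapse.
#'
#' @param values Numeric data, n >= 50.
#' @param init A \code{\link{gmm_init}}; defaults to initialization from the
#'   data themselves.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Lower bound for component SDs; default
#'   \code{1e-3 * sd(values)}.
#' @return Object of class \code{"gmm3"}: \code{weights}, \code{means},
#'   \code{sds} (sorted by mean), \code{resp} (n x 3 responsibilities),
#'   \code{loglik}, \code{loglik_trace} (non-decreasing), \code{n_iter},
#'   \code{converged}, and the \code{data}.
#' @seealso \code{\link{select_healthy}}, \code{\link{gmm_partition}}
#' @export
gmm_fit <- function(values, init = gmm_init(values), tol = 1e-8,
                    max_iter = 500L, sd_floor = NULL) {
  n <- length(values)
  if (n < 50L) stop("EM fit needs n >= 50")
  if (any(!is.finite(values))) stop("non-finite values")
  if (is.null(sd_floor)) sd_floor <- 1e-3 * stats::sd(values)

  pi_k <- init$weights
  mu <- as.numeric(init$means)
  sg <- as.numeric(init$sds)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  clamped <- FALSE
  resp <- NULL
  it <- 0L

  e_step <- function() {
    ld <- vapply(1:3, function(k) {
      log(pi_k[k]) + stats::dnorm(values, mu[k], sg[k], log = TRUE)
    }, numeric(n))
    lse <- row_log_sum_exp(ld)
    list(resp = exp(ld - lse), ll = sum(lse))
  }

  for (it in seq_len(max_iter)) {
    es <- e_step()
    resp <- es$resp
    if (!is.finite(es$ll)) stop("non-finite mixture likelihood")
    ll_trace <- c(ll_trace, es$ll)
    if (it > 1L && abs(es$ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- es$ll
    # M-step
    nk <- colSums(resp)
    pi_k <- nk / n
    mu <- colSums(resp * values) / nk
    sg <- sqrt(colSums(resp * (outer(values, mu, "-")^2)) / nk)
    low <- sg < sd_floor
    if (any(low)) {
      sg[low] <- sd_floor
      if (!clamped) warning("component SD clamped to floor to prevent collapse")
      clamped <- TRUE
    }
  }
  if (!converged) {
    # parameters moved in the last M-step; sync responsibilities once
    es <- e_step()
    resp <- es$resp
    ll_trace <- c(ll_trace, es$ll)
  }
  ord <- order(mu)
  structure(list(weights = pi_k[ord], means = mu[ord], sds = sg[ord],
                 resp = resp[, ord, drop = FALSE],
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 n_iter = it, converged = converged,
                 sd_floor = sd_floor, data = values, init = init),
            class = "gmm3")
}

#' @export
print.gmm3 <- function(x, digits = 4, ...) {
  cat(sprintf("3-component Gaussian mixture (EM, %d iteration(s), %s)\n",
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  print(coef(x), digits = digits)
  cat(sprintf("log-likelihood %.4f on n = %d\n", x$loglik, length(x$data)))
  invisible(x)
}

#' @export
summary.gmm3 <- function(object, ...) {
  lab <- predict(object, type = "class")
  out <- list(coef = coef(object), n = tabulate(lab, 3L),
              loglik = object$loglik, n_iter = object$n_iter,
              converged = object$converged)
  class(out) <- "summary.gmm3"
  out
}

#' @export
print.summary.gmm3 <- function(x, ...) {
  tab <- cbind(x$coef, n = x$n)
  print(tab, digits = 4)
  cat(sprintf("log-likelihood %.4f; %d iterations%s\n", x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.gmm3 <- function(object, ...) {
  m <- cbind(weight = object$weights, mean = object$means, sd = object$sds)
  rownames(m) <- c("low", "middle", "high")
  m
}

#' @export
logLik.gmm3 <- function(object, ...) {
  structure(object$loglik, df = 8L, nobs = length(object$data),
            class = "logLik")
}

#' Posterior responsibilities or hard cluster labels
#'
#' Hard labels are the argmax posterior responsibility; components are
#' ordered by increasing mean, and exact ties go to the lower-mean component.
#'
#' @param object A fitted \code{"gmm3"}.
#' @param newdata Optional new values (defaults to the training data).
#' @param type "class" for hard labels 1/2/3 (low/middle/high) or "response"
#'   for the n x 3 responsibility matrix.
#' @param ... Unused.
#' @return Integer labels or responsibility matrix.
#' @export
predict.gmm3 <- function(object, newdata = NULL, type = c("class", "response"),
                         ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    resp <- object$resp
  } else {
    ld <- vapply(1:3, function(k) {
      log(object$weights[k]) +
        stats::dnorm(newdata, object$means[k], object$sds[k], log = TRUE)
    }, numeric(length(newdata)))
    if (length(newdata) == 1L) ld <- matrix(ld, nrow = 1L)
    resp <- exp(ld - row_log_sum_exp(ld))
  }
  if (type == "response") return(resp)
  max.col(resp, ties.method = "first")
}

#' Draw from a fitted mixture
#'
#' @param object A fitted \code{"gmm3"}.
#' @param nsim Number of draws.
#' @param seed Optional seed applied before drawing.
#' @param ... Unused.
#' @return Numeric vector of \code{nsim} simulated values.
#' @export
simulate.gmm3 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(3L, nsim, replace = TRUE, prob = object$weights)
  stats::rnorm(nsim, object$means[k], object$sds[k])
}

#' @export
plot.gmm3 <- function(x, breaks = 50, main = "Gaussian mixture fit", ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE, main = main,
                      xlab = "value", border = "grey70", ...)
  xx <- seq(min(x$data), max(x$data), length.out = 400)
  for (k in 1:3) {
    graphics::lines(xx, x$weights[k] * stats::dnorm(xx, x$means[k], x$sds[k]),
                    col = k + 1, lwd = 2)
  }
  graphics::lines(xx, rowSums(vapply(1:3, function(k) {
    x$weights[k] * stats::dnorm(xx, x$means[k], x$sds[k])
  }, numeric(length(xx)))), lty = 2)
  invisible(h)
}

#' Extract the potential-healthy (middle) component
#'
#' Returns the values hard-assigned to the component with the middle fitted
#' mean. If two component means coincide (degenerate fit), the middle is
#' chosen by largest weight with a warning.
#'
#' @param fit A fitted \code{"gmm3"}.
#' @param labels Optional hard labels; defaults to \code{predict(fit)}.
#' @return List: \code{values} (selected), \code{index} (positions in the
#'   training data), \code{component} (selected component), \code{fraction}.
#' @export
select_healthy <- function(fit, labels = predict(fit, type = "class")) {
  mid <- 2L
  eps <- 1e-8 * (abs(fit$means[3]) + abs(fit$means[1]) + 1)
  if (diff(fit$means)[1] < eps || diff(fit$means)[2] < eps) {
    warning("component means nearly identical; middle chosen by largest weight")
    mid <- which.max(fit$weights)
  }
  idx <- which(labels == mid)
  list(values = fit$data[idx], index = idx, component = mid,
       fraction = length(idx) / length(fit$data))
}

#' GMM partitioning across strata
#'
#' Runs \code{\link{gmm_fit}} independently in every stratum of a scheme,
#' initializing each fit from the transferred direct sample of the same
#' stratum, and extracts the middle ("potential healthy") cluster.
#'
#' @param lis_records Cleaned LIS records for one analyte.
#' @param direct_records Cleaned, transferred direct-sample records for the
#'   same analyte (initialization source).
#' @param scheme \code{\link{stratum_scheme}} for the analyte.
#' @param ... Passed to \code{\link{gmm_fit}}.
#' @return Named list per stratum: \code{fit}, \code{selected} (record
#'   indices into the stratum's LIS rows), \code{records} (selected LIS
#'   records), \code{fraction}.
#' @export
gmm_partition <- function(lis_records, direct_records, scheme, ...) {
  lab_lis <- assign_stratum(lis_records$age, lis_records$sex, scheme)
  lab_dir <- assign_stratum(direct_records$age, direct_records$sex, scheme)
  out <- list()
  for (s in scheme$label) {
    li <- which(!is.na(lab_lis) & lab_lis == s)
    di <- which(!is.na(lab_dir) & lab_dir == s)
    if (length(di) < 20L || length(li) < 50L) {
      warning("stratum '", s, "' skipped: insufficient records")
      next
    }
    init <- gmm_init(direct_records$value[di])
    fit <- gmm_fit(lis_records$value[li], init = init, ...)
    sel <- select_healthy(fit)
    out[[s]] <- list(fit = fit, selected = li[sel$index],
                     records = lis_records[li[sel$index], , drop = FALSE],
                     n_total = length(li), fraction = sel$fraction)
  }
  out
}
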