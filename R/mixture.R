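# 1-D Gaussian mixture fitting for Ks distributions: EM with k-means++
# initialization, multiple restarts, a variance floor against singular
# components, and BIC model selection over a range of component counts.

kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- vapply(x, function(v) min((v - centers[1:(j - 1L)])^2),
                   numeric(1))
      if (sum(d2) <= 0) {
        centers[j] <- x[sample.int(length(x), 1L)]
      } else {
        centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
      }
    }
  }
  centers
}

em_gmm_1d <- function(x, k, init_means, variance_floor = 1e-6,
                      tol = 1e-8, max_iter = 500L) {
  n <- length(x)
  sd_floor <- sqrt(variance_floor)
  # initial hard assignment to nearest center
  assign <- max.col(-abs(outer(x, init_means, "-")), ties.method = "first")
  w <- tabulate(assign, k) / n
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  mu <- vapply(1:k, function(j) {
    if (any(assign == j)) mean(x[assign == j]) else init_means[j]
  }, numeric(1))
  sdev <- vapply(1:k, function(j) {
    if (sum(assign == j) > 1L) max(sd(x[assign == j]), sd_floor) else
      max(sd(x) / k, sd_floor)
  }, numeric(1))

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(1:k, function(j) w[j] * dnorm(x, mu[j], sdev[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens) + 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    for (j in 1:k) {
      v <- sum(resp[, j] * (x - mu[j])^2) / nk[j]
      sdev[j] <- sqrt(max(v, variance_floor))
    }
  }
  list(weights = w, means = mu, sds = sdev, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, n_iter = length(ll_trace))
}

#' Fit a Gaussian mixture to a Ks distribution
#'
#' Values are restricted to the Ks analysis window (dropping near-zero
#' allelic/identical pairs and saturated values), then a Gaussian mixture is
#' fitted by EM for each candidate component count `K`, with k-means++
#' initialization per restart and the best restart kept by log-likelihood.
#' The reported model minimizes BIC over `k_range`.  Components are sorted
#' by ascending mean.
#'
#' @param values Numeric Ks values (NAs dropped).
#' @param k_range Candidate component counts.
#' @param n_restarts EM restarts per `K`.
#' @param seed Optional RNG seed for reproducible restarts.
#' @param variance_floor Lower bound on component variances.
#' @param window Ks analysis window `c(lo, hi)`, or `NULL` for no filtering.
#' @param tol EM convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @return `ks_mixture` list: `K`, `weights`, `means`, `sds`, `loglik`,
#'   `bic`, `bic_table` (per-`K` BIC), `n`, `loglik_trace` of the selected
#'   fit.
#' @export
fit_gmm <- function(values, k_range = 1:5, n_restarts = 10L, seed = NULL,
                    variance_floor = 1e-6, window = c(0.01, 2.0),
                    tol = 1e-8, max_iter = 500L) {
  x <- values[!is.na(values)]
  if (!is.null(window)) x <- x[x >= window[1L] & x <= window[2L]]
  if (length(x) < 10L) stop("need at least 10 Ks values in the window")
  k_range <- k_range[k_range <= length(x)]
  if (length(k_range) == 0L) stop("fewer values than components")
  runner <- function() {
    best_by_k <- list()
    for (k in k_range) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- em_gmm_1d(x, k, kmeanspp_centers(x, k),
                         variance_floor = variance_floor, tol = tol,
                         max_iter = max_iter)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      p <- 3L * k - 1L
      best$bic <- -2 * best$loglik + p * log(length(x))
      best$K <- k
      best_by_k[[as.character(k)]] <- best
    }
    best_by_k
  }
  best_by_k <- if (is.null(seed)) runner() else with_seed(seed, runner())
  bic_table <- vapply(best_by_k, `[[`, numeric(1), "bic")
  names(bic_table) <- names(best_by_k)
  sel <- best_by_k[[which.min(bic_table)]]
  o <- order(sel$means)
  structure(list(K = sel$K, weights = sel$weights[o], means = sel$means[o],
                 sds = sel$sds[o], loglik = sel$loglik, bic = sel$bic,
                 bic_table = bic_table, n = length(x),
                 loglik_trace = sel$loglik_trace),
            class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K=%d (BIC=%.1f, n=%d)\n", x$K, x$bic, x$n))
  for (j in seq_len(x$K)) {
    cat(sprintf("  component %d: weight=%.3f mean=%.3f sd=%.3f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Mixture density
#'
#' @param model A `ks_mixture`.
#' @param x Points at which to evaluate the density.
#' @return Numeric density values.
#' @export
mixture_density <- function(model, x) {
  d <- vapply(seq_len(model$K), function(j) {
    model$weights[j] * dnorm(x, model$means[j], model$sds[j])
  }, numeric(length(x)))
  rowSums(matrix(d, nrow = length(x)))
}

#' Plot a Ks histogram with the fitted mixture overlaid
#'
#' @param values Ks values used for the fit.
#' @param model A `ks_mixture`.
#' @param breaks Histogram breaks.
#' @param ... Passed to [graphics::hist()].
#' @export
plot_ks_mixture <- function(values, model, breaks = 50, ...) {
  x <- values[!is.na(values)]
  graphics::hist(x, breaks = breaks, freq = FALSE,
                 xlab = "Ks", main = "Ks distribution", ...)
  grid_x <- seq(min(x), max(x), length.out = 400)
  graphics::lines(grid_x, mixture_density(model, grid_x), lwd = 2)
  for (j in seq_len(model$K)) {
    graphics::lines(grid_x, model$weights[j] *
                      dnorm(grid_x, model$means[j], model$sds[j]), lty = 2)
  }
  invisible(model)
}
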