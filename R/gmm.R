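#' Fit a three-component Gaussian mixture to layer intensities
#'
#' Models one region's grey-value distribution as a mixture of three
#' univariate Gaussians, fitted by expectation-maximization.  This is the
#' intensity model used for maximum-likelihood pixel classification in
#' [segment_layer()].
#'
#' The fit is deterministic given `seed`: initial responsibilities come
#' from a seeded k-means partition of the sample (falling back to a
#' quantile split when the sample has too few distinct values), EM runs
#' to a relative log-likelihood tolerance of `1e-6` or 200 iterations,
#' and component variances are floored at `1e-8` to keep the likelihood
#' bounded.  Samples smaller than `min_n` are fitted with a single
#' Gaussian (flagged in the result); an all-constant sample yields a
#' degenerate single component at the variance floor.
#'
#' @param values numeric sample of grey values.
#' @param seed integer seed for the initialization.
#' @param k number of components (default 3).
#' @param min_n below this sample size a single-Gaussian fallback is
#'   used (default 30).
#' @param max_n if non-`NULL`, fit on a seeded subsample of at most this
#'   many values (density evaluation is unaffected).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param var_floor lower bound on component variances.
#' @return A `layer_gmm` object: components (`weights`, `means`,
#'   `vars`, sorted by mean), `loglik`, `iters`, `converged`, `n`, and
#'   flags `fallback_single` / `degenerate`.
#' @seealso [gmm_density()], [classify_region()]
#' @export
fit_layer_gmm <- function(values, seed = 1L, k = 3L, min_n = 30L,
                          max_n = NULL, tol = 1e-6, max_iter = 200L,
                          var_floor = 1e-8) {
  x <- as.numeric(values)
  n_total <- length(x)
  if (n_total < 2L) stop("need at least 2 values to fit an intensity model")
  set.seed(seed)
  if (!is.null(max_n) && n_total > max_n) {
    x <- x[sample.int(n_total, max_n)]
  }
  n <- length(x)
  fallback <- FALSE
  if (n < min_n) {
    k <- 1L
    fallback <- TRUE
  }
  if (stats::var(x) <= var_floor) {
    # constant sample: degenerate single component at the floor
    fit <- list(weights = 1, means = mean(x), vars = var_floor,
                k = 1L, loglik = sum(stats::dnorm(x, mean(x),
                                                  sqrt(var_floor),
                                                  log = TRUE)),
                iters = 0L, converged = TRUE, n = n_total,
                fallback_single = fallback, degenerate = TRUE)
    return(structure(fit, class = "layer_gmm"))
  }
  k <- min(k, length(unique(x)))
  if (k == 1L) {
    mu <- mean(x); v <- max(stats::var(x), var_floor)
    fit <- list(weights = 1, means = mu, vars = v, k = 1L,
                loglik = sum(stats::dnorm(x, mu, sqrt(v), log = TRUE)),
                iters = 0L, converged = TRUE, n = n_total,
                fallback_single = fallback, degenerate = FALSE)
    return(structure(fit, class = "layer_gmm"))
  }
  cl <- tryCatch(
    stats::kmeans(x, centers = k, nstart = 5L, iter.max = 100L)$cluster,
    error = function(e) {
      # quantile split fallback for near-degenerate samples
      cut(rank(x, ties.method = "first"), breaks = k, labels = FALSE)
    })
  w <- tabulate(cl, k) / n
  mu <- vapply(seq_len(k), function(j) mean(x[cl == j]), 0)
  v <- vapply(seq_len(k), function(j) {
    vj <- stats::var(x[cl == j])
    if (!is.finite(vj)) vj <- stats::var(x)
    max(vj, var_floor)
  }, 0)
  loglik <- -Inf
  iters <- 0L
  converged <- FALSE
  x2 <- x * x
  for (it in seq_len(max_iter)) {
    # E-step in log space for numerical safety
    logd <- (-0.5) * sweep(outer(x2, 1 / v) - 2 * outer(x, mu / v),
                           2L, -mu^2 / v, "-")
    logd <- sweep(logd, 2L, log(w) - 0.5 * log(2 * pi * v), "+")
    mx <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    # M-step (sufficient statistics form)
    nk <- pmax(colSums(resp), 1e-12)
    sx <- colSums(resp * x)
    sxx <- colSums(resp * x2)
    w <- nk / n
    mu <- sx / nk
    v <- pmax(sxx / nk - mu^2, var_floor)
    iters <- it
    if (is.finite(loglik) && abs(ll - loglik) <= tol * abs(ll)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  ord <- order(mu)
  fit <- list(weights = w[ord], means = mu[ord], vars = v[ord], k = k,
              loglik = loglik, iters = iters, converged = converged,
              n = n_total, fallback_single = fallback, degenerate = FALSE)
  structure(fit, class = "layer_gmm")
}

#' @export
print.layer_gmm <- function(x, ...) {
  cat(sprintf("<layer_gmm: %d component(s), n = %d, loglik = %.2f, %s>\n",
              x$k, x$n, x$loglik,
              if (x$converged) sprintf("converged in %d iter", x$iters)
              else "not converged"))
  tab <- rbind(weight = x$weights, mean = x$means, sd = sqrt(x$vars))
  colnames(tab) <- paste0("c", seq_len(x$k))
  print(round(tab, 4))
  invisible(x)
}

#' Mixture density of a fitted intensity model
#'
#' @param model a `layer_gmm` from [fit_layer_gmm()].
#' @param x numeric vector of grey values.
#' @param log if `TRUE`, return log-density.
#' @return Density of the mixture evaluated at `x`.
#' @export
gmm_density <- function(model, x, log = FALSE) {
  stopifnot(inherits(model, "layer_gmm"))
  x <- as.numeric(x)
  w <- model$weights; mu <- model$means; v <- model$vars
  logd <- (-0.5) * sweep(outer(x * x, 1 / v) - 2 * outer(x, mu / v),
                         2L, -mu^2 / v, "-")
  logd <- sweep(logd, 2L, log(w) - 0.5 * log(2 * pi * v), "+")
  if (any(w == 0)) logd[, w == 0] <- -Inf
  mx <- logd[cbind(seq_along(x), max.col(logd, ties.method = "first"))]
  out <- mx + log(rowSums(exp(logd - mx)))
  if (log) out else exp(out)
}
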