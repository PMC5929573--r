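# Univariate Gaussian mixture fitting by EM with BIC model selection.
# Two covariance families are considered, mirroring the 1-D reduction of the
# usual mixture-model families: "E" (equal variance) and "V" (per-component
# variance). The best (family, k) combination is chosen by BIC.

# k-means++ seeding for initial component means
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  if (k > 1L) {
    d2 <- (x - centers[1L])^2
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        centers[j] <- x[sample.int(length(x), 1L)]
      } else {
        centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
      }
      d2 <- pmin(d2, (x - centers[j])^2)
    }
  }
  centers
}

# one EM run (C++ inner loop); returns NULL if a component degenerates
em_run_1d <- function(x, k, model, init_means, tol, max_iter, var_floor) {
  fit <- em_gauss1d(x, init_means, equal_var = (model == "E"),
                    tol = tol, max_iter = max_iter, var_floor = var_floor)
  if (!fit$ok) return(NULL)
  n <- length(x)
  npar <- if (model == "V") 3L * k - 1L else 2L * k
  ord <- order(fit$means)
  logd <- vapply(seq_len(k), function(j) {
    dnorm(x, fit$means[j], sqrt(fit$variances[j]), log = TRUE) +
      log(fit$weights[j])
  }, numeric(n))
  logd <- matrix(logd, nrow = n)
  assignment <- max.col(logd[, ord, drop = FALSE])
  list(k = k, model = model, weights = fit$weights[ord],
       means = fit$means[ord], variances = fit$variances[ord],
       loglik = fit$loglik, bic = 2 * fit$loglik - npar * log(n),
       assignment = assignment, loglik_trace = fit$loglik_trace,
       iterations = fit$iterations)
}

#' Fit a univariate Gaussian mixture by EM with BIC selection
#'
#' Runs EM from multiple k-means++ initializations for every candidate number
#' of components and both variance families (equal and per-component), and
#' returns the fit with the highest BIC (on the \code{2*loglik - npar*log(n)}
#' scale where higher is better). Deterministic for a fixed \code{seed}.
#'
#' @param x Numeric values to cluster (already on the scale to be modelled).
#' @param k_range Candidate component counts (default 1:7).
#' @param n_restarts EM restarts per candidate (default 10).
#' @param tol Convergence tolerance on the log-likelihood increment
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per run (default 2000).
#' @param seed Integer seed for the restarts; NULL uses the current RNG.
#' @return A list of class \code{mixture_fit}: k, model, weights, means,
#'   variances (components sorted by mean), loglik, bic, assignment (MAP
#'   component per observation), loglik_trace of the winning run, and
#'   bic_table over all candidates.
#' @export
fit_gmm1d <- function(x, k_range = 1:7, n_restarts = 10L, tol = 1e-8,
                      max_iter = 2000L, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 10L) stopf("need at least 10 values, got %d", length(x))
  if (anyNA(x) || any(!is.finite(x))) stopf("values must be finite")
  k_range <- k_range[k_range >= 1 & k_range < length(x)]
  var_floor <- max(1e-8, var(x) * 1e-8)
  if (var(x) == 0) {  # degenerate: all values identical
    fit <- list(k = 1L, model = "E", weights = 1, means = x[1L],
                variances = var_floor, loglik = NA_real_, bic = NA_real_,
                assignment = rep(1L, length(x)), loglik_trace = numeric(0),
                bic_table = data.frame())
    class(fit) <- "mixture_fit"
    return(fit)
  }
  with_seed(seed, {
    best <- NULL
    rows <- list()
    for (model in c("E", "V")) {
      for (k in k_range) {
        best_k <- NULL
        for (r in seq_len(n_restarts)) {
          init <- if (k == 1L) mean(x) else kmeanspp_centers(x, k)
          fit <- em_run_1d(x, k, model, init, tol, max_iter, var_floor)
          if (is.null(fit)) next
          if (is.null(best_k) || fit$loglik > best_k$loglik) best_k <- fit
        }
        if (is.null(best_k)) next
        rows[[length(rows) + 1L]] <-
          data.frame(model = model, k = k, loglik = best_k$loglik,
                     bic = best_k$bic)
        if (is.null(best) || best_k$bic > best$bic) best <- best_k
      }
    }
    if (is.null(best)) {
      stopf("EM failed to produce a non-degenerate fit for any candidate k")
    }
    # a fit that hits the iteration cap is accepted when the remaining
    # log-likelihood increment is immaterial for model selection
    if (best$iterations >= max_iter &&
        length(best$loglik_trace) >= 2L &&
        diff(utils::tail(best$loglik_trace, 2L)) > 1e-4) {
      stopf(paste0("EM did not converge in %d iterations ",
                   "(last loglik increment %.3g); increase max_iter"),
            max_iter, diff(utils::tail(best$loglik_trace, 2L)))
    }
    best$bic_table <- do.call(rbind, rows)
    class(best) <- "mixture_fit"
    best
  })
}

#' Fit a Gaussian mixture to log10-transformed GEI scores
#'
#' Convenience wrapper around \code{\link{fit_gmm1d}} that takes raw GEI
#' scores (which are strictly positive thanks to the pseudocount floor) and
#' models their base-10 logarithms.
#'
#' @param gei Positive GEI scores.
#' @param ... Passed to \code{\link{fit_gmm1d}}.
#' @return A \code{mixture_fit} (means/variances on the log10 scale).
#' @export
fit_log_gmm <- function(gei, ...) {
  if (any(gei <= 0)) stopf("GEI scores must be positive (pseudocount floor)")
  fit_gmm1d(log10(gei), ...)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d (model %s), loglik = %.3f, BIC = %.3f\n",
              x$k, x$model, x$loglik, x$bic))
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  invisible(x)
}
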