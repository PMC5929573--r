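#' Affinity propagation clustering of univariate values
#'
#' Standard affinity propagation (responsibility/availability message
#' passing) with similarity \code{-(x_i - x_j)^2} and the preference on the
#' diagonal. Because the values are one-dimensional, clusters are made
#' contiguous after convergence: exemplar values are sorted and every point
#' is assigned to the interval around its nearest exemplar, which merges any
#' stray non-contiguous assignments.
#'
#' @param values Numeric vector (>= 2 values).
#' @param preference Shared exemplar preference; default is the median
#'   off-diagonal similarity.
#' @param damping Message damping factor in [0.5, 1), default 0.9.
#' @param max_iter Maximum message-passing iterations (default 1000).
#' @param conv_iter Iterations the exemplar set must stay unchanged to
#'   declare convergence (default 100).
#' @return List of class \code{ap_fit}: labels (1..n_clusters, ordered by
#'   exemplar value), exemplars (indices into \code{values}),
#'   exemplar_values, iterations, n_clusters.
#' @export
refine_affinity_propagation <- function(values, preference = NULL,
                                        damping = 0.9, max_iter = 1000L,
                                        conv_iter = 100L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stopf("affinity propagation needs at least 2 values")
  if (damping < 0.5 || damping >= 1) stopf("damping must be in [0.5, 1)")
  if (all(x == x[1L])) {  # identical points: one cluster, first as exemplar
    return(structure(list(labels = rep(1L, n), exemplars = 1L,
                          exemplar_values = x[1L], iterations = 0L,
                          n_clusters = 1L), class = "ap_fit"))
  }
  S <- -outer(x, x, "-")^2
  if (is.null(preference)) {
    preference <- median(S[upper.tri(S) | lower.tri(S)])
  }
  diag(S) <- preference
  res <- ap_message_passing(S, damping, as.integer(max_iter),
                            as.integer(conv_iter))
  if (!res$converged) {
    stopf(paste0("affinity propagation did not converge in %d iterations; ",
                 "try a higher damping factor"), max_iter)
  }
  ex <- sort(unique(res$exemplars))
  exv <- x[ex]
  ord <- order(exv)
  ex <- ex[ord]
  exv <- exv[ord]
  # 1-D contiguity: assign each point to the nearest exemplar value
  if (length(ex) == 1L) {
    labels <- rep(1L, n)
  } else {
    mid <- (exv[-1L] + exv[-length(exv)]) / 2
    labels <- findInterval(x, mid) + 1L
  }
  structure(list(labels = labels, exemplars = ex, exemplar_values = exv,
                 iterations = res$iterations,
                 n_clusters = length(unique(labels))),
            class = "ap_fit")
}
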