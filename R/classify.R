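# Fitness classification: zero-insertion essentials, mixture clustering of
# log GEI refined by affinity propagation, ordinal mapping of clusters to
# fitness groups I-V, and differential-fitness calls between conditions.

fitness_groups <- c("I", "II", "III", "IV", "V")

#' Flag genes with no observed insertions
#'
#' Genes with zero reads in both replicates (raw counts, before normalization
#' and pseudocounts) are classified as essential (Group I) outright; all other
#' genes are passed on to mixture clustering.
#'
#' @param profiles A \code{gei_profile} data.frame for one condition.
#' @return Logical vector: TRUE where the gene is auto-called essential.
#' @export
call_zero_insertion <- function(profiles) {
  profiles$raw_rep1 == 0 & profiles$raw_rep2 == 0
}

# merge clusters (given by per-point labels and the values) until at most
# `target` remain, always fusing the adjacent pair with the smallest gap
# between cluster means; returns new labels ordered by mean
merge_to_at_most <- function(values, labels, target) {
  repeat {
    means <- tapply(values, labels, mean)
    ord <- order(means)
    labels <- match(labels, names(means)[ord])  # relabel 1..k by mean order
    means <- sort(as.numeric(means))
    k <- length(means)
    if (k <= target) return(list(labels = labels, means = means))
    gaps <- diff(means)
    j <- which.min(gaps)  # fuse clusters j and j+1
    labels[labels == j + 1L] <- j
    labels[labels > j + 1L] <- labels[labels > j + 1L] - 1L
  }
}

#' Map ordered clusters of log GEI values to fitness groups I-V
#'
#' Clusters are ordered by mean GEI. The lowest cluster becomes Group I
#' (essential; merged with the zero-insertion genes), followed by II, III and
#' IV. A fifth, top cluster is labelled V (growth improvement on disruption)
#' only when its mean exceeds the next cluster's mean by \code{v_margin}
#' log10 units; otherwise the two top clusters are fused, matching datasets
#' in which no growth-improvement group is distinguishable. If more clusters
#' than groups are found, adjacent clusters with the smallest mean separation
#' are fused first; if fewer than four remain, middle groups are dropped
#' (III first, then II), so group severity stays a monotone step function of
#' GEI.
#'
#' @param log_gei log10 GEI per gene.
#' @param cluster_labels Integer cluster label per gene.
#' @param zero_insertion Logical per gene; TRUE forces Group I with basis
#'   "zero_insertion".
#' @param v_margin Minimum log10 separation of a growth-improvement cluster
#'   from the cluster below it (default 0.25).
#' @return Data.frame: group (factor I-V), basis ("zero_insertion" or
#'   "cluster").
#' @export
assign_groups <- function(log_gei, cluster_labels, zero_insertion = NULL,
                          v_margin = 0.25) {
  n <- length(log_gei)
  if (is.null(zero_insertion)) zero_insertion <- rep(FALSE, n)
  m <- merge_to_at_most(log_gei, cluster_labels, 5L)
  labels <- m$labels
  means <- m$means
  k <- length(means)
  # enforce 1-D contiguity: clusters become intervals of the sorted values
  # with their sizes preserved, so group severity is monotone in GEI
  ord <- order(log_gei)
  labels[ord] <- rep.int(seq_len(k), tabulate(labels, k))
  has_v <- k == 5L && (means[5L] - means[4L]) >= v_margin
  if (k == 5L && !has_v) {
    labels[labels == 5L] <- 4L
    means <- c(means[1:3], mean(log_gei[labels == 4L]))
    k <- 4L
  }
  base_k <- if (has_v) k - 1L else k
  # groups I..IV for the non-V clusters, dropping middles when fewer than 4
  base_groups <- switch(as.character(base_k),
                        "1" = "IV",
                        "2" = c("I", "IV"),
                        "3" = c("I", "II", "IV"),
                        "4" = c("I", "II", "III", "IV"))
  group_of <- c(base_groups, if (has_v) "V")
  group <- group_of[labels]
  basis <- rep("cluster", n)
  group[zero_insertion] <- "I"
  basis[zero_insertion] <- "zero_insertion"
  data.frame(group = factor(group, levels = fitness_groups),
             basis = basis, stringsAsFactors = FALSE)
}

#' Classify genes of one condition into fitness groups I-V
#'
#' The full classification procedure: genes with no insertions in either
#' replicate are called essential outright; log10 GEI scores of all genes are
#' clustered with a BIC-selected Gaussian mixture; each mixture cluster is
#' refined by affinity propagation and split only where the refinement finds
#' exemplars separated by more than \code{split_tol} log10 units; the
#' resulting clusters are mapped to groups I-V by mean GEI.
#'
#' @param profiles A \code{gei_profile} data.frame for a single condition.
#' @param k_range Candidate mixture sizes (default 1:7).
#' @param v_margin See \code{\link{assign_groups}}.
#' @param refine Run affinity-propagation refinement (default TRUE).
#' @param split_tol Minimum exemplar separation (log10 GEI) for an AP split
#'   within a mixture cluster (default 0.5).
#' @param ap_damping Damping for affinity propagation (default 0.9).
#' @param seed Seed for the mixture restarts.
#' @return Data.frame of class \code{fitness_call}: gene_id, condition,
#'   group, basis, gei.
#' @export
classify_fitness <- function(profiles, k_range = 1:7, v_margin = 0.25,
                             refine = TRUE, split_tol = 0.5,
                             ap_damping = 0.9, seed = 1L) {
  cond <- unique(profiles$condition)
  if (length(cond) != 1L) {
    stopf("classify_fitness expects one condition, got: %s",
          paste(cond, collapse = ", "))
  }
  zero <- call_zero_insertion(profiles)
  lg <- log10(profiles$gei)
  fit <- fit_log_gmm(profiles$gei, k_range = k_range, seed = seed)
  labels <- fit$assignment
  if (refine) {
    labels <- refine_within_clusters(lg, labels, split_tol, ap_damping)
  }
  grp <- assign_groups(lg, labels, zero_insertion = zero, v_margin = v_margin)
  out <- data.frame(gene_id = profiles$gene_id, condition = cond,
                    group = grp$group, basis = grp$basis, gei = profiles$gei,
                    stringsAsFactors = FALSE)
  attr(out, "mixture_fit") <- fit
  class(out) <- c("fitness_call", "data.frame")
  out
}

# run affinity propagation inside each mixture cluster; split a cluster only
# if AP finds >1 exemplar separated by more than split_tol
refine_within_clusters <- function(values, labels, split_tol, damping) {
  out <- integer(length(values))
  nxt <- 1L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 3L) {
      out[idx] <- nxt
      nxt <- nxt + 1L
      next
    }
    # refinement is a polish step: an oscillating message-passing run on one
    # cluster leaves that cluster unsplit instead of aborting the analysis
    ap <- tryCatch(refine_affinity_propagation(values[idx],
                                               damping = damping),
                   error = function(e) NULL)
    if (is.null(ap)) {
      out[idx] <- nxt
      nxt <- nxt + 1L
      next
    }
    exv <- ap$exemplar_values
    if (length(exv) > 1L && max(diff(sort(exv))) > split_tol) {
      # keep only the splits at wide exemplar gaps
      gaps <- diff(sort(exv))
      cuts <- which(gaps > split_tol)
      bounds <- (sort(exv)[cuts] + sort(exv)[cuts + 1L]) / 2
      sub <- findInterval(values[idx], bounds) + 1L
      out[idx] <- nxt + sub - 1L
      nxt <- nxt + max(sub)
    } else {
      out[idx] <- nxt
      nxt <- nxt + 1L
    }
  }
  out
}

#' Call differential fitness between two conditions
#'
#' Computes per-gene \code{log10(geiA / geiB)} over the matched gene set and
#' clusters the fold changes with a BIC-selected Gaussian mixture. Clusters
#' whose mean absolute fold change lies inside the equal zone are called
#' "equal"; clusters beyond it are direction-specific calls. A positive fold
#' change (higher GEI, i.e. more insertions tolerated, in condition A) means
#' the gene is more important for growth in condition B.
#'
#' @param profiles_a,profiles_b \code{gei_profile} data.frames of the two
#'   conditions covering the same genes.
#' @param equal_zone Clusters with |mean log10 FC| below this are "equal"
#'   (default 0.3).
#' @param k_range Candidate mixture sizes (default 1:5).
#' @param seed Seed for the mixture restarts.
#' @return Data.frame of class \code{differential_call}: gene_id,
#'   condition_pair, log10_fold_change, call (higher_in_A / equal /
#'   higher_in_B).
#' @export
call_differential <- function(profiles_a, profiles_b, equal_zone = 0.3,
                              k_range = 1:5, seed = 1L) {
  missing_b <- setdiff(profiles_a$gene_id, profiles_b$gene_id)
  missing_a <- setdiff(profiles_b$gene_id, profiles_a$gene_id)
  if (length(missing_a) || length(missing_b)) {
    stopf("gene sets differ between conditions; missing: %s",
          paste(head(c(missing_a, missing_b), 5L), collapse = ", "))
  }
  b <- profiles_b[match(profiles_a$gene_id, profiles_b$gene_id), ]
  lfc <- log10(profiles_a$gei / b$gei)
  fit <- fit_gmm1d(lfc, k_range = k_range, seed = seed)
  cluster_call <- ifelse(abs(fit$means) < equal_zone, "equal",
                         ifelse(fit$means > 0, "higher_in_A", "higher_in_B"))
  pair <- paste(unique(profiles_a$condition), unique(b$condition), sep = "_vs_")
  out <- data.frame(gene_id = profiles_a$gene_id, condition_pair = pair,
                    log10_fold_change = lfc,
                    call = cluster_call[fit$assignment],
                    stringsAsFactors = FALSE)
  attr(out, "mixture_fit") <- fit
  class(out) <- c("differential_call", "data.frame")
  out
}
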