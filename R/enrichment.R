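#' Functional-category enrichment of a gene set
#'
#' For every category, membership of the gene set versus the rest of the
#' background is tested with a two-sided Fisher exact test on the 2x2 table,
#' and the fold enrichment is the in-set category fraction divided by the
#' background category fraction. P-values are Bonferroni-corrected for the
#' family of 18 category tests.
#'
#' @param gene_set Character vector of gene ids (must be a subset of the
#'   background).
#' @param background Data.frame with columns \code{gene_id} and
#'   \code{category} covering every gene, or a \code{tn_annotation}.
#' @param categories Category vocabulary to test (default the fixed
#'   18-category set).
#' @return Data.frame of class \code{enrichment_result}: category, set_count,
#'   background_count, fold_enrichment, direction (over/under), p_value,
#'   p_bonferroni.
#' @export
fisher_enrichment <- function(gene_set, background,
                              categories = functional_categories()) {
  if (inherits(background, "tn_annotation")) background <- background$genes
  if (length(gene_set) == 0) stopf("gene set is empty")
  bad <- setdiff(gene_set, background$gene_id)
  if (length(bad)) {
    stopf("gene set contains ids not in the background: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  if (anyNA(background$category)) stopf("every background gene needs a category")
  n_tests <- length(categories)
  in_set <- background$gene_id %in% gene_set
  n_set <- sum(in_set)
  n_bg <- nrow(background)
  rows <- lapply(categories, function(cat) {
    in_cat <- background$category == cat
    a <- sum(in_set & in_cat)
    k_bg <- sum(in_cat)
    tab <- matrix(c(a, n_set - a, k_bg - a, n_bg - n_set - (k_bg - a)), 2L)
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    bg_frac <- k_bg / n_bg
    set_frac <- a / n_set
    fold <- if (bg_frac > 0) set_frac / bg_frac else NA_real_
    data.frame(category = cat, set_count = a, background_count = k_bg,
               fold_enrichment = fold,
               direction = if (!is.na(fold) && fold >= 1) "over" else "under",
               p_value = p, p_bonferroni = min(1, p * n_tests),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Two-sided Fisher exact p-value by hypergeometric enumeration
#'
#' Independent oracle for the Fisher test: enumerates all tables with the
#' observed margins and sums the hypergeometric probabilities of every table
#' at most as probable as the observed one (with the conventional 1e-7
#' relative slack).
#'
#' @param a,b,c,d Cell counts of the 2x2 table (rows: in set / not, columns:
#'   in category / not).
#' @return The two-sided p-value.
#' @export
fisher_p_enumerated <- function(a, b, c, d) {
  m <- a + c          # column-1 margin
  n <- b + d
  k <- a + b          # row-1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
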