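# Single/double gene and reaction deletion screens, in-silico replicon
# removal, and synthetic-negative epistasis classification.

DEFECT_GRRATIO <- 0.9         # growth defect when grRatio < 0.9
EPISTASIS_FACTOR <- 0.9       # synthetic negative when obs < 0.9 * expected

#' Constrain a model by deleting genes
#'
#' Every reaction whose GPR rule evaluates to inactive under the deletion has
#' its flux bounds fixed to zero; all other reactions are untouched.
#'
#' @param model A \code{metabolic_model}.
#' @param genes Character vector of gene ids to delete.
#' @return The constrained model.
#' @export
delete_genes <- function(model, genes) {
  unknown <- setdiff(genes, model$genes$gene_id)
  if (length(unknown)) {
    stopf("unknown gene '%s'", unknown[1L])
  }
  if (length(genes) == 0) return(model)
  for (j in seq_along(model$rxns)) {
    if (!nzchar(model$gpr[j])) next
    if (!evaluate_gpr(model$gpr[j], genes)) {
      model$lb[j] <- 0
      model$ub[j] <- 0
    }
  }
  model
}

grratio_status <- function(grRatio) {
  ifelse(grRatio < ZERO_GROWTH_TOL, "lethal",
         ifelse(grRatio < DEFECT_GRRATIO, "defect", "no_effect"))
}

mutant_growth <- function(model, method, reference) {
  sol <- if (method == "moma") moma(model, reference = reference) else
    fba(model)
  g <- sol$objective_value
  if (!is.finite(g) || g < ZERO_GROWTH_TOL) 0 else g
}

#' Single gene deletion screen
#'
#' Deletes each gene in turn, recomputes growth with FBA or MOMA, and reports
#' the growth rate ratio grRatio = mutant growth / wild-type growth. A gene
#' is a growth defect when grRatio < 0.9 and lethal when growth is below the
#' zero-growth tolerance.
#'
#' @param model A \code{metabolic_model} with wild-type growth > 0.
#' @param genes Genes to screen (default: all model genes).
#' @param method "fba" or "moma".
#' @return Data.frame of class \code{deletion_result}: gene_id, grRatio,
#'   status (no_effect/defect/lethal).
#' @export
single_gene_deletion <- function(model, genes = model$genes$gene_id,
                                 method = c("fba", "moma")) {
  method <- match.arg(method)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value < ZERO_GROWTH_TOL) {
    stopf("wild-type model does not grow; cannot compute grRatio")
  }
  reference <- if (method == "moma") fba_reference(model) else NULL
  gr <- vapply(genes, function(g) {
    mutant_growth(delete_genes(model, g), method, reference) /
      wt$objective_value
  }, numeric(1))
  gr <- pmin(pmax(gr, 0), 1 + 1e-9)
  out <- data.frame(gene_id = genes, grRatio = unname(gr),
                    status = grratio_status(unname(gr)),
                    stringsAsFactors = FALSE)
  class(out) <- c("deletion_result", "data.frame")
  out
}

#' Single reaction deletion screen
#'
#' As \code{\link{single_gene_deletion}}, but each reaction's bounds are
#' zeroed directly, bypassing GPR logic.
#'
#' @param model A \code{metabolic_model}.
#' @param reactions Reactions to screen (default: all).
#' @param method "fba" or "moma".
#' @return Data.frame of class \code{deletion_result}: reaction_id, grRatio,
#'   status.
#' @export
single_reaction_deletion <- function(model, reactions = model$rxns,
                                     method = c("fba", "moma")) {
  method <- match.arg(method)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value < ZERO_GROWTH_TOL) {
    stopf("wild-type model does not grow; cannot compute grRatio")
  }
  reference <- if (method == "moma") fba_reference(model) else NULL
  gr <- vapply(reactions, function(r) {
    m <- model
    j <- match(r, model$rxns)
    if (is.na(j)) stopf("unknown reaction '%s'", r)
    m$lb[j] <- 0
    m$ub[j] <- 0
    mutant_growth(m, method, reference) / wt$objective_value
  }, numeric(1))
  gr <- pmin(pmax(gr, 0), 1 + 1e-9)
  out <- data.frame(reaction_id = reactions, grRatio = unname(gr),
                    status = grratio_status(unname(gr)),
                    stringsAsFactors = FALSE)
  class(out) <- c("deletion_result", "data.frame")
  out
}

replicon_of <- function(model) {
  setNames(model$genes$replicon, model$genes$gene_id)
}

pair_class_of <- function(model, ga, gb) {
  rep_of <- replicon_of(model)
  a_chr <- rep_of[ga] == "chromosome"
  b_chr <- rep_of[gb] == "chromosome"
  ifelse(a_chr & b_chr, "chr-chr",
         ifelse(!a_chr & !b_chr, "psym-psym", "chr-psym"))
}

#' Double gene deletion (epistasis) screen
#'
#' For every gene pair, the observed grRatio of the double mutant is compared
#' with the expected grRatio under independence (the product of the two
#' single-mutant grRatios); a pair is a synthetic negative interaction when
#' the observed value is below 90 percent of the expected one. Pairs are
#' enumerated in sorted id order and each pair is classified by the replicons
#' its genes reside on.
#'
#' @param model A \code{metabolic_model}.
#' @param pairs Two-column matrix/data.frame of gene pairs; default all
#'   unordered pairs of model genes.
#' @param method "fba" or "moma".
#' @param singles Optional precomputed \code{\link{single_gene_deletion}}
#'   result (computed if NULL).
#' @return Data.frame of class \code{epistasis_record}: gene_a, gene_b,
#'   grRatio_observed, grRatio_expected, synthetic_negative, pair_class.
#' @export
double_gene_deletion <- function(model, pairs = NULL,
                                 method = c("fba", "moma"), singles = NULL) {
  method <- match.arg(method)
  if (is.null(pairs)) {
    g <- sort(model$genes$gene_id)
    pairs <- t(utils::combn(g, 2L))
  }
  pairs <- as.matrix(pairs)
  # deterministic orientation and order
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, 2:1]
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  need <- unique(as.vector(pairs))
  if (is.null(singles)) {
    singles <- single_gene_deletion(model, genes = need, method = method)
  }
  sgr <- setNames(singles$grRatio, singles$gene_id)
  missing <- setdiff(need, names(sgr))
  if (length(missing)) {
    stopf("no single-deletion grRatio for gene '%s'", missing[1L])
  }
  wt <- fba(model)
  reference <- if (method == "moma") fba_reference(model) else NULL
  obs <- vapply(seq_len(nrow(pairs)), function(i) {
    mutant_growth(delete_genes(model, pairs[i, ]), method, reference) /
      wt$objective_value
  }, numeric(1))
  obs <- pmin(pmax(obs, 0), 1 + 1e-9)
  expected <- unname(sgr[pairs[, 1L]] * sgr[pairs[, 2L]])
  out <- data.frame(
    gene_a = pairs[, 1L], gene_b = pairs[, 2L],
    grRatio_observed = obs, grRatio_expected = expected,
    synthetic_negative = obs < EPISTASIS_FACTOR * expected - 1e-9,
    pair_class = pair_class_of(model, pairs[, 1L], pairs[, 2L]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("epistasis_record", "data.frame")
  out
}

#' Remove a replicon from a model in silico
#'
#' All genes carrying the replicon tag are deleted (reactions whose GPR
#' becomes unsatisfiable are closed), the genes are dropped from the gene
#' table, and the remaining GPR rules are simplified so the reduced model
#' validates and can be written out. Whether the reduced model still grows is
#' left to the caller to interrogate.
#'
#' @param model A \code{metabolic_model}.
#' @param replicon Replicon tag (e.g. "pSym").
#' @return The reduced \code{metabolic_model}.
#' @export
remove_replicon <- function(model, replicon) {
  doomed <- model$genes$gene_id[model$genes$replicon == replicon]
  if (length(doomed) == 0) return(model)
  gpr <- model$gpr
  lb <- model$lb
  ub <- model$ub
  for (j in seq_along(model$rxns)) {
    if (!nzchar(gpr[j])) next
    simp <- simplify_gpr(gpr[j], doomed)
    if (!simp$active) {
      lb[j] <- 0
      ub[j] <- 0
    }
    gpr[j] <- simp$rule
  }
  metabolic_model(
    mets = model$mets, rxns = model$rxns, S = model$S, lb = lb, ub = ub,
    gpr = gpr, genes = model$genes[model$genes$replicon != replicon, ,
                                   drop = FALSE],
    objective = model$objective,
    id = sprintf("%s_minus_%s", model$id, replicon)
  )
}

#' Compare single-deletion screens across genomic backgrounds
#'
#' Joins per-gene grRatios from screens of the full and the replicon-reduced
#' model (each normalized to its own wild-type growth) and flags genes whose
#' deletion is more severe in one background by more than \code{margin}.
#' Genes that become lethal specifically in the reduced background are
#' reported as such.
#'
#' @param full,reduced \code{deletion_result} data.frames over the same gene
#'   set.
#' @param margin grRatio difference below which backgrounds are called equal
#'   (absorbs solver noise; default 0.01).
#' @return Data.frame: gene_id, grRatio_full, grRatio_reduced, call
#'   (more_severe_without / more_severe_with / unchanged), lethal_specific.
#' @export
compare_backgrounds <- function(full, reduced, margin = 0.01) {
  if (!setequal(full$gene_id, reduced$gene_id)) {
    stopf("gene sets differ between screens; e.g. %s",
          paste(head(c(setdiff(full$gene_id, reduced$gene_id),
                       setdiff(reduced$gene_id, full$gene_id)), 5L),
                collapse = ", "))
  }
  r <- reduced[match(full$gene_id, reduced$gene_id), ]
  delta <- r$grRatio - full$grRatio
  call <- ifelse(delta < -margin, "more_severe_without",
                 ifelse(delta > margin, "more_severe_with", "unchanged"))
  data.frame(gene_id = full$gene_id,
             grRatio_full = full$grRatio,
             grRatio_reduced = r$grRatio,
             call = call,
             lethal_specific = r$status == "lethal" &
               full$status != "lethal",
             stringsAsFactors = FALSE)
}

#' Overlap between two gene sets (report utility)
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return Named counts: a_only, b_only, both.
#' @export
set_overlap <- function(set_a, set_b) {
  c(a_only = length(setdiff(set_a, set_b)),
    b_only = length(setdiff(set_b, set_a)),
    both = length(intersect(set_a, set_b)))
}
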