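#' Construct a constraint-based metabolic model
#'
#' A stoichiometric model: metabolites, reactions with flux bounds
#' (mmol/gDW/h convention), gene-protein-reaction (GPR) boolean rules, a gene
#' table with replicon tags, and a biomass objective reaction.
#'
#' @param mets Character vector of metabolite ids.
#' @param rxns Character vector of reaction ids.
#' @param S Stoichiometric matrix (metabolites x reactions); coerced to a
#'   sparse \code{Matrix}.
#' @param lb,ub Numeric lower/upper flux bounds per reaction (finite).
#' @param gpr Character GPR rule per reaction ("" = no gene requirement).
#' @param genes Data.frame with columns \code{gene_id} and \code{replicon}.
#' @param objective Reaction id of the biomass objective.
#' @param id Model identifier.
#' @return An object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(mets, rxns, S, lb, ub, gpr, genes, objective,
                            id = "model") {
  S <- Matrix(S, sparse = TRUE)
  if (nrow(S) != length(mets) || ncol(S) != length(rxns)) {
    stopf("S must be %d x %d, got %d x %d",
          length(mets), length(rxns), nrow(S), ncol(S))
  }
  dimnames(S) <- list(mets, rxns)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != length(rxns) || length(ub) != length(rxns)) {
    stopf("bounds must have one entry per reaction")
  }
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stopf("flux bounds must be finite (use +/-1000 for unconstrained)")
  }
  if (any(lb > ub)) {
    stopf("lower bound exceeds upper bound for reaction '%s'",
          rxns[which(lb > ub)[1L]])
  }
  gpr <- as.character(gpr)
  if (length(gpr) != length(rxns)) stopf("one GPR rule per reaction required")
  if (!objective %in% rxns) stopf("objective reaction '%s' not in model",
                                  objective)
  used <- unique(unlist(lapply(gpr[nzchar(gpr)], gpr_genes)))
  unknown <- setdiff(used, genes$gene_id)
  if (length(unknown)) {
    stopf("GPR rules reference genes missing from the gene table: %s",
          paste(head(unknown, 5L), collapse = ", "))
  }
  structure(list(id = id, mets = mets, rxns = rxns, S = S, lb = lb, ub = ub,
                 gpr = gpr, genes = genes, objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions, %d genes; objective %s\n",
              x$id, length(x$mets), length(x$rxns), nrow(x$genes),
              x$objective))
  invisible(x)
}

# --- GPR boolean rules -------------------------------------------------------

# tokenize a GPR rule; returns data.frame(token, pos)
gpr_tokenize <- function(rule) {
  tokens <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(token = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(rule, i, n),
                    regexpr("^[^()[:space:]]+", substr(rule, i, n)))
    tokens[[length(tokens) + 1L]] <- list(token = m, pos = i)
    i <- i + nchar(m)
  }
  tokens
}

# recursive-descent parse of "expr := term (or term)*; term := factor (and
# factor)*; factor := gene | ( expr )"; AND/OR case-insensitive
parse_gpr <- function(rule) {
  tokens <- gpr_tokenize(rule)
  idx <- 1L
  peek <- function() if (idx <= length(tokens)) tokens[[idx]] else NULL
  advance <- function() { t <- tokens[[idx]]; idx <<- idx + 1L; t }
  fail <- function(what, tok) {
    stopf("GPR parse error at position %d of '%s': %s",
          if (is.null(tok)) nchar(rule) + 1L else tok$pos, rule, what)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.null(peek()) && tolower(peek()$token) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.null(peek()) && tolower(peek()$token) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) fail("unexpected end of rule", tok)
    if (tok$token == "(") {
      advance()
      e <- parse_expr()
      close_tok <- peek()
      if (is.null(close_tok) || close_tok$token != ")") {
        fail("expected ')'", close_tok)
      }
      advance()
      return(e)
    }
    if (tok$token == ")" || tolower(tok$token) %in% c("and", "or")) {
      fail(sprintf("unexpected '%s'", tok$token), tok)
    }
    advance()
    tok$token
  }
  if (length(tokens) == 0) return(NULL)
  e <- parse_expr()
  if (idx <= length(tokens)) fail(sprintf("unexpected '%s'",
                                          tokens[[idx]]$token), tokens[[idx]])
  e
}

# genes referenced by a rule
gpr_genes <- function(rule) {
  ast <- if (is.character(rule)) parse_gpr(rule) else rule
  collect <- function(node) {
    if (is.null(node)) return(character())
    if (is.character(node)) return(node)
    unlist(lapply(node$args, collect))
  }
  unique(collect(ast))
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' Standard boolean semantics: a present gene is TRUE, a deleted gene FALSE;
#' AND/OR (case-insensitive) with parentheses; an empty rule means the
#' reaction needs no gene and is always active.
#'
#' @param rule GPR rule string (or a parsed rule).
#' @param deleted_genes Character vector of deleted gene ids.
#' @return TRUE if the reaction remains active.
#' @export
evaluate_gpr <- function(rule, deleted_genes = character()) {
  ast <- if (is.character(rule)) parse_gpr(rule) else rule
  if (is.null(ast)) return(TRUE)
  eval_node <- function(node) {
    if (is.character(node)) return(!(node %in% deleted_genes))
    vals <- vapply(node$args, eval_node, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  eval_node(ast)
}

# simplify a rule under deletions: deleted genes become FALSE and the rule is
# reduced; returns list(rule = string or "", active = logical)
simplify_gpr <- function(rule, deleted_genes) {
  ast <- parse_gpr(rule)
  simp <- function(node) {
    if (is.null(node)) return(TRUE)
    if (is.character(node)) {
      return(if (node %in% deleted_genes) FALSE else node)
    }
    args <- lapply(node$args, simp)
    if (node$op == "and") {
      if (any(vapply(args, isFALSE, logical(1)))) return(FALSE)
      args <- args[!vapply(args, isTRUE, logical(1))]
      if (length(args) == 0) return(TRUE)
    } else {
      if (any(vapply(args, isTRUE, logical(1)))) return(TRUE)
      args <- args[!vapply(args, isFALSE, logical(1))]
      if (length(args) == 0) return(FALSE)
    }
    if (length(args) == 1L) args[[1L]] else list(op = node$op, args = args)
  }
  res <- simp(ast)
  if (isFALSE(res)) return(list(rule = "", active = FALSE))
  if (isTRUE(res)) return(list(rule = "", active = TRUE))
  list(rule = deparse_gpr(res), active = TRUE)
}

deparse_gpr <- function(node) {
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a) && a$op != node$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}
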