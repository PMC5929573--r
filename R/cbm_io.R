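# Model IO: SBML Level 3 with the fbc extension (the interchange format of
# constraint-based modeling), plus a simple tabular dialect for hand-written
# fixtures. The SBML support covers the subset needed for flux models:
# species, reactions with stoichiometry, fbc flux bounds as parameters,
# fbc gene products (replicon tag in fbc:name), nested gene-product
# associations, and an active biomass objective.

sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

#' Write a metabolic model as SBML Level 3 + fbc
#'
#' @param model A \code{metabolic_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = sbml_ns[["sbml"]], "xmlns:fbc" = sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  species <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$mets) {
    xml2::xml_add_child(species, "species", id = m, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  params <- xml2::xml_add_child(mdl, "listOfParameters")
  for (j in seq_along(model$rxns)) {
    xml2::xml_add_child(params, "parameter",
                        id = sprintf("lb_%s", model$rxns[j]),
                        value = format(model$lb[j], digits = 17),
                        constant = "true")
    xml2::xml_add_child(params, "parameter",
                        id = sprintf("ub_%s", model$rxns[j]),
                        value = format(model$ub[j], digits = 17),
                        constant = "true")
  }
  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  S <- as(model$S, "TsparseMatrix")
  for (j in seq_along(model$rxns)) {
    rid <- model$rxns[j]
    rx <- xml2::xml_add_child(
      rxns, "reaction", id = rid, fast = "false",
      reversible = if (model$lb[j] < 0) "true" else "false",
      "fbc:lowerFluxBound" = sprintf("lb_%s", rid),
      "fbc:upperFluxBound" = sprintf("ub_%s", rid)
    )
    rows <- which(S@j + 1L == j)
    coefs <- S@x[rows]
    met_ids <- model$mets[S@i[rows] + 1L]
    if (any(coefs < 0)) {
      reac <- xml2::xml_add_child(rx, "listOfReactants")
      for (r in which(coefs < 0)) {
        xml2::xml_add_child(reac, "speciesReference", species = met_ids[r],
                            stoichiometry = format(-coefs[r], digits = 17),
                            constant = "true")
      }
    }
    if (any(coefs > 0)) {
      prod <- xml2::xml_add_child(rx, "listOfProducts")
      for (r in which(coefs > 0)) {
        xml2::xml_add_child(prod, "speciesReference", species = met_ids[r],
                            stoichiometry = format(coefs[r], digits = 17),
                            constant = "true")
      }
    }
    if (nzchar(model$gpr[j])) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpa_node(gpa, parse_gpr(model$gpr[j]))
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  flux <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(flux, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")
  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (i in seq_len(nrow(model$genes))) {
    xml2::xml_add_child(gps, "fbc:geneProduct",
                        "fbc:id" = model$genes$gene_id[i],
                        "fbc:label" = model$genes$gene_id[i],
                        "fbc:name" = model$genes$replicon[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

add_gpa_node <- function(parent, ast) {
  if (is.character(ast)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = ast)
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (a in ast$args) add_gpa_node(node, a)
  }
}

#' Read a metabolic model from SBML Level 3 + fbc
#'
#' @param path SBML file written by \code{\link{write_sbml}} or any file
#'   restricted to the same fbc subset.
#' @return A \code{metabolic_model}.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  model_id <- xml2::xml_attr(mdl, "id")
  mets <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", ns), "id")
  pnodes <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter",
                               ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                    xml2::xml_attr(pnodes, "id"))
  rnodes <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction",
                               ns)
  rxns <- xml2::xml_attr(rnodes, "id")
  lb <- unname(pvals[xml2::xml_attr(rnodes, "lowerFluxBound")])
  ub <- unname(pvals[xml2::xml_attr(rnodes, "upperFluxBound")])
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  gpr <- character(length(rxns))
  for (j in seq_along(rnodes)) {
    reac <- xml2::xml_find_all(rnodes[[j]],
                               "./sbml:listOfReactants/sbml:speciesReference",
                               ns)
    prod <- xml2::xml_find_all(rnodes[[j]],
                               "./sbml:listOfProducts/sbml:speciesReference",
                               ns)
    sp <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    st <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
            as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    mi <- match(sp, mets)
    if (anyNA(mi)) {
      stopf("reaction '%s' references unknown metabolite '%s'",
            rxns[j], sp[which(is.na(mi))[1L]])
    }
    trip_i <- c(trip_i, mi); trip_j <- c(trip_j, rep(j, length(mi)))
    trip_x <- c(trip_x, st)
    gpa <- xml2::xml_find_first(rnodes[[j]], "./fbc:geneProductAssociation",
                                ns)
    if (!inherits(gpa, "xml_missing")) {
      child <- xml2::xml_children(gpa)[[1L]]
      gpr[j] <- deparse_gpr(parse_gpa_node(child, ns))
    }
  }
  S <- sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                    dims = c(length(mets), length(rxns)))
  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  genes <- data.frame(
    gene_id = xml2::xml_attr(gp, "id"),
    replicon = xml2::xml_attr(gp, "name"),
    stringsAsFactors = FALSE
  )
  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- xml2::xml_attr(fo, "reaction")
  metabolic_model(mets = mets, rxns = rxns, S = S, lb = lb, ub = ub,
                  gpr = gpr, genes = genes, objective = objective,
                  id = model_id)
}

parse_gpa_node <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(xml2::xml_attr(node, "geneProduct"))
  }
  if (!nm %in% c("and", "or")) stopf("unsupported GPR element '%s'", nm)
  list(op = nm,
       args = lapply(xml2::xml_children(node), parse_gpa_node, ns = ns))
}

#' Write/read a metabolic model in the tabular fixture dialect
#'
#' Four TSV files in a directory: \code{metabolites.tsv} (id),
#' \code{reactions.tsv} (id, lb, ub, objective, gpr),
#' \code{stoichiometry.tsv} (reaction, metabolite, coefficient) and
#' \code{genes.tsv} (gene_id, replicon). Hand-editing these is less
#' error-prone than editing SBML.
#'
#' @param model A \code{metabolic_model}.
#' @param dir Directory for the four TSV files.
#' @return \code{dir} (write) or a \code{metabolic_model} (read).
#' @export
write_model_tab <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(data.frame(id = model$mets), "metabolites.tsv")
  wt(data.frame(id = model$rxns, lb = model$lb, ub = model$ub,
                objective = as.integer(model$rxns == model$objective),
                gpr = model$gpr), "reactions.tsv")
  S <- as(model$S, "TsparseMatrix")
  wt(data.frame(reaction = model$rxns[S@j + 1L],
                metabolite = model$mets[S@i + 1L],
                coefficient = S@x), "stoichiometry.tsv")
  wt(model$genes, "genes.tsv")
  invisible(dir)
}

#' @rdname write_model_tab
#' @export
read_model_tab <- function(dir) {
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                               na.strings = NULL)
  mets <- rd("metabolites.tsv")$id
  rxn <- rd("reactions.tsv")
  st <- rd("stoichiometry.tsv")
  genes <- rd("genes.tsv")
  mi <- match(st$metabolite, mets)
  if (anyNA(mi)) {
    bad <- st[is.na(mi), ][1L, ]
    stopf("reaction '%s' references unknown metabolite '%s'",
          bad$reaction, bad$metabolite)
  }
  ji <- match(st$reaction, rxn$id)
  if (anyNA(ji)) {
    stopf("stoichiometry references unknown reaction '%s'",
          st$reaction[which(is.na(ji))[1L]])
  }
  S <- sparseMatrix(i = mi, j = ji, x = st$coefficient,
                    dims = c(length(mets), nrow(rxn)))
  metabolic_model(mets = mets, rxns = rxn$id, S = S, lb = rxn$lb,
                  ub = rxn$ub, gpr = ifelse(is.na(rxn$gpr), "", rxn$gpr),
                  genes = genes, objective = rxn$id[rxn$objective == 1][1L],
                  id = basename(dir))
}
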