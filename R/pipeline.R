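# Pipeline orchestration: simulate -> GEI -> classify -> differential ->
# enrichment -> constraint-based screens, with structured logging, per-stage
# outputs and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' A demo-scale configuration (300 genes, 0.3-Mb replicon, 2e6 reads/sample)
#' exercising all stages in a few minutes of CPU time; production analyses
#' supply their own values. Conditions cross two strains with two media; a
#' planted set of genes is more important in the reduced-genome strain, so
#' the differential stage has signal.
#'
#' @param seed Integer seed propagated to every stochastic stage.
#' @param outdir Output directory.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = tempfile("tnrun")) {
  list(
    seed = seed,
    outdir = outdir,
    simulation = list(n_genes = 300L, genome_length = 3e5,
                      median_sites_per_gene = 39L, generations = 9,
                      read_depth = 2e6),
    conditions = c("WT_rich", "dAB_rich", "WT_min", "dAB_min"),
    n_strain_dependent = 20L,       # genes planted as weaker in dAB_*
    strain_dependent_fitness = 0.717,  # ~20-fold GEI reduction over 9 gens
    classification = list(k_range = 1:7, v_margin = 0.25, split_tol = 0.5,
                          ap_damping = 0.9),
    differential = list(equal_zone = 0.3, k_range = 1:5),
    toy_model = list(n_chromosome_genes = 4L, n_plasmid_genes = 2L,
                     n_isozyme_pairs = 2L, n_parallel_pathways = 1L),
    screen_method = "fba"
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  modifyList(base, config)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  log_stage(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates annotation, truth and insertion libraries for the configured
#' conditions, computes GEI profiles, classifies every condition into fitness
#' groups, calls differential fitness for the strain pairs within each
#' medium, tests the essential genome for functional-category enrichment,
#' builds the engineered toy metabolic model and runs single/double deletion
#' and replicon-removal screens. All stage outputs are written under
#' \code{config$outdir} along with \code{summary.json} and a
#' \code{manifest.json} recording versions, the seed and output checksums.
#'
#' @param config Configuration list or path to a YAML file; see
#'   \code{\link{default_pipeline_config}}.
#' @return Invisible list with all in-memory stage results plus the summary.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- read_pipeline_config(if (is.character(config)) config else config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("insertions", "gei", "classification", "differential",
              "enrichment", "model", "screens")) {
    dir.create(file.path(cfg$outdir, d), showWarnings = FALSE)
  }
  sim <- do.call(sim_config, c(cfg$simulation, list(seed = cfg$seed)))

  ann <- run_stage("simulate/annotation", {
    a <- simulate_annotation(sim)
    write_annotation_gff3(a, file.path(cfg$outdir, "annotation.gff3"))
    a
  })

  truth <- run_stage("simulate/truth", {
    dep_genes <- with_seed(cfg$seed + 3L, {
      neutral_pool <- ann$genes$gene_id
      sample(neutral_pool, min(cfg$n_strain_dependent, length(neutral_pool)))
    })
    dab <- grep("^dAB", cfg$conditions, value = TRUE)
    overrides <- if (length(dab) && length(dep_genes)) {
      expand <- expand.grid(gene_id = dep_genes, condition = dab,
                            stringsAsFactors = FALSE)
      expand$relative_fitness <- cfg$strain_dependent_fitness
      expand
    } else NULL
    tr <- simulate_truth(ann, sim, conditions = cfg$conditions,
                         overrides = overrides)
    write_truth_json(tr, file.path(cfg$outdir, "truth.json"))
    tr
  })

  tables <- run_stage("simulate/library", {
    tabs <- simulate_library(ann, truth, sim)
    for (nm in names(tabs)) {
      write_insertion_tsv(tabs[[nm]],
                          file.path(cfg$outdir, "insertions",
                                    paste0(nm, ".tsv")))
    }
    tabs
  })

  profiles <- run_stage("gei", {
    p <- gei_profiles(tables, ann)
    for (cond in unique(p$condition)) {
      write_gei_tsv(p[p$condition == cond, ],
                    file.path(cfg$outdir, "gei", paste0(cond, ".tsv")))
    }
    p
  })

  calls <- run_stage("classify", {
    cl <- lapply(cfg$conditions, function(cond) {
      cc <- classify_fitness(profiles[profiles$condition == cond, ],
                             k_range = cfg$classification$k_range,
                             v_margin = cfg$classification$v_margin,
                             split_tol = cfg$classification$split_tol,
                             ap_damping = cfg$classification$ap_damping,
                             seed = cfg$seed)
      write.table(cc, file.path(cfg$outdir, "classification",
                                paste0(cond, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cc
    })
    names(cl) <- cfg$conditions
    cl
  })

  diffs <- run_stage("differential", {
    media <- unique(sub("^[^_]+_", "", cfg$conditions))
    d <- list()
    for (med in media) {
      pair <- cfg$conditions[endsWith(cfg$conditions, paste0("_", med))]
      if (length(pair) != 2L) next
      dc <- call_differential(profiles[profiles$condition == pair[1L], ],
                              profiles[profiles$condition == pair[2L], ],
                              equal_zone = cfg$differential$equal_zone,
                              k_range = cfg$differential$k_range,
                              seed = cfg$seed)
      key <- paste(pair, collapse = "_vs_")
      write.table(dc, file.path(cfg$outdir, "differential",
                                paste0(key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      d[[key]] <- dc
    }
    d
  })

  enrich <- run_stage("enrichment", {
    first <- calls[[1L]]
    ess <- first$gene_id[first$group == "I"]
    er <- if (length(ess) > 0) {
      fisher_enrichment(ess, ann$genes)
    } else NULL
    if (!is.null(er)) {
      write.table(er, file.path(cfg$outdir, "enrichment",
                                "essential_vs_background.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    er
  })

  screens <- run_stage("cbm/screens", {
    toy <- build_toy_model(do.call(toy_model_spec,
                                   c(cfg$toy_model, list(seed = cfg$seed))))
    write_sbml(toy$model, file.path(cfg$outdir, "model", "toy_model.xml"))
    singles <- single_gene_deletion(toy$model, method = cfg$screen_method)
    doubles <- double_gene_deletion(toy$model, method = cfg$screen_method,
                                    singles = singles)
    reduced <- remove_replicon(toy$model, "pSym")
    chr_genes <- reduced$genes$gene_id
    singles_reduced <- single_gene_deletion(reduced, genes = chr_genes,
                                            method = cfg$screen_method)
    backgrounds <- compare_backgrounds(
      singles[singles$gene_id %in% chr_genes, ], singles_reduced)
    write.table(singles, file.path(cfg$outdir, "screens", "single_gene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(doubles, file.path(cfg$outdir, "screens", "double_gene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(backgrounds,
                file.path(cfg$outdir, "screens", "backgrounds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(toy = toy, singles = singles, doubles = doubles,
         singles_reduced = singles_reduced, backgrounds = backgrounds)
  })

  summary <- run_stage("summary", {
    group_counts <- lapply(calls, function(cc) as.list(table(cc$group)))
    diff_counts <- lapply(diffs, function(d) as.list(table(d$call)))
    cmp <- summarize_comparison(calls)
    s <- list(
      seed = cfg$seed,
      group_counts = group_counts,
      differential_counts = diff_counts,
      comparison = cmp,
      enrichment_significant =
        if (!is.null(enrich)) sum(enrich$p_bonferroni < 0.05) else 0L,
      epistasis = list(
        pairs_tested = nrow(screens$doubles),
        synthetic_negative = sum(screens$doubles$synthetic_negative)
      )
    )
    jsonlite::write_json(s, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    s
  })

  manifest <- run_stage("manifest", {
    files <- list.files(cfg$outdir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, file.path(cfg$outdir, "manifest.json"))
    m <- list(
      package = "tnseqfit",
      version = as.character(packageVersion("tnseqfit")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = cfg$seed,
      checksums = as.list(setNames(unname(tools::md5sum(files)),
                                   sub(paste0("^", cfg$outdir, "/?"), "",
                                       files)))
    )
    jsonlite::write_json(m, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE)
    m
  })

  invisible(list(config = cfg, annotation = ann, truth = truth,
                 tables = tables, profiles = profiles, calls = calls,
                 differential = diffs, enrichment = enrich,
                 screens = screens, summary = summary, manifest = manifest))
}

#' Cross-condition comparison of fitness classifications
#'
#' Counts genes essential (Group I) in every condition, growth promoting
#' (Groups I or II) in every condition, and the pairwise overlaps of the
#' essential sets.
#'
#' @param calls Named list of \code{fitness_call} data.frames, one per
#'   condition (at least two).
#' @return List: n_conditions, essential_in_all, growth_promoting_in_all,
#'   pairwise (data.frame condition_a, condition_b, overlap).
#' @export
summarize_comparison <- function(calls) {
  if (length(calls) < 2L) stopf("need at least 2 condition classifications")
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    stopf("'calls' must be a named list of conditions")
  }
  ess <- lapply(calls, function(cc) cc$gene_id[cc$group == "I"])
  gp <- lapply(calls, function(cc) cc$gene_id[cc$group %in% c("I", "II")])
  pair_idx <- utils::combn(names(calls), 2L)
  pairwise <- data.frame(
    condition_a = pair_idx[1L, ],
    condition_b = pair_idx[2L, ],
    overlap = apply(pair_idx, 2L, function(p) {
      length(intersect(ess[[p[1L]]], ess[[p[2L]]]))
    }),
    stringsAsFactors = FALSE
  )
  list(n_conditions = length(calls),
       essential_in_all = length(Reduce(intersect, ess)),
       growth_promoting_in_all = length(Reduce(intersect, gp)),
       pairwise = pairwise)
}
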