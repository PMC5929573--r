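#' The 18 functional categories used for enrichment analysis
#'
#' Bacterial gene functions simplified to a fixed vocabulary of 18 labels.
#' Enrichment p-values are Bonferroni-corrected for this family of 18 tests.
#'
#' @return Character vector of length 18.
#' @export
functional_categories <- function() {
  c("amino acid metabolism", "carbon metabolism", "cell cycle",
    "cell envelope", "cofactor metabolism", "DNA replication and repair",
    "electron transport", "hypothetical", "lipid metabolism",
    "motility and attachment", "nucleotide metabolism", "oxidoreductases",
    "protein fate", "regulation", "stress response", "transcription",
    "translation", "transport")
}

#' Fitness classes and their default per-generation growth factors
#'
#' The five ground-truth fitness classes mirror the five fitness groups used
#' for classification: disruption of an essential gene is lethal (relative
#' fitness 0), a strong or moderate defect slows growth multiplicatively per
#' generation, a neutral gene has no effect, and a small class of genes
#' improves growth when disrupted.
#'
#' @return Named numeric vector of per-generation relative fitness values.
#' @export
fitness_class_values <- function() {
  c(essential = 0, strong_defect = 0.5, moderate_defect = 0.8,
    neutral = 1.0, improved = 1.15)
}

#' Simulation configuration for synthetic insertion libraries
#'
#' Defaults describe a realistic single-chromosome Tn-seq experiment:
#' ~3,500 genes on a 3.65-Mb replicon, a library dense enough to give a
#' median of 39 unique insertion sites per gene (~190,000 genome-wide),
#' two replicate selections of approximately nine generations each, and a
#' fitness-class composition of roughly 12% essential, 5% strong defect,
#' 15% moderate defect, 66% neutral and 2% growth-improving genes.
#'
#' @param n_genes Number of genes (>= 10).
#' @param genome_length Replicon length in nucleotides.
#' @param median_sites_per_gene Target median number of unique insertion
#'   sites per gene.
#' @param replicates Number of replicate selections per condition.
#' @param generations Generations of competitive selection, in [1, 20].
#' @param class_fractions Named proportions over the five fitness classes;
#'   must sum to 1.
#' @param class_values Named per-generation relative fitness per class.
#' @param read_depth Total mapped reads per sample.
#' @param mean_gene_length Mean of the log-normal gene-length distribution
#'   (nucleotides).
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 3500L,
                       genome_length = 3.65e6,
                       median_sites_per_gene = 39L,
                       replicates = 2L,
                       generations = 9,
                       class_fractions = c(essential = 0.12,
                                           strong_defect = 0.05,
                                           moderate_defect = 0.15,
                                           neutral = 0.66,
                                           improved = 0.02),
                       class_values = fitness_class_values(),
                       read_depth = 2e7,
                       mean_gene_length = 950,
                       seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 10)
  assert_scalar_number(genome_length, "genome_length", lower = 1000)
  assert_scalar_number(generations, "generations", lower = 1, upper = 20)
  assert_scalar_number(read_depth, "read_depth", lower = 1)
  assert_scalar_number(replicates, "replicates", lower = 1)
  classes <- names(fitness_class_values())
  if (!setequal(names(class_fractions), classes)) {
    stopf("class_fractions must be named over: %s",
          paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stopf("class_fractions must sum to 1 (got %.12f)", sum(class_fractions))
  }
  if (any(class_fractions < 0)) stopf("class_fractions must be non-negative")
  if (!setequal(names(class_values), classes)) {
    stopf("class_values must be named over the five fitness classes")
  }
  if (any(class_values < 0)) stopf("relative fitness values must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes),
    genome_length = as.numeric(genome_length),
    median_sites_per_gene = as.numeric(median_sites_per_gene),
    replicates = as.integer(replicates),
    generations = as.numeric(generations),
    class_fractions = class_fractions,
    class_values = class_values[classes],
    read_depth = as.numeric(read_depth),
    mean_gene_length = as.numeric(mean_gene_length),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a non-overlapping gene annotation on a circular replicon
#'
#' Gene lengths are drawn from a log-normal distribution (sdlog 0.4) scaled to
#' the configured mean; genes are laid out head-to-tail around the replicon
#' with at least 1 nt of intergenic sequence between consecutive genes, so the
#' gene and intergenic intervals partition \code{[1, genome_length]} exactly.
#' Coordinates are 1-based inclusive; strands are assigned at random; each
#' gene receives one of the 18 functional-category labels.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{tn_annotation} with elements \code{genes}
#'   (data.frame: gene_id, replicon, start, end, strand, length, category),
#'   \code{intergenic} (data.frame: start, end) and \code{genome_length}.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    sdlog <- 0.4
    meanlog <- log(config$mean_gene_length) - sdlog^2 / 2
    len <- pmax(60L, as.integer(round(rlnorm(n, meanlog, sdlog))))
    total_gap <- config$genome_length - sum(len)
    if (total_gap < n) {
      stopf(paste0("cannot pack %d genes totalling %d nt plus %d intergenic ",
                   "gaps into a %d nt replicon"),
            n, sum(len), n, as.integer(config$genome_length))
    }
    # one gap after every gene; each gap at least 1 nt
    gap <- as.vector(rmultinom(1L, size = total_gap - n, prob = rep(1, n))) + 1L
    start <- 1L + c(0L, cumsum(len + gap))[seq_len(n)]
    end <- start + len - 1L
    genes <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n)),
      replicon = "chromosome",
      start = start,
      end = end,
      strand = sample(c("+", "-"), n, replace = TRUE),
      length = len,
      category = sample(functional_categories(), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    intergenic <- data.frame(start = end + 1L, end = end + gap)
    structure(list(genes = genes, intergenic = intergenic,
                   genome_length = config$genome_length),
              class = "tn_annotation")
  })
}

#' Simulate per-gene fitness ground truth for a set of conditions
#'
#' Genes are assigned to the five fitness classes according to the configured
#' class fractions (exact counts, randomly permuted over genes, identical
#' across conditions). \code{overrides} lets specific genes take a different
#' relative fitness in a specific condition, which is how strain- or
#' medium-dependent effects are planted.
#'
#' @param annotation A \code{tn_annotation}.
#' @param config A \code{\link{sim_config}}.
#' @param conditions Character vector of condition labels (strain x medium).
#' @param overrides Optional data.frame (gene_id, condition, relative_fitness)
#'   overriding individual truth entries.
#' @return Data.frame of class \code{fitness_truth}: gene_id, condition,
#'   class, relative_fitness.
#' @export
simulate_truth <- function(annotation, config,
                           conditions = "WT_rich", overrides = NULL) {
  stopifnot(inherits(annotation, "tn_annotation"))
  genes <- annotation$genes
  n <- nrow(genes)
  with_seed(config$seed + 1L, {
    counts <- floor(config$class_fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {  # give leftovers to the largest class
      counts[which.max(counts)] <- counts[which.max(counts)] + rem
    }
    cls <- sample(rep(names(counts), counts))
    truth <- do.call(rbind, lapply(conditions, function(cond) {
      data.frame(gene_id = genes$gene_id, condition = cond, class = cls,
                 relative_fitness = unname(config$class_values[cls]),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(overrides)) {
      need <- c("gene_id", "condition", "relative_fitness")
      if (!all(need %in% names(overrides))) {
        stopf("overrides needs columns: %s", paste(need, collapse = ", "))
      }
      key <- paste(truth$gene_id, truth$condition)
      okey <- paste(overrides$gene_id, overrides$condition)
      hit <- match(okey, key)
      if (anyNA(hit)) {
        stopf("override refers to unknown gene/condition: %s",
              okey[which(is.na(hit))[1L]])
      }
      truth$relative_fitness[hit] <- overrides$relative_fitness
      if ("class" %in% names(overrides)) truth$class[hit] <- overrides$class
    }
    class(truth) <- c("fitness_truth", "data.frame")
    truth
  })
}

#' Simulate post-selection insertion libraries
#'
#' Insertion sites are sampled uniformly over the replicon (optionally
#' reweighted through \code{bias_fun}); initial clone abundances are
#' Dirichlet-uniform (independent exponential weights); after \code{g}
#' generations of competitive selection the expected read share of a site in
#' gene \code{j} is proportional to its initial abundance times
#' \code{relative_fitness^g}, so sites in essential genes (fitness 0) receive
#' zero reads. Read counts per sample are drawn by multinomial sampling at
#' exactly \code{read_depth} total reads. Replicates share the insertion-site
#' set and initial abundances (both replicates derive from one mutant
#' library) but resample read counts independently.
#'
#' @param annotation A \code{tn_annotation}.
#' @param truth A \code{fitness_truth} covering every gene in every condition.
#' @param config A \code{\link{sim_config}}.
#' @param bias_fun Optional function(positions) returning positive weights,
#'   e.g. a GC-motif insertion bias. Default NULL (uniform).
#' @return Named list of \code{insertion_table} objects
#'   ("<condition>_rep<k>"), each a list with sample_id, condition, replicate
#'   and records (data.frame: position, strand, count; only positions with
#'   at least one read are kept).
#' @export
simulate_library <- function(annotation, truth, config, bias_fun = NULL) {
  stopifnot(inherits(annotation, "tn_annotation"),
            inherits(config, "sim_config"))
  genes <- annotation$genes
  conditions <- unique(truth$condition)
  for (cond in conditions) {
    have <- truth$gene_id[truth$condition == cond]
    missing <- setdiff(genes$gene_id, have)
    if (length(missing) > 0) {
      stopf("no fitness truth for gene '%s' in condition '%s'",
            missing[1L], cond)
    }
  }
  with_seed(config$seed + 2L, {
    density <- config$median_sites_per_gene / median(genes$length)
    n_sites <- round(density * config$genome_length)
    if (is.null(bias_fun)) {
      pos <- sort(sample.int(config$genome_length, n_sites))
    } else {
      w <- bias_fun(seq_len(config$genome_length))
      pos <- sort(sample.int(config$genome_length, n_sites, prob = w))
    }
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    # map sites to genes (0 = intergenic); genes are sorted, non-overlapping
    idx <- findInterval(pos, genes$start)
    gene_of <- ifelse(idx > 0 & pos <= genes$end[pmax(idx, 1L)], idx, 0L)
    w0 <- rexp(n_sites)  # shared pre-selection abundances
    out <- list()
    for (cond in conditions) {
      tr <- truth[truth$condition == cond, ]
      fit <- tr$relative_fitness[match(genes$gene_id, tr$gene_id)]
      site_fit <- ifelse(gene_of > 0, fit[pmax(gene_of, 1L)], 1)
      wsel <- w0 * site_fit^config$generations
      prob <- wsel / sum(wsel)
      for (rep_i in seq_len(config$replicates)) {
        cnt <- as.vector(rmultinom(1L, size = config$read_depth, prob = prob))
        keep <- cnt > 0L
        sid <- sprintf("%s_rep%d", cond, rep_i)
        out[[sid]] <- structure(list(
          sample_id = sid, condition = cond, replicate = rep_i,
          records = data.frame(position = pos[keep], strand = strand[keep],
                               count = as.numeric(cnt[keep]),
                               stringsAsFactors = FALSE)
        ), class = "insertion_table")
      }
    }
    out
  })
}

#' Simulate a random genome sequence
#'
#' @param length Sequence length in nucleotides.
#' @param gc GC content in [0, 1]; the genome emulated here is GC-rich
#'   (default 0.62).
#' @param seed Integer seed.
#' @return A single character string of A/C/G/T.
#' @export
simulate_genome_sequence <- function(length, gc = 0.62, seed = 1L) {
  assert_scalar_number(gc, "gc", 0, 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Specification of an engineered toy metabolic model
#'
#' The toy network is a linear substrate-to-biomass backbone whose stages
#' encode known redundancy: isozyme stages are one reaction with an OR rule
#' over a chromosomal and a plasmid gene; parallel-pathway stages are two
#' branch reactions with capacities 6 and 4 (chromosomal and plasmid gene
#' respectively) feeding the same product, against a substrate uptake of 10.
#' Every isozyme pair and within-stage parallel pair is a ground-truth
#' synthetic-negative interaction.
#'
#' @param n_chromosome_genes Number of singly-essential chromosomal backbone
#'   genes.
#' @param n_plasmid_genes Number of dispensable plasmid-only side-branch
#'   genes.
#' @param n_isozyme_pairs Number of cross-replicon isozyme stages.
#' @param n_parallel_pathways Number of parallel-pathway stages
#'   (capacities 6 and 4, uptake 10).
#' @param uptake Substrate uptake bound (mmol/gDW/h), default 10.
#' @param seed Integer seed (layout is deterministic; kept for interface
#'   symmetry).
#' @return A list of class \code{toy_model_spec}.
#' @export
toy_model_spec <- function(n_chromosome_genes = 4L, n_plasmid_genes = 2L,
                           n_isozyme_pairs = 2L, n_parallel_pathways = 1L,
                           uptake = 10, seed = 1L) {
  for (nm in c("n_chromosome_genes", "n_plasmid_genes", "n_isozyme_pairs",
               "n_parallel_pathways")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  if (n_chromosome_genes + n_isozyme_pairs + n_parallel_pathways < 1) {
    stopf("the model needs at least one biomass-producing stage")
  }
  structure(list(n_chromosome_genes = as.integer(n_chromosome_genes),
                 n_plasmid_genes = as.integer(n_plasmid_genes),
                 n_isozyme_pairs = as.integer(n_isozyme_pairs),
                 n_parallel_pathways = as.integer(n_parallel_pathways),
                 uptake = as.numeric(uptake), seed = as.integer(seed)),
            class = "toy_model_spec")
}

#' Build an engineered toy metabolic model with known epistasis ground truth
#'
#' @param spec A \code{\link{toy_model_spec}}.
#' @return List with elements \code{model} (a \code{\link{metabolic_model}})
#'   and \code{interactions} (data.frame gene_a, gene_b, mechanism) listing
#'   every engineered synthetic-negative gene pair.
#' @export
build_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  mets <- "S_e"
  rxn <- list()  # each: id, stoich (named), lb, ub, gpr
  add_rxn <- function(id, stoich, lb, ub, gpr = "") {
    rxn[[id]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr)
  }
  genes <- data.frame(gene_id = character(), replicon = character(),
                      stringsAsFactors = FALSE)
  add_gene <- function(id, replicon) {
    genes <<- rbind(genes, data.frame(gene_id = id, replicon = replicon,
                                      stringsAsFactors = FALSE))
  }
  interactions <- data.frame(gene_a = character(), gene_b = character(),
                             mechanism = character(), stringsAsFactors = FALSE)

  add_rxn("EX_S", c(S_e = -1), lb = -spec$uptake, ub = 1000)
  cur <- "S_e"
  stage <- 0L
  next_met <- function() {
    stage <<- stage + 1L
    m <- sprintf("M%02d", stage)
    mets <<- c(mets, m)
    m
  }
  # essential chromosomal backbone steps
  for (i in seq_len(spec$n_chromosome_genes)) {
    g <- sprintf("gC%02d", i)
    add_gene(g, "chromosome")
    nxt <- next_met()
    add_rxn(sprintf("CHR%02d", i), setNames(c(-1, 1), c(cur, nxt)),
            lb = 0, ub = 1000, gpr = g)
    cur <- nxt
  }
  # cross-replicon isozyme stages (one reaction, OR rule)
  for (i in seq_len(spec$n_isozyme_pairs)) {
    ga <- sprintf("gIC%02d", i)
    gb <- sprintf("gIP%02d", i)
    add_gene(ga, "chromosome")
    add_gene(gb, "pSym")
    nxt <- next_met()
    add_rxn(sprintf("ISO%02d", i), setNames(c(-1, 1), c(cur, nxt)),
            lb = 0, ub = 1000, gpr = sprintf("%s or %s", ga, gb))
    interactions <- rbind(interactions,
                          data.frame(gene_a = ga, gene_b = gb,
                                     mechanism = "isozyme",
                                     stringsAsFactors = FALSE))
    cur <- nxt
  }
  # parallel-pathway stages: branches of capacity 6 (chromosome) and
  # 4 (plasmid) against uptake 10
  for (i in seq_len(spec$n_parallel_pathways)) {
    ga <- sprintf("gPC%02d", i)
    gb <- sprintf("gPP%02d", i)
    add_gene(ga, "chromosome")
    add_gene(gb, "pSym")
    nxt <- next_met()
    add_rxn(sprintf("PARA%02d", i), setNames(c(-1, 1), c(cur, nxt)),
            lb = 0, ub = 6, gpr = ga)
    add_rxn(sprintf("PARB%02d", i), setNames(c(-1, 1), c(cur, nxt)),
            lb = 0, ub = 4, gpr = gb)
    interactions <- rbind(interactions,
                          data.frame(gene_a = ga, gene_b = gb,
                                     mechanism = "parallel_pathway",
                                     stringsAsFactors = FALSE))
    cur <- nxt
  }
  # dispensable plasmid side branches (secretion of a byproduct)
  for (i in seq_len(spec$n_plasmid_genes)) {
    g <- sprintf("gS%02d", i)
    add_gene(g, "pSym")
    w <- sprintf("W%02d", i)
    mets <- c(mets, w)
    add_rxn(sprintf("SIDE%02d", i), setNames(c(-1, 1), c(cur, w)),
            lb = 0, ub = 1000, gpr = g)
    add_rxn(sprintf("EX_W%02d", i), setNames(-1, w), lb = 0, ub = 1000)
  }
  add_rxn("BIOMASS", setNames(-1, cur), lb = 0, ub = 1000)

  ids <- names(rxn)
  triplets <- do.call(rbind, lapply(seq_along(rxn), function(j) {
    st <- rxn[[j]]$stoich
    data.frame(i = match(names(st), mets), j = j, x = unname(st))
  }))
  S <- sparseMatrix(i = triplets$i, j = triplets$j, x = triplets$x,
                    dims = c(length(mets), length(ids)),
                    dimnames = list(mets, ids))
  model <- metabolic_model(
    mets = mets, rxns = ids, S = S,
    lb = vapply(rxn, `[[`, numeric(1), "lb"),
    ub = vapply(rxn, `[[`, numeric(1), "ub"),
    gpr = vapply(rxn, `[[`, character(1), "gpr"),
    genes = genes, objective = "BIOMASS", id = "toy_model"
  )
  list(model = model, interactions = interactions)
}
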