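test_that("simulated genes and intergenic intervals partition the replicon", {
  cfg <- sim_config(n_genes = 10L, genome_length = 20000, seed = 7L)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 10L)
  # non-overlapping, sorted genes
  expect_true(all(diff(ann$genes$start) > 0))
  expect_true(all(ann$genes$start[-1] > ann$genes$end[-10]))
  # the union of genes and intergenic intervals covers [1, 20000] exactly
  ivs <- rbind(ann$genes[, c("start", "end")], ann$intergenic)
  ivs <- ivs[order(ivs$start), ]
  expect_equal(ivs$start[1], 1)
  expect_equal(ivs$end[nrow(ivs)], 20000)
  expect_true(all(ivs$start[-1] == ivs$end[-nrow(ivs)] + 1))
})

test_that("annotation simulation is deterministic and respects the length model", {
  cfg <- sim_config(seed = 11L)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  ann <- simulate_annotation(cfg)
  expect_gt(mean(ann$genes$length), 900)
  expect_lt(mean(ann$genes$length), 1000)
})

test_that("infeasible gene packing is rejected with an explicit error", {
  cfg <- sim_config(n_genes = 100L, genome_length = 20000, seed = 1L)
  expect_error(simulate_annotation(cfg), "cannot pack")
})

test_that("library simulation conserves read depth and shares sites between replicates", {
  cfg <- small_sim_config(seed = 2L)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg, conditions = "WT_rich")
  tabs <- simulate_library(ann, truth, cfg)
  expect_named(tabs, c("WT_rich_rep1", "WT_rich_rep2"))
  for (tab in tabs) {
    expect_equal(sum(tab$records$count), cfg$read_depth)
  }
  # replicates draw reads from one shared site set
  expect_true(all(tabs[[2]]$records$position %in%
                    union(tabs[[1]]$records$position,
                          tabs[[2]]$records$position)))
  common <- intersect(tabs[[1]]$records$position, tabs[[2]]$records$position)
  expect_gt(length(common) / nrow(tabs[[1]]$records), 0.8)
  # determinism
  expect_identical(tabs, simulate_library(ann, truth, cfg))
})

test_that("genes with fitness zero receive no reads in any replicate", {
  cfg <- small_sim_config(seed = 3L)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg, conditions = "WT_rich")
  tabs <- simulate_library(ann, truth, cfg)
  ess <- truth$gene_id[truth$class == "essential"]
  genes <- ann$genes[ann$genes$gene_id %in% ess, ]
  for (tab in tabs) {
    pos <- tab$records$position
    inside <- vapply(seq_len(nrow(genes)), function(i) {
      sum(pos >= genes$start[i] & pos <= genes$end[i])
    }, numeric(1))
    expect_true(all(inside == 0))
  }
})

test_that("an all-neutral library is homogeneous across replicates", {
  cfg <- small_sim_config(
    seed = 1L,
    class_fractions = c(essential = 0, strong_defect = 0,
                        moderate_defect = 0, neutral = 1, improved = 0))
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg, conditions = "A")
  tabs <- simulate_library(ann, truth, cfg)
  prof <- gei_profiles(tabs, ann, normalize = FALSE)
  # the two replicates are conditionally independent multinomials over the
  # same clone library: a two-sample chi-square homogeneity test on per-gene
  # read totals should not reject
  o1 <- prof$raw_rep1
  o2 <- prof$raw_rep2
  keep <- o1 + o2 >= 10
  chi <- suppressWarnings(stats::chisq.test(cbind(o1[keep], o2[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("selection reduces read density by fitness^generations", {
  cfg <- small_sim_config(
    seed = 1L, n_genes = 400L, genome_length = 4e5, read_depth = 1e7,
    class_fractions = c(essential = 0, strong_defect = 0.5,
                        moderate_defect = 0, neutral = 0.5, improved = 0))
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg, conditions = "A")
  tabs <- simulate_library(ann, truth, cfg)
  prof <- gei_profiles(tabs, ann, normalize = FALSE)
  cls <- truth$class[match(prof$gene_id, truth$gene_id)]
  dens <- (prof$raw_rep1 + prof$raw_rep2) / prof$length
  ratio <- mean(dens[cls == "strong_defect"]) / mean(dens[cls == "neutral"])
  expected <- 0.5^9
  # per-gene density has ~25% CV; allow 3x the standard error of the ratio
  n_s <- sum(cls == "strong_defect")
  se <- expected * sqrt(var(dens[cls == "strong_defect"]) /
                          mean(dens[cls == "strong_defect"])^2 / n_s +
                        var(dens[cls == "neutral"]) /
                          mean(dens[cls == "neutral"])^2 / sum(cls == "neutral"))
  expect_lt(abs(ratio - expected), 3 * se)
})

test_that("missing truth entries are reported by gene name", {
  cfg <- small_sim_config(seed = 4L)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg, conditions = "A")
  truth <- truth[truth$gene_id != "g00005", ]
  expect_error(simulate_library(ann, truth, cfg), "g00005")
})

test_that("toy models encode the engineered redundancy", {
  # single isozyme pair: deleting either gene alone is silent, both lethal
  iso <- build_toy_model(toy_model_spec(n_chromosome_genes = 0L,
                                        n_plasmid_genes = 0L,
                                        n_isozyme_pairs = 1L,
                                        n_parallel_pathways = 0L))
  wt <- fba(iso$model)$objective_value
  expect_gt(wt, 0)
  expect_equal(fba(delete_genes(iso$model, "gIC01"))$objective_value, wt,
               tolerance = 1e-9)
  expect_equal(fba(delete_genes(iso$model, "gIP01"))$objective_value, wt,
               tolerance = 1e-9)
  expect_equal(
    fba(delete_genes(iso$model, c("gIC01", "gIP01")))$objective_value, 0,
    tolerance = 1e-9)

  # one parallel pathway with capacities 6 and 4 against uptake 10
  par <- parallel_toy()
  expect_equal(fba(par$model)$objective_value, 10, tolerance = 1e-6)

  # a purely linear path is a chain of essential genes
  lin <- build_toy_model(toy_model_spec(n_chromosome_genes = 3L,
                                        n_plasmid_genes = 0L,
                                        n_isozyme_pairs = 0L,
                                        n_parallel_pathways = 0L))
  singles <- single_gene_deletion(lin$model)
  expect_true(all(singles$status == "lethal"))
})
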