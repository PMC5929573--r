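make_profiles <- function(gei, raw1 = NULL, raw2 = NULL, condition = "A",
                          length = rep(1000, base::length(gei))) {
  n <- base::length(gei)
  if (is.null(raw1)) raw1 <- round(gei * length / 2)
  if (is.null(raw2)) raw2 <- raw1
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), condition = condition,
             length = length, unique_sites = pmax(1, round(length / 25)),
             raw_rep1 = raw1, raw_rep2 = raw2,
             norm_rep1 = raw1, norm_rep2 = raw2, gei = gei,
             stringsAsFactors = FALSE)
}

test_that("only genes with zero reads in both replicates are auto-essential", {
  prof <- make_profiles(gei = c(0.002, 0.003, 1),
                        raw1 = c(0, 0, 400), raw2 = c(0, 1, 500))
  expect_equal(call_zero_insertion(prof), c(TRUE, FALSE, FALSE))
})

test_that("well-separated clusters map to groups I-V in mean order", {
  set.seed(1)
  lg <- c(rnorm(50, -3, 0.1), rnorm(50, -1.5, 0.1), rnorm(50, 0, 0.1),
          rnorm(50, 1, 0.1), rnorm(50, 2, 0.1))
  labels <- rep(1:5, each = 50)
  grp <- assign_groups(lg, labels)
  expect_equal(as.character(grp$group), rep(c("I", "II", "III", "IV", "V"),
                                            each = 50))
  # group severity is a monotone step function of GEI
  ord <- order(lg)
  expect_true(all(diff(as.integer(grp$group[ord])) >= 0))
})

test_that("the growth-improvement group requires a separation margin", {
  set.seed(2)
  lg <- c(rnorm(50, -3, 0.05), rnorm(50, -1.5, 0.05), rnorm(50, 0, 0.05),
          rnorm(100, 1, 0.05), rnorm(30, 1.1, 0.05))
  labels <- rep(1:5, c(50, 50, 50, 100, 30))
  grp <- assign_groups(lg, labels, v_margin = 0.25)
  expect_false("V" %in% grp$group)   # 0.1 apart: top cluster fuses into IV
  lg2 <- c(lg[1:250], rnorm(30, 1.6, 0.05))
  grp2 <- assign_groups(lg2, labels, v_margin = 0.25)
  expect_true("V" %in% grp2$group)
})

test_that("fewer clusters than groups collapse from the middle", {
  set.seed(3)
  lg <- c(rnorm(30, -3, 0.1), rnorm(30, -1, 0.1), rnorm(30, 1, 0.1))
  grp <- assign_groups(lg, rep(1:3, each = 30))
  expect_equal(sort(unique(as.character(grp$group))), c("I", "II", "IV"))
  grp2 <- assign_groups(lg, rep(c(1, 1, 2), each = 30))
  expect_equal(sort(unique(as.character(grp2$group))), c("I", "IV"))
})

test_that("zero-insertion genes are forced into Group I", {
  set.seed(4)
  lg <- c(rnorm(40, -3, 0.1), rnorm(40, 0, 0.1))
  zero <- c(rep(TRUE, 40), rep(FALSE, 40))
  grp <- assign_groups(lg, rep(1:2, each = 40), zero_insertion = zero)
  expect_true(all(grp$group[zero] == "I"))
  expect_true(all(grp$basis[zero] == "zero_insertion"))
})

test_that("classification recovers a planted three-class structure", {
  # three classes whose ordinal positions are unambiguous with three
  # clusters: essential (I), strong defect (II), neutral (IV)
  cfg <- small_sim_config(
    seed = 6L, n_genes = 400L, genome_length = 4e5,
    class_fractions = c(essential = 0.15, strong_defect = 0.2,
                        moderate_defect = 0, neutral = 0.65, improved = 0))
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg, conditions = "A")
  tabs <- simulate_library(ann, truth, cfg)
  prof <- gei_profiles(tabs, ann)
  calls <- classify_fitness(prof, seed = 1L)
  tg <- truth_group_map[truth$class[match(calls$gene_id, truth$gene_id)]]
  long <- ann$genes$length[match(calls$gene_id, ann$genes$gene_id)] >= 500
  acc <- mean(as.character(calls$group)[long] == tg[long])
  expect_gt(acc, 0.9)
  # essential simulated genes carry zero reads and are Group I
  ess <- truth$gene_id[truth$class == "essential"]
  expect_true(all(calls$group[calls$gene_id %in% ess] == "I"))
})

test_that("differential calls separate planted fold changes from nulls", {
  set.seed(7)
  n <- 300
  geiA <- 10^rnorm(n, 0.5, 0.1)
  geiB <- geiA * 10^rnorm(n, 0, 0.05)
  idx <- 1:40
  geiB[idx] <- geiA[idx] / 10^rnorm(40, 1.3, 0.05)  # ~20-fold lower in B
  pa <- make_profiles(geiA, condition = "A")
  pb <- make_profiles(geiB, condition = "B")
  dc <- call_differential(pa, pb, seed = 1L)
  expect_true(all(dc$call[idx] == "higher_in_A"))
  expect_lt(mean(dc$call[-idx] != "equal"), 0.02)
})

test_that("a gene essential only in the reduced strain is called differential", {
  # GEI profile like the chaperonin example: 2.926 in the wild type against
  # the 0.001 zero-insertion floor in the reduced strain
  set.seed(8)
  n <- 60
  geiA <- 10^rnorm(n, 0.3, 0.08)
  geiB <- geiA * 10^rnorm(n, 0, 0.04)
  geiA[1] <- 2.926
  geiB[1] <- 0.001
  dc <- call_differential(make_profiles(geiA, condition = "WT"),
                          make_profiles(geiB, condition = "dAB"), seed = 1L)
  expect_equal(dc$log10_fold_change[1], log10(2.926 / 0.001))
  expect_equal(dc$call[1], "higher_in_A")
})

test_that("identical conditions yield only equal calls", {
  set.seed(9)
  gei <- 10^rnorm(100, 0.5, 0.2)
  pa <- make_profiles(gei, condition = "A")
  pb <- make_profiles(gei, condition = "B")
  dc <- call_differential(pa, pb, seed = 1L)
  expect_true(all(dc$call == "equal"))
  expect_true(all(dc$log10_fold_change == 0))
})

test_that("mismatched gene sets are rejected with the missing ids", {
  pa <- make_profiles(10^rnorm(20), condition = "A")
  pb <- pa[-3, ]
  pb$condition <- "B"
  expect_error(call_differential(pa, pb, seed = 1L), "g0003")
})
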