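test_that("gene deletion closes exactly the reactions its GPR kills", {
  tm <- build_toy_model(toy_model_spec())
  m <- tm$model
  iso <- match("ISO01", m$rxns)
  # one isozyme partner: the OR rule keeps the reaction open
  d1 <- delete_genes(m, "gIC01")
  expect_equal(d1$ub[iso], m$ub[iso])
  # both partners close it
  d2 <- delete_genes(m, c("gIC01", "gIP01"))
  expect_equal(c(d2$lb[iso], d2$ub[iso]), c(0, 0))
  # a gene not in any GPR leaves the model untouched
  m2 <- m
  m2$genes <- rbind(m2$genes, data.frame(gene_id = "orphan",
                                         replicon = "chromosome"))
  expect_equal(delete_genes(m2, "orphan")$ub, m2$ub)
  expect_error(delete_genes(m, "nope"), "unknown gene")
})

test_that("single gene deletions recover the hand-computed grRatios", {
  par <- parallel_toy()
  singles <- single_gene_deletion(par$model)
  gr <- setNames(singles$grRatio, singles$gene_id)
  expect_equal(unname(gr["gC01"]), 0, tolerance = 1e-9)    # essential step
  expect_equal(unname(gr["gPC01"]), 0.4, tolerance = 1e-6) # lose 6-cap branch
  expect_equal(unname(gr["gPP01"]), 0.6, tolerance = 1e-6) # lose 4-cap branch
  st <- setNames(singles$status, singles$gene_id)
  expect_equal(unname(st[c("gC01", "gPC01", "gPP01")]),
               c("lethal", "defect", "defect"))
  iso <- build_toy_model(toy_model_spec(n_isozyme_pairs = 1L,
                                        n_chromosome_genes = 0L,
                                        n_plasmid_genes = 0L,
                                        n_parallel_pathways = 0L))
  s2 <- single_gene_deletion(iso$model)
  expect_true(all(s2$grRatio == 1))
  expect_true(all(s2$status == "no_effect"))
})

test_that("single reaction deletions mirror the gene screen", {
  par <- parallel_toy()
  res <- single_reaction_deletion(par$model)
  gr <- setNames(res$grRatio, res$reaction_id)
  expect_equal(unname(gr["BIOMASS"]), 0)
  expect_equal(unname(gr["PARB01"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(gr["EX_S"]), 0)
})

test_that("double deletions flag exactly the engineered interactions", {
  tm <- build_toy_model(toy_model_spec())
  doubles <- double_gene_deletion(tm$model)
  flagged <- doubles[doubles$synthetic_negative, c("gene_a", "gene_b")]
  truth <- tm$interactions[, c("gene_a", "gene_b")]
  key <- function(df) sort(paste(pmin(df$gene_a, df$gene_b),
                                 pmax(df$gene_a, df$gene_b)))
  expect_identical(key(flagged), key(truth))
  # sensitivity and specificity are both exactly 1
  expect_equal(nrow(flagged), nrow(truth))
  # expected grRatio is the product of the singles
  singles <- single_gene_deletion(tm$model)
  sgr <- setNames(singles$grRatio, singles$gene_id)
  expect_equal(doubles$grRatio_expected,
               unname(sgr[doubles$gene_a] * sgr[doubles$gene_b]),
               tolerance = 1e-9)
  # pair classes reflect the replicon tags
  iso_pair <- doubles[doubles$gene_a == "gIC01" & doubles$gene_b == "gIP01", ]
  expect_equal(iso_pair$pair_class, "chr-psym")
})

test_that("a lethal single neutralizes the expected product rule", {
  par <- parallel_toy()
  doubles <- double_gene_deletion(par$model,
                                  pairs = rbind(c("gC01", "gPC01")))
  expect_equal(doubles$grRatio_expected, 0)
  expect_false(doubles$synthetic_negative)
})

test_that("the epistasis flag is symmetric in pair order", {
  tm <- build_toy_model(toy_model_spec())
  d1 <- double_gene_deletion(tm$model, pairs = rbind(c("gIC01", "gIP01")))
  d2 <- double_gene_deletion(tm$model, pairs = rbind(c("gIP01", "gIC01")))
  expect_identical(d1$synthetic_negative, d2$synthetic_negative)
  expect_identical(d1$grRatio_observed, d2$grRatio_observed)
})

test_that("observed double grRatio never exceeds the smaller single", {
  tm <- build_toy_model(toy_model_spec())
  singles <- single_gene_deletion(tm$model)
  sgr <- setNames(singles$grRatio, singles$gene_id)
  doubles <- double_gene_deletion(tm$model, singles = singles)
  expect_true(all(doubles$grRatio_observed <=
                    pmin(sgr[doubles$gene_a], sgr[doubles$gene_b]) + 1e-6))
})

test_that("replicon removal keeps the model viable and shifts essentiality", {
  tm <- build_toy_model(toy_model_spec())
  red <- remove_replicon(tm$model, "pSym")
  expect_false(any(red$genes$replicon == "pSym"))
  expect_gt(fba(red)$objective_value, 0)
  # the chromosomal isozyme partner becomes essential without the plasmid copy
  expect_equal(single_gene_deletion(red, "gIC01")$grRatio, 0)
  # absent tag is an identity operation; removing everything kills growth
  expect_identical(remove_replicon(tm$model, "pXYZ"), tm$model)
  dead <- remove_replicon(remove_replicon(tm$model, "pSym"), "chromosome")
  expect_equal(fba(dead)$objective_value, 0, tolerance = 1e-9)
})

test_that("background comparison recovers the planted dependence structure", {
  tm <- build_toy_model(toy_model_spec())
  red <- remove_replicon(tm$model, "pSym")
  chr <- red$genes$gene_id
  full <- single_gene_deletion(tm$model, genes = chr)
  reduced <- single_gene_deletion(red, genes = chr)
  cmp <- compare_backgrounds(full, reduced)
  # hand enumeration: isozyme partners and the parallel chromosome branch
  # are more severe without the plasmid; backbone genes are lethal in both
  worse <- sort(cmp$gene_id[cmp$call == "more_severe_without"])
  expect_equal(worse, c("gIC01", "gIC02", "gPC01"))
  # all three are lethal only in the reduced background (the parallel
  # chromosome branch loses its 4-capacity bypass as well)
  expect_true(all(cmp$lethal_specific[cmp$gene_id %in% worse]))
  expect_false(any(cmp$lethal_specific[!cmp$gene_id %in% worse]))
  expect_true(all(cmp$call[cmp$gene_id %in% c("gC01", "gC02")] ==
                    "unchanged"))
  expect_error(compare_backgrounds(full, reduced[-1, ]), "differ")
})

test_that("MOMA-based screens agree with FBA on the lethal set", {
  par <- parallel_toy()
  f <- single_gene_deletion(par$model, method = "fba")
  m <- single_gene_deletion(par$model, method = "moma")
  expect_identical(f$gene_id, m$gene_id)
  expect_identical(f$status == "lethal", m$status == "lethal")
  expect_true(all(m$grRatio <= f$grRatio + 1e-6))
})
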