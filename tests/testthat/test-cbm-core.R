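test_that("GPR rules follow boolean semantics", {
  expect_false(evaluate_gpr("(g1 and g2)", "g1"))
  expect_true(evaluate_gpr("(g1 or g2)", "g1"))
  expect_false(evaluate_gpr("(g1 or g2)", c("g1", "g2")))
  expect_false(evaluate_gpr("(g1 and (g2 or g3))", c("g2", "g3")))
  expect_true(evaluate_gpr("(g1 and (g2 or g3))", "g2"))
  expect_true(evaluate_gpr("", c("g1")))        # empty rule: always active
  expect_true(evaluate_gpr("G1 AND g2", character()))  # case-insensitive ops
})

test_that("GPR evaluation matches an R boolean-expression oracle", {
  rules <- c("gA and gB", "gA or gB", "gA and (gB or gC)",
             "(gA and gB) or (gC and gD)", "gA or (gB and (gC or gD))")
  genes <- c("gA", "gB", "gC", "gD")
  for (rule in rules) {
    r_expr <- parse(text = gsub(" or ", " | ",
                                gsub(" and ", " & ", rule)))[[1]]
    for (mask in 0:15) {
      present <- genes[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
      deleted <- setdiff(genes, present)
      env <- as.list(setNames(genes %in% present, genes))
      expect_equal(evaluate_gpr(rule, deleted),
                   eval(r_expr, env),
                   info = sprintf("%s | deleted: %s", rule,
                                  paste(deleted, collapse = ",")))
    }
  }
})

test_that("GPR parse errors carry a position", {
  expect_error(evaluate_gpr("g1 and (g2 or", "g1"), "position")
  expect_error(evaluate_gpr("and g1", character()), "position")
})

test_that("FBA solves the closed-form toy networks", {
  par <- parallel_toy()
  sol <- fba(par$model)
  expect_equal(sol$objective_value, 10, tolerance = 1e-6)
  expect_lte(sol$residual, 1e-6)
  # block the 4-capacity branch
  m <- par$model
  m$ub[match("PARB01", m$rxns)] <- 0
  expect_equal(fba(m)$objective_value, 6, tolerance = 1e-6)
  # closing all exchanges kills growth
  m2 <- apply_medium(par$model, c(EX_S = 0))
  expect_equal(fba(m2)$objective_value, 0, tolerance = 1e-9)
})

test_that("the minimum-norm reference reproduces the FBA optimum deterministically", {
  par <- parallel_toy()
  ref <- fba_reference(par$model)
  expect_equal(ref$objective_value, 10, tolerance = 1e-6)
  # at uptake 10 the parallel branches are forced to their capacities
  expect_equal(unname(ref$fluxes[c("PARA01", "PARB01")]), c(6, 4),
               tolerance = 1e-6)
  ref2 <- fba_reference(par$model)
  expect_equal(ref$fluxes, ref2$fluxes)
})

test_that("MOMA with no deletion returns the reference flux", {
  par <- parallel_toy()
  ref <- fba_reference(par$model)
  sol <- moma(par$model, reference = ref)
  expect_equal(sol$fluxes, ref$fluxes, tolerance = 1e-6)
})

test_that("MOMA equals the brute-force quadratic projection oracle", {
  par <- parallel_toy()
  ref <- fba_reference(par$model)
  for (del in c("PARB01", "PARA01")) {
    sol <- moma(par$model, reference = ref, deleted_rxns = del)
    oracle <- moma_parallel_oracle(ref$fluxes, delete = del)
    expect_equal(unname(sol$fluxes[names(oracle$fluxes)]),
                 unname(oracle$fluxes), tolerance = 1e-4)
    expect_equal(sol$objective_value, oracle$growth, tolerance = 1e-4)
  }
})

test_that("MOMA growth never exceeds FBA growth for any knockout", {
  tm <- build_toy_model(toy_model_spec())
  ref <- fba_reference(tm$model)
  wt <- fba(tm$model)$objective_value
  for (g in tm$model$genes$gene_id) {
    m <- delete_genes(tm$model, g)
    f <- fba(m)$objective_value
    q <- moma(m, reference = ref)$objective_value
    expect_lte(q, f + 1e-6)
    expect_lte(f, wt + 1e-6)
  }
})

test_that("every optimal solution is mass balanced", {
  tm <- build_toy_model(toy_model_spec())
  S <- as.matrix(tm$model$S)
  for (g in c(NA, "gPC01", "gIC01")) {
    m <- if (is.na(g)) tm$model else delete_genes(tm$model, g)
    sol <- fba(m)
    expect_equal(sol$status, "optimal")
    expect_lte(max(abs(S %*% sol$fluxes)), 1e-6)
  }
})

test_that("SBML and tabular model files round-trip exactly", {
  tm <- build_toy_model(toy_model_spec())
  f <- tempfile(fileext = ".xml")
  write_sbml(tm$model, f)
  m2 <- read_sbml(f)
  for (field in c("mets", "rxns", "lb", "ub", "gpr", "genes", "objective")) {
    expect_identical(m2[[field]], tm$model[[field]], label = field)
  }
  expect_true(all(m2$S == tm$model$S))

  d <- tempfile()
  write_model_tab(tm$model, d)
  m3 <- read_model_tab(d)
  expect_identical(m3$gpr, tm$model$gpr)
  expect_identical(m3$lb, tm$model$lb)
  expect_true(all(m3$S == tm$model$S))

  # a second write of the re-read model is byte-identical
  f2 <- tempfile(fileext = ".xml")
  write_sbml(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("unknown metabolites in model files are reported by reaction", {
  tm <- build_toy_model(toy_model_spec())
  d <- tempfile()
  write_model_tab(tm$model, d)
  st <- read.delim(file.path(d, "stoichiometry.tsv"))
  st$metabolite[1] <- "ghost"
  write.table(st, file.path(d, "stoichiometry.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_model_tab(d), "ghost")
})

test_that("an SBML toy model is a valid flux model for an independent solver", {
  # cross-check the SBML writer and the FBA optimum against the reference
  # COBRA implementation available through the system python
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  have_cobra <- suppressWarnings(system2(
    py, c("-c", shQuote("import cobra")), stdout = FALSE, stderr = FALSE))
  skip_if(have_cobra != 0L, "cobra not importable")
  tm <- build_toy_model(toy_model_spec())
  f <- tempfile(fileext = ".xml")
  write_sbml(tm$model, f)
  script <- sprintf(
    "import cobra; m = cobra.io.read_sbml_model('%s'); print(m.slim_optimize())",
    f)
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE, stderr = FALSE)
  expect_equal(as.numeric(out[length(out)]),
               fba(tm$model)$objective_value, tolerance = 1e-6)
})

test_that("medium overrides change uptake bounds", {
  par <- parallel_toy()
  sol <- fba(par$model, medium = c(EX_S = -4))
  expect_equal(sol$objective_value, 4, tolerance = 1e-6)
  expect_error(apply_medium(par$model, c(EX_nope = -1)), "unknown reaction")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("medium:", "  EX_S: -2.5"), yml)
  med <- read_medium_yaml(yml)
  expect_equal(fba(par$model, medium = med)$objective_value, 2.5,
               tolerance = 1e-6)
})
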