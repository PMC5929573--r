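# Shared fixtures and independent oracles used across the test files.

# map from ground-truth fitness class to the fitness group it should recover
truth_group_map <- c(essential = "I", strong_defect = "II",
                     moderate_defect = "III", neutral = "IV", improved = "V")

# a small, fast simulation configuration for unit tests
small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 200L, genome_length = 2e5,
               median_sites_per_gene = 39L, read_depth = 2e6, seed = seed)
  do.call(sim_config, modifyList(args, list(...)))
}

# an insertion_table built directly from vectors
make_table <- function(position, count, sample_id = "s1", condition = "c1",
                       replicate = 1L,
                       strand = rep("+", length(position))) {
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = replicate,
                 records = data.frame(position = position, strand = strand,
                                      count = count,
                                      stringsAsFactors = FALSE)),
            class = "insertion_table")
}

# a minimal annotation from a gene coordinate table (non-overlapping, sorted)
make_annotation <- function(start, end, strand = rep("+", length(start)),
                            genome_length = max(end) + 100,
                            category = rep("translation", length(start))) {
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_along(start)),
    replicon = "chromosome", start = start, end = end, strand = strand,
    length = end - start + 1, category = category, stringsAsFactors = FALSE
  )
  gaps <- data.frame(start = c(1, end + 1),
                     end = c(start - 1, genome_length))
  gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
  structure(list(genes = genes, intergenic = gaps,
                 genome_length = genome_length), class = "tn_annotation")
}

# brute-force grid-search oracle for the 2-component equal-variance mixture
# log-likelihood; returns the maximum log-likelihood found on the grid
gmm2_grid_loglik <- function(x, mean_step = 0.05, weight_step = 0.05) {
  mu_grid <- seq(min(x), max(x), by = mean_step)
  w_grid <- seq(weight_step, 1 - weight_step, by = weight_step)
  sd_grid <- seq(0.5, 2, by = 0.1) * sd(x) / 2
  best <- -Inf
  for (s in sd_grid) {
    d <- outer(x, mu_grid, function(xi, m) dnorm(xi, m, s))
    for (w in w_grid) {
      # loglik for every (mu1, mu2) pair via matrix algebra
      for (j1 in seq_along(mu_grid)) {
        mix <- w * d[, j1] + (1 - w) * d
        ll <- colSums(log(mix))
        m <- max(ll)
        if (m > best) best <- m
      }
    }
  }
  best
}

# brute-force quadratic projection oracle for MOMA on the single
# parallel-pathway toy model (1 degree of freedom after a branch deletion):
# fluxes are (EX_S, CHR01, PARA01, PARB01, BIOMASS) = (-u, u, a, b, u)
moma_parallel_oracle <- function(ref, delete = c("PARB01", "PARA01"),
                                 step = 1e-5) {
  delete <- match.arg(delete)
  cap <- if (delete == "PARB01") 6 else 4
  u <- seq(0, cap, by = step)
  if (delete == "PARB01") {
    obj <- (-u - ref["EX_S"])^2 + (u - ref["CHR01"])^2 +
      (u - ref["PARA01"])^2 + (0 - ref["PARB01"])^2 +
      (u - ref["BIOMASS"])^2
  } else {
    obj <- (-u - ref["EX_S"])^2 + (u - ref["CHR01"])^2 +
      (0 - ref["PARA01"])^2 + (u - ref["PARB01"])^2 +
      (u - ref["BIOMASS"])^2
  }
  i <- which.min(obj)
  ustar <- u[i]
  fluxes <- c(EX_S = -ustar, CHR01 = ustar,
              PARA01 = if (delete == "PARB01") ustar else 0,
              PARB01 = if (delete == "PARA01") ustar else 0,
              BIOMASS = ustar)
  list(fluxes = fluxes, objective = obj[i], growth = ustar)
}

# toy model with a single parallel pathway and one essential upstream gene
parallel_toy <- function() {
  build_toy_model(toy_model_spec(n_chromosome_genes = 1L,
                                 n_plasmid_genes = 0L,
                                 n_isozyme_pairs = 0L,
                                 n_parallel_pathways = 1L))
}
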