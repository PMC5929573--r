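#' Effective gene window after 3' trimming
#'
#' Insertions in the 3'-most 5% of a gene often escape selection (truncated
#' but functional protein), so reads mapping there are discarded. The trim is
#' \code{floor(0.05 * length)} nucleotides taken from the 3' end, which is the
#' high-coordinate end for + strand genes and the low-coordinate end for
#' - strand genes. Insertions exactly on a window boundary belong to the
#' window (closed interval).
#'
#' @param gene One-row data.frame or list with \code{start}, \code{end},
#'   \code{strand} (and optionally \code{length}).
#' @return Numeric vector \code{c(start, end)} of the retained window.
#' @export
effective_gene_window <- function(gene) {
  start <- as.numeric(gene$start)
  end <- as.numeric(gene$end)
  if (is.na(start) || is.na(end) || start > end) {
    stopf("invalid gene interval [%s, %s]", start, end)
  }
  len <- end - start + 1
  trim <- floor(0.05 * len)
  if (identical(as.character(gene$strand), "-")) {
    c(start + trim, end)
  } else {
    c(start, end - trim)
  }
}

# vectorized windows for an annotation; returns data.frame(wstart, wend)
effective_windows <- function(genes) {
  len <- genes$end - genes$start + 1
  trim <- floor(0.05 * len)
  minus <- genes$strand == "-"
  data.frame(wstart = ifelse(minus, genes$start + trim, genes$start),
             wend = ifelse(minus, genes$end, genes$end - trim))
}

#' Normalize samples to a common intergenic read density
#'
#' Tn-seq read totals differ between samples for technical reasons; reads in
#' intergenic regions are assumed selectively neutral, so each sample is
#' rescaled by a single factor that equalizes its intergenic read density
#' (reads per intergenic nucleotide) to the across-sample median density.
#'
#' @param tables Named list of \code{insertion_table} objects.
#' @param intergenic Data.frame of intergenic intervals (start, end).
#' @return List with \code{tables} (scaled copies; counts become fractional)
#'   and \code{factors} (named numeric scale factors).
#' @export
normalize_samples <- function(tables, intergenic) {
  if (length(tables) == 0) stopf("no samples to normalize")
  ig_nt <- sum(intergenic$end - intergenic$start + 1)
  if (ig_nt <= 0) stopf("intergenic intervals are empty")
  ig_sorted <- intergenic[order(intergenic$start), , drop = FALSE]
  density <- vapply(tables, function(tab) {
    pos <- tab$records$position
    idx <- findInterval(pos, ig_sorted$start)
    inter <- idx > 0 & pos <= ig_sorted$end[pmax(idx, 1L)]
    s <- sum(tab$records$count[inter])
    if (s <= 0) {
      stopf("sample '%s' has no intergenic reads; cannot normalize",
            tab$sample_id)
    }
    s / ig_nt
  }, numeric(1))
  anchor <- median(density)
  factors <- anchor / density
  scaled <- Map(function(tab, f) {
    tab$records$count <- tab$records$count * f
    tab
  }, tables, factors)
  names(scaled) <- names(tables)
  list(tables = scaled, factors = factors)
}

#' Gene essentiality index for one gene
#'
#' GEI = ((c1 + 1) + (c2 + 1)) / length: a pseudocount of one is added to each
#' replicate's normalized read count, the two are summed and divided by the
#' gene length in nucleotides. A gene with no insertions therefore has GEI
#' exactly 2/length (0.002 for a 1-kb gene, 0.001 for a 2-kb gene).
#'
#' @param c1,c2 Normalized read counts of the two replicates, aggregated over
#'   the effective gene window.
#' @param length Gene length in nucleotides (full length, not the trimmed
#'   window).
#' @return GEI score (reads per nucleotide).
#' @export
compute_gei <- function(c1, c2, length) {
  if (any(length <= 0)) stopf("gene length must be positive")
  ((c1 + 1) + (c2 + 1)) / length
}

# aggregate counts of one insertion table over gene windows;
# returns list(counts, sites): per-gene totals and unique-site positions mask
aggregate_counts <- function(tab, windows) {
  pos <- tab$records$position
  cnt <- tab$records$count
  idx <- findInterval(pos, windows$wstart)
  ok <- idx > 0 & pos <= windows$wend[pmax(idx, 1L)]
  counts <- numeric(nrow(windows))
  agg <- rowsum(cnt[ok], group = idx[ok])
  counts[as.integer(rownames(agg))] <- agg[, 1L]
  list(counts = counts, gene_of = idx[ok], pos = pos[ok])
}

#' Per-gene GEI profiles for every condition
#'
#' Runs the full scoring chain on a set of insertion tables: intergenic
#' normalization across all samples, aggregation of read counts over
#' 3'-trimmed gene windows, and GEI computation per condition from the two
#' replicates. Raw (unnormalized) per-replicate totals are retained because
#' the zero-insertion essentiality rule operates on raw reads.
#'
#' @param tables Named list of \code{insertion_table} objects covering one or
#'   more conditions, two replicates each.
#' @param annotation A \code{tn_annotation}.
#' @param normalize Apply intergenic normalization (default TRUE).
#' @return Data.frame of class \code{gei_profile}: gene_id, condition, length,
#'   unique_sites, raw_rep1, raw_rep2, norm_rep1, norm_rep2, gei.
#' @export
gei_profiles <- function(tables, annotation, normalize = TRUE) {
  stopifnot(inherits(annotation, "tn_annotation"))
  genes <- annotation$genes
  windows <- effective_windows(genes)
  if (normalize && length(tables) > 1) {
    norm <- normalize_samples(tables, annotation$intergenic)
    scaled <- norm$tables
  } else {
    scaled <- tables
  }
  conditions <- unique(vapply(tables, `[[`, character(1), "condition"))
  out <- lapply(conditions, function(cond) {
    sel <- vapply(tables, function(t) t$condition == cond, logical(1))
    reps <- vapply(tables[sel], `[[`, numeric(1), "replicate")
    if (length(reps) != 2L) {
      stopf("condition '%s' needs exactly 2 replicates, found %d",
            cond, length(reps))
    }
    ord <- order(reps)
    raw_tabs <- tables[sel][ord]
    norm_tabs <- scaled[sel][ord]
    raw1 <- aggregate_counts(raw_tabs[[1L]], windows)
    raw2 <- aggregate_counts(raw_tabs[[2L]], windows)
    nrm1 <- aggregate_counts(norm_tabs[[1L]], windows)
    nrm2 <- aggregate_counts(norm_tabs[[2L]], windows)
    usites <- numeric(nrow(genes))
    tab <- rowsum(rep(1L, length(c(raw1$pos, raw2$pos))),
                  group = c(raw1$gene_of, raw2$gene_of))
    # unique positions across the union of both replicates
    u <- unique(data.frame(g = c(raw1$gene_of, raw2$gene_of),
                           p = c(raw1$pos, raw2$pos)))
    cnt <- table(u$g)
    usites[as.integer(names(cnt))] <- as.integer(cnt)
    data.frame(gene_id = genes$gene_id, condition = cond,
               length = genes$length, unique_sites = usites,
               raw_rep1 = raw1$counts, raw_rep2 = raw2$counts,
               norm_rep1 = nrm1$counts, norm_rep2 = nrm2$counts,
               gei = compute_gei(nrm1$counts, nrm2$counts, genes$length),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("gei_profile", "data.frame")
  res
}

#' Position frequency matrix around insertion sites
#'
#' Summarizes the sequence context of unique insertion positions: the
#' \code{flank} nucleotides before the insertion site, the 9-nt target
#' duplication created by the transposon (columns D1..D9, starting at the
#' insertion position), and the \code{flank} nucleotides after it. Each
#' column of the returned matrix is a base-frequency distribution summing
#' to 1.
#'
#' @param tables Named list of \code{insertion_table} objects (unique
#'   positions are pooled over tables).
#' @param genome_seq Genome sequence as a single character string (circular;
#'   offsets wrap around).
#' @param flank Number of flanking positions on each side (default 10).
#' @return 4 x (2*flank + 9) column-stochastic matrix with rows A, C, G, T.
#' @export
insertion_site_matrix <- function(tables, genome_seq, flank = 10L) {
  pos <- unique(unlist(lapply(tables, function(t) t$records$position)))
  if (length(pos) == 0) stopf("no insertion positions supplied")
  gl <- nchar(genome_seq)
  chars <- strsplit(genome_seq, "", fixed = TRUE)[[1L]]
  offsets <- c(-(flank:1), 0:8, 9 + (0:(flank - 1L)))
  labels <- c(sprintf("-%d", flank:1), sprintf("D%d", 1:9),
              sprintf("+%d", 1:flank))
  bases <- c("A", "C", "G", "T")
  pfm <- matrix(0, nrow = 4L, ncol = length(offsets),
                dimnames = list(bases, labels))
  for (j in seq_along(offsets)) {
    p <- ((pos - 1 + offsets[j]) %% gl) + 1
    tab <- table(factor(chars[p], levels = bases))
    pfm[, j] <- as.numeric(tab) / sum(tab)
  }
  pfm
}
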