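# Reciprocal best-hit ortholog calling from BLAST tabular (outfmt 6) files.

blast_outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' @param path Path to a 12-column tab-separated BLAST output file.
#' @return Data.frame with the standard outfmt-6 columns.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("'%s' contains no hits", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12L)) {
    stopf("malformed BLAST tabular row at line %d of '%s' (%d fields, need 12)",
          which(nfield != 12L)[1L], path, nfield[nfield != 12L][1L])
  }
  m <- do.call(rbind, parts)
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- blast_outfmt6_cols
  num_cols <- blast_outfmt6_cols[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      stopf("non-numeric '%s' at line %d of '%s'",
            cc, which(is.na(v))[1L], path)
    }
    df[[cc]] <- v
  }
  df
}

# best hit per query: highest bitscore, ties broken by identity then
# lexicographic subject id; multiple HSPs per pair collapse to the best one
best_hits <- function(hits) {
  ord <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  h <- hits[ord, ]
  h[!duplicated(h$qseqid), ]
}

#' Reciprocal best-hit ortholog pairs from precomputed BLAST tables
#'
#' A pair (a, b) is reported when a's top bit-score hit in the other proteome
#' is b and b's top hit is a, and the aligned region passes the identity and
#' coverage thresholds (defaults: at least 30 percent amino acid identity
#' over at least 60 percent of the protein). Coverage is computed against the
#' shorter protein by default; ties in bit score are broken by identity and
#' then lexicographic subject id.
#'
#' @param hits_ab,hits_ba BLAST outfmt-6 files or data.frames (A vs B and
#'   B vs A).
#' @param protein_lengths Data.frame with columns \code{id} and \code{length}
#'   (amino acids) covering every protein appearing in the hits.
#' @param min_identity Minimum percent identity (default 30).
#' @param min_coverage Minimum aligned fraction (default 0.6).
#' @param coverage_ref Protein whose length anchors coverage: "shorter"
#'   (default), "query" or "subject".
#' @return Data.frame of class \code{ortholog_pairs}: gene_a, gene_b,
#'   identity, coverage, bitscore, sorted by gene_a.
#' @export
reciprocal_best_hit <- function(hits_ab, hits_ba, protein_lengths,
                                min_identity = 30, min_coverage = 0.6,
                                coverage_ref = c("shorter", "query",
                                                 "subject")) {
  coverage_ref <- match.arg(coverage_ref)
  if (is.character(hits_ab)) hits_ab <- read_blast_tab(hits_ab)
  if (is.character(hits_ba)) hits_ba <- read_blast_tab(hits_ba)
  plen <- setNames(protein_lengths$length, protein_lengths$id)
  ids <- unique(c(hits_ab$qseqid, hits_ab$sseqid,
                  hits_ba$qseqid, hits_ba$sseqid))
  missing <- setdiff(ids, names(plen))
  if (length(missing)) {
    stopf("no protein length for: %s", paste(head(missing, 5L),
                                             collapse = ", "))
  }
  ab <- best_hits(hits_ab)
  ba <- best_hits(hits_ba)
  back <- setNames(ba$sseqid, ba$qseqid)
  mutual <- ab[!is.na(back[ab$sseqid]) & back[ab$sseqid] == ab$qseqid, ,
               drop = FALSE]
  if (nrow(mutual) == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("ortholog_pairs", "data.frame")
    return(out)
  }
  ref_len <- switch(coverage_ref,
                    shorter = pmin(plen[mutual$qseqid], plen[mutual$sseqid]),
                    query = plen[mutual$qseqid],
                    subject = plen[mutual$sseqid])
  coverage <- mutual$length / ref_len
  keep <- mutual$pident >= min_identity & coverage >= min_coverage
  out <- data.frame(gene_a = mutual$qseqid[keep],
                    gene_b = mutual$sseqid[keep],
                    identity = mutual$pident[keep],
                    coverage = unname(coverage[keep]),
                    bitscore = mutual$bitscore[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), ]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}
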