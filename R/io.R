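# Reading and writing the pipeline's standard file formats:
# GFF3 gene annotations, TSV insertion tables, JSON truth files,
# per-condition GEI/classification TSVs and BED insertion tracks.

#' Write a gene annotation to GFF3
#'
#' @param annotation A \code{tn_annotation}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$category <- genes$category
  GenomeInfoDb::seqlengths(gr) <-
    setNames(rep(as.integer(annotation$genome_length),
                 length(unique(genes$replicon))),
             unique(genes$replicon))
  rtracklayer::export.gff3(gr, path)
  # keep the replicon length in the header so the intergenic complement can
  # be reconstructed on reading
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", unique(genes$replicon),
                    as.integer(annotation$genome_length))
  writeLines(append(lines, pragma, after = 1L), path)
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Intergenic intervals are reconstructed as the complement of the gene
#' intervals over \code{[1, genome_length]}.
#'
#' @param path GFF3 file (gene features with ID and category attributes).
#' @param genome_length Replicon length; if NULL, taken from the GFF3
#'   sequence-region pragma or the last gene end.
#' @return A \code{tn_annotation}.
#' @export
read_annotation_gff3 <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  gr <- gr[order(GenomicRanges::start(gr))]
  if (is.null(genome_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (!all(is.na(sl))) {
      genome_length <- max(sl, na.rm = TRUE)
    } else {
      header <- grep("^##sequence-region", readLines(path, n = 50L),
                     value = TRUE)
      genome_length <- if (length(header)) {
        max(as.numeric(vapply(strsplit(header, "\\s+"), `[`, character(1),
                              4L)))
      } else {
        max(GenomicRanges::end(gr))
      }
    }
  }
  genes <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr),
    category = if (!is.null(S4Vectors::mcols(gr)$category))
      S4Vectors::mcols(gr)$category else NA_character_,
    stringsAsFactors = FALSE
  )
  gaps <- data.frame(start = c(1, genes$end + 1),
                     end = c(genes$start - 1, genome_length))
  gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
  structure(list(genes = genes, intergenic = gaps,
                 genome_length = genome_length),
            class = "tn_annotation")
}

#' Write an insertion table to TSV (columns: position, strand, count)
#'
#' @param table An \code{insertion_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_insertion_tsv <- function(table, path) {
  write.table(table$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an insertion table from TSV
#'
#' @param path TSV with columns position, strand, count.
#' @param sample_id,condition,replicate Sample metadata.
#' @return An \code{insertion_table}.
#' @export
read_insertion_tsv <- function(path, sample_id, condition, replicate) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "strand", "count")
  if (!all(need %in% names(rec))) {
    stopf("'%s' must have columns: %s", path, paste(need, collapse = ", "))
  }
  if (any(rec$count < 0)) stopf("negative read count in '%s'", path)
  if (anyDuplicated(rec$position)) {
    stopf("duplicate insertion positions in '%s'", path)
  }
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = replicate, records = rec[, need]),
            class = "insertion_table")
}

#' Write insertion positions of a sample as BED
#'
#' @param table An \code{insertion_table}.
#' @param path Output path.
#' @param chrom Chromosome name used in the BED records.
#' @return \code{path}, invisibly.
#' @export
write_insertion_bed <- function(table, path, chrom = "chromosome") {
  rec <- table$records
  bed <- data.frame(chrom = chrom, start = rec$position - 1L,
                    end = rec$position, name = table$sample_id,
                    score = rec$count, strand = rec$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read fitness ground truth as JSON
#'
#' @param truth A \code{fitness_truth} data.frame.
#' @param path File path.
#' @return \code{path} (write) or the truth data.frame (read).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  truth <- jsonlite::fromJSON(path)
  class(truth) <- c("fitness_truth", "data.frame")
  truth
}

#' Write per-condition GEI profiles to TSV
#'
#' @param profiles A \code{gei_profile} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gei_tsv <- function(profiles, path) {
  write.table(profiles[, c("gene_id", "condition", "gei", "unique_sites")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
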