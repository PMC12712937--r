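#' Read a FASTA file into a named vector of uppercase sequences
#'
#' Sequences are normalised to uppercase over the alphabet \{A,C,G,T,N\}.
#' IUPAC ambiguity codes other than N (R, Y, S, W, K, M, B, D, H, V) are
#' collapsed to N with a warning rather than dropped, so coordinates are
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are the FASTA record ids (first
#'   whitespace-delimited token of each header), values the sequences.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contain ambiguity codes other than N; ",
            "converted to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) > 0L, !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read genomic intervals from BED or a 1-based tabular dialect
#'
#' All intervals are stored 0-based half-open internally. The `tsv` dialect
#' is 1-based closed (as in GFF-style tables) and is converted at the
#' boundary.
#'
#' @param path Path to the interval file.
#' @param dialect `"bed"` (0-based half-open, no header) or `"tsv"`
#'   (1-based closed, header row with columns chrom, start, end and
#'   optionally id).
#' @return data.frame with columns `chrom`, `start`, `end`, `id`.
#' @export
read_intervals <- function(path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    names(x) <- c("chrom", "start", "end", "id", "score",
                  "strand")[seq_len(min(ncol(x), 6L))]
    if (!"id" %in% names(x)) x$id <- paste0("region_", seq_len(nrow(x)))
  } else {
    x <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    names(x) <- tolower(names(x))
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    x$start <- x$start - 1L  # 1-based closed -> 0-based half-open
    if (!"id" %in% names(x)) x$id <- paste0("region_", seq_len(nrow(x)))
  }
  x <- x[, c("chrom", "start", "end", "id")]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(x$start < 0L)) stop("negative interval start")
  if (any(x$start >= x$end)) stop("interval with start >= end")
  x
}

#' Write intervals as BED
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `id` (0-based
#'   half-open).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read gene and LTR feature starts from GFF3 or a tabular file
#'
#' For GFF3 input (1-based closed), the transcription start is the leftmost
#' coordinate for + strand features and the rightmost for - strand features,
#' converted to 0-based. Tabular input (`.tsv`) must carry a header with
#' columns chrom, pos (0-based), strand, feature_id, feature_type.
#'
#' @param path Path to a `.gff`/`.gff3` or `.tsv` file.
#' @param feature_types GFF3 `type` values to keep, mapped to the two
#'   recognised classes: types containing "gene" become `gene`, types
#'   containing "long_terminal_repeat" or "LTR" become `LTR`.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `feature_id`,
#'   `feature_type`.
#' @export
read_feature_starts <- function(path,
                                feature_types = c("gene", "long_terminal_repeat")) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path)
    g <- g[as.character(g$type) %in% feature_types]
    if (length(g) == 0L) stop("no gene/LTR features in ", path)
    strand <- as.character(GenomicRanges::strand(g))
    if (any(!strand %in% c("+", "-"))) stop("unknown strand symbol in ", path)
    pos <- ifelse(strand == "+",
                  GenomicRanges::start(g) - 1L,  # 1-based -> 0-based
                  GenomicRanges::end(g) - 1L)    # rightmost base for - strand
    id <- g$ID
    if (is.null(id)) id <- g$Name
    if (is.null(id)) id <- paste0("feature_", seq_along(g))
    type <- ifelse(grepl("gene", as.character(g$type)), "gene", "LTR")
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                      pos = as.integer(pos), strand = strand,
                      feature_id = as.character(id), feature_type = type,
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "strand", "feature_id", "feature_type")
                  %in% names(out)))
    if (any(!out$strand %in% c("+", "-"))) stop("unknown strand symbol")
    out$pos <- as.integer(out$pos)
  }
  rownames(out) <- NULL
  out
}

#' Read a differential-expression contrast table
#'
#' @param path TSV with header columns `gene`, `lfc` (shrunk log2
#'   fold-change) and `padj`; missing padj is treated as non-significant.
#' @return data.frame with those three columns.
#' @export
read_contrast_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "lfc", "padj") %in% names(x)))
  if (anyDuplicated(x$gene)) stop("duplicate gene ids in ", path)
  x[, c("gene", "lfc", "padj")]
}

#' Read per-strand tag coverage from a bedGraph file
#'
#' @param path bedGraph path (chrom, start, end, count; 0-based half-open).
#' @return data.frame with columns `chrom`, `start`, `end`, `count`.
#' @export
read_bedgraph <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "count"),
                         stringsAsFactors = FALSE)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x
}

#' Write per-strand tag coverage as bedGraph
#'
#' @param cov data.frame with `chrom`, `start`, `end`, `count`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(cov, path) {
  utils::write.table(cov[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
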