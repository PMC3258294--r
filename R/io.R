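#' Read and write the pipeline's on-disk formats
#'
#' Thin wrappers around Biostrings and rtracklayer for sequence and
#' annotation formats, and around base R for the tabular formats: BLAST
#' tabular (outfmt 6), the gene-by-library count table, the qPCR Ct
#' table, and JSON manifests. All writers are deterministic: the same
#' object always produces byte-identical files.
#'
#' @param x Object to write (see individual functions).
#' @param path File path.
#' @name pipeline-io
NULL

#' @describeIn pipeline-io Write a named character vector (or
#'   `DNAStringSet`) as FASTA.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn pipeline-io Read FASTA into a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @describeIn pipeline-io Write a read table (see [read_table()]) as
#'   FASTQ (Phred+33). The library label is not stored in the file;
#'   supply it again on reading.
#' @export
write_fastq <- function(x, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$id))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(x$qual))
  invisible(path)
}

#' @describeIn pipeline-io Read FASTQ into a read table.
#' @param library Library label to attach to every read.
#' @export
read_fastq <- function(path, library = NA_character_) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  read_table(id = names(dna), seq = as.character(dna),
             qual = as.character(S4Vectors::mcols(dna)$qualities),
             library = library)
}

#' @describeIn pipeline-io Write mRNA annotations (data frame with
#'   `seqid`, `start`, `end`, `strand`, `type`, `ID`) as GFF3.
#' @export
write_gff3 <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$seqid,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = x$strand %||% "+")
  gr$type <- x$type
  gr$ID <- x$ID
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @describeIn pipeline-io Read GFF3 into the annotation data frame.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type),
             ID = as.character(gr$ID),
             stringsAsFactors = FALSE)
}

outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' @describeIn pipeline-io Read a 12-column BLAST tabular (outfmt 6 /
#'   m8) file.
#' @export
read_hits <- function(path) {
  h <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) != 12L) stop("expected 12 outfmt-6 columns, got ", ncol(h))
  names(h) <- outfmt6_cols
  h
}

#' @describeIn pipeline-io Write a hit table as outfmt 6 (no header).
#' @export
write_hits <- function(x, path) {
  utils::write.table(x[, outfmt6_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn pipeline-io Write a count table (`gene_id`, `length`,
#'   `count_DI`, `count_NDI`) as TSV; library sizes, when attached as
#'   `attr(x, "library_sizes")`, are stored in a header comment.
#' @export
write_counts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ls <- attr(x, "library_sizes")
  if (!is.null(ls)) {
    writeLines(sprintf("# library_sizes\tDI=%d\tNDI=%d",
                       as.integer(ls[["DI"]]), as.integer(ls[["NDI"]])), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn pipeline-io Read a count table written by
#'   [write_counts()].
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "# library_sizes")) {
    f <- strsplit(sub("^# library_sizes\t", "", first), "\t")[[1]]
    v <- vapply(strsplit(f, "="), function(p) as.numeric(p[2]), numeric(1))
    names(v) <- vapply(strsplit(f, "="), `[`, character(1), 1)
    attr(x, "library_sizes") <- v
  }
  x
}

#' @describeIn pipeline-io Write a qPCR Ct table (`gene_id`, `role`,
#'   `treatment`, `bio_rep`, `tech_rep`, `ct`) as CSV.
#' @export
write_ct <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn pipeline-io Read a qPCR Ct table.
#' @export
read_ct <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @describeIn pipeline-io Write any list-like manifest as JSON.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @describeIn pipeline-io Read a JSON manifest.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
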