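`%||%` <- function(x, y) if (is.null(x)) y else x

# Phred+33 encoding helpers; scores are plain integers
phred_decode <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)

phred_encode <- function(scores) {
  vapply(scores, function(s) intToUtf8(as.integer(s) + 33L, multiple = FALSE),
         character(1))
}

mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1))
}

random_dna <- function(n, lengths) {
  lengths <- rep_len(lengths, n)
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

gc_percent <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  as.numeric(Biostrings::letterFrequency(x, "GC", as.prob = TRUE)) * 100
}

#' Construct a read table
#'
#' Reads are kept in a plain data frame with one row per read: the id,
#' the nucleotide sequence, the Phred+33-encoded quality string, and the
#' sequencing-library label (`"DI"` or `"NDI"` in the two-photoperiod
#' design, but any label is accepted).
#'
#' @param id Character vector of read identifiers (must be unique).
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @param qual Character vector of Phred+33 quality strings, one
#'   character per base.
#' @param library Library label(s), recycled along reads.
#' @return A `data.frame` with columns `id`, `seq`, `qual`, `library`.
#' @export
read_table <- function(id, seq, qual, library = NA_character_) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (anyDuplicated(id)) stop("read ids must be unique")
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop("sequence and quality lengths differ for read(s): ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  }
  data.frame(id = as.character(id), seq = toupper(as.character(seq)),
             qual = as.character(qual),
             library = rep_len(as.character(library), length(id)),
             stringsAsFactors = FALSE)
}
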