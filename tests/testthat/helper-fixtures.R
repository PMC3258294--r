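# shared fixture builders and independent oracles

q40 <- function(n) strrep(intToUtf8(40 + 33), n)

mk_reads <- function(seqs, quals = NULL, ids = NULL, library = "DI") {
  ids <- ids %||% sprintf("r%03d", seq_along(seqs))
  quals <- quals %||% vapply(nchar(seqs), q40, character(1))
  diapauseTx::read_table(ids, seqs, quals, library)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

mk_hit <- function(qseqid, sseqid, pident = 99, length = 100,
                   qstart = 1, qend = length, sstart = 1, send = length,
                   evalue = 1e-50, bitscore = 200, mismatch = 0,
                   gapopen = 0) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = mismatch, gapopen = gapopen,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# exhaustive re-statement of the representative-selection rule,
# scoring every member independently of the vectorised implementation
oracle_select <- function(group, min_identity) {
  best <- NULL
  better <- function(a, b, keys) {
    # TRUE if a beats b: larger wins on numeric keys, earlier wins on est_id
    for (k in keys) {
      if (k == "est_id") {
        if (a[[k]] < b[[k]]) return(TRUE)
        if (a[[k]] > b[[k]]) return(FALSE)
      } else {
        if (a[[k]] > b[[k]]) return(TRUE)
        if (a[[k]] < b[[k]]) return(FALSE)
      }
    }
    FALSE
  }
  if (min_identity > 0) {
    qual <- group[group$pident >= min_identity, , drop = FALSE]
    pool <- if (nrow(qual) > 0) qual else group
    keys <- if (nrow(qual) > 0) c("aln_length", "pident", "est_id")
            else c("pident", "aln_length", "est_id")
  } else {
    pool <- group[group$aln_length >= 50, , drop = FALSE]
    if (nrow(pool) == 0) return(NULL)
    keys <- c("pident", "aln_length", "est_id")
  }
  for (i in seq_len(nrow(pool))) {
    row <- pool[i, ]
    if (is.null(best) || better(row, best, keys)) best <- row
  }
  best
}

random_group <- function(n, id_prefix = "e") {
  data.frame(est_id = paste0(id_prefix, sample(100:999, n)),
             gene_id = "g1", tier = "Ae_aegypti_transcripts",
             pident = round(stats::runif(n, 60, 100), 1),
             aln_length = sample(30:800, n, replace = TRUE),
             qstart = 1L, qend = 1L, sstart = 1L, send = 1L,
             evalue = 1e-40, bitscore = 100,
             stringsAsFactors = FALSE)
}
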