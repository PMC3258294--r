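#' Simulate a read set with labelled QC defects
#'
#' Draws clean reads as substrings of the reference genes with high
#' base qualities, then injects mutually exclusive defects at the
#' requested rates: reads with an ambiguous base (`N`), exact
#' duplicates of an earlier read, reads with mean Phred quality below
#' 25, contaminant-origin reads (random sequence, also emitted as rows
#' of a contaminant hit table with e-values at or below 1e-25),
#' poly-A/T tailed reads, and reads shorter than 50 bp. The manifest
#' labels every read with its defect so the QC report can be checked
#' against the injection bookkeeping.
#'
#' @param ref A `"synthetic_reference"` from [simulate_reference()].
#' @param n_reads Total number of reads across both libraries.
#' @param defect_rates Named rates in `[0, 1]` for `ambiguous`,
#'   `duplicate`, `low_quality`, `contaminant`, `polyat`, `short`;
#'   their sum must be <= 1, the remainder is clean.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_reads"`: `reads` (read table),
#'   `manifest` (`read_id`, `library`, `defect`), and
#'   `contaminant_hits` (outfmt-6 data frame).
#' @export
simulate_qc_reads <- function(ref, n_reads = 1000,
                              defect_rates = c(ambiguous = 0.03,
                                               duplicate = 0.03,
                                               low_quality = 0.03,
                                               contaminant = 0.02,
                                               polyat = 0.05,
                                               short = 0.02),
                              seed = 1) {
  stopifnot(inherits(ref, "synthetic_reference"))
  defects <- c("ambiguous", "duplicate", "low_quality", "contaminant",
               "polyat", "short")
  rates <- stats::setNames(rep(0, length(defects)), defects)
  rates[names(defect_rates)] <- defect_rates
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("defect rates must lie in [0, 1] and sum to <= 1")
  }
  genes <- ref$sequences
  withr::with_seed(seed, {
    labels <- sample(c(defects, "none"), n_reads, replace = TRUE,
                     prob = c(rates, 1 - sum(rates)))
    # a duplicate needs an earlier clean read to copy
    if (labels[1] == "duplicate") labels[1] <- "none"

    qual_hi <- function(L) phred_encode(list(sample(30:40, L, TRUE)))
    qual_lo <- function(L) phred_encode(list(sample(10:24, L, TRUE)))
    draw_clean <- function() {
      g <- sample(names(genes), 1)
      L <- nchar(genes[[g]])
      rl <- sample(60:min(L, 350), 1)
      s <- sample.int(L - rl + 1L, 1)
      list(seq = substr(genes[[g]], s, s + rl - 1L), gene = g)
    }

    ids <- sprintf("read%06d", seq_len(n_reads))
    lib <- rep_len(c("DI", "NDI"), n_reads)
    seqs <- character(n_reads)
    quals <- character(n_reads)
    src <- rep(NA_character_, n_reads)
    cont_hits <- list()
    for (i in seq_len(n_reads)) {
      lab <- labels[i]
      if (lab == "duplicate") {
        prev <- which(labels[seq_len(i - 1L)] == "none")
        if (length(prev) == 0) { lab <- "none"; labels[i] <- "none" }
      }
      if (lab %in% c("none", "ambiguous", "low_quality", "polyat")) {
        cl <- draw_clean()
        s <- cl$seq
        src[i] <- cl$gene
        q <- if (lab == "low_quality") qual_lo(nchar(s)) else qual_hi(nchar(s))
        if (lab == "ambiguous") {
          pos <- sample.int(nchar(s), sample(1:3, 1))
          for (p in pos) substr(s, p, p) <- "N"
        }
        if (lab == "polyat") {
          run <- sample(12:20, 1)
          if (stats::runif(1) < 0.5) {
            s <- paste0(s, strrep("A", run))
          } else {
            s <- paste0(strrep("T", run), s)
          }
          q <- qual_hi(nchar(s))
        }
      } else if (lab == "duplicate") {
        j <- if (length(prev) == 1) prev else sample(prev, 1)
        s <- seqs[j]
        q <- quals[j]
        src[i] <- src[j]
      } else if (lab == "contaminant") {
        s <- random_dna(1, sample(80:200, 1))
        q <- qual_hi(nchar(s))
        alen <- nchar(s)
        cont_hits[[ids[i]]] <-
          data.frame(qseqid = ids[i], sseqid = "rRNA_Wolbachia_ref",
                     pident = 98, length = alen, mismatch = 0L, gapopen = 0L,
                     qstart = 1L, qend = alen, sstart = 1L, send = alen,
                     evalue = min(model_evalue(alen, 98), 1e-25),
                     bitscore = round(2 * alen * 0.98, 1),
                     stringsAsFactors = FALSE)
      } else if (lab == "short") {
        cl <- draw_clean()
        s <- substr(cl$seq, 1, sample(20:49, 1))
        src[i] <- cl$gene
        q <- qual_hi(nchar(s))
      }
      seqs[i] <- s
      quals[i] <- q
    }
    reads <- read_table(ids, seqs, quals, lib)
    manifest <- data.frame(read_id = ids, library = lib, defect = labels,
                           source_gene = src, stringsAsFactors = FALSE)
    hits <- if (length(cont_hits)) {
      do.call(rbind, c(unname(cont_hits), list(make.row.names = FALSE)))
    } else {
      stats::setNames(
        data.frame(matrix(nrow = 0, ncol = 12)), outfmt6_cols)
    }
    structure(list(reads = reads, manifest = manifest,
                   contaminant_hits = hits),
              class = "synthetic_reads")
  })
}
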