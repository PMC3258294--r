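#' Read-cleaning filters for 454-style transcriptome reads
#'
#' The cleaning pass applies, in a fixed order, the four quality
#' filters of the study design plus poly-A/T tail trimming and a 50 bp
#' length floor: (1) remove reads containing any ambiguous base,
#' (2) remove exact duplicate reads (a known 454 artifact), keeping the
#' first occurrence, (3) remove reads with mean Phred quality below 25,
#' (4) remove reads with a contaminant (rRNA/endosymbiont) homology hit
#' at e-value <= 1e-25, then trim terminal poly-A/T runs and drop reads
#' shorter than 50 bp. All filters are stable: retained reads keep
#' their input order.
#'
#' @param reads A read table (see [read_table()]).
#' @name read-qc
NULL

#' @describeIn read-qc Remove reads containing at least one ambiguous
#'   base (`N`).
#' @export
filter_ambiguous <- function(reads) {
  reads[!grepl("N", reads$seq, fixed = TRUE), , drop = FALSE]
}

#' @describeIn read-qc Remove exact-duplicate sequences, retaining the
#'   first occurrence in input order.
#' @export
remove_duplicates <- function(reads) {
  reads[!duplicated(reads$seq), , drop = FALSE]
}

#' @describeIn read-qc Remove reads whose arithmetic mean Phred score
#'   is below `min_mean` (boundary reads with mean exactly `min_mean`
#'   are kept).
#' @param min_mean Minimum mean Phred quality.
#' @export
filter_mean_quality <- function(reads, min_mean = 25) {
  if (any(is.na(reads$qual)) || any(nchar(reads$qual) == 0 & nchar(reads$seq) > 0)) {
    stop("reads are missing quality strings")
  }
  reads[mean_phred(reads$qual) >= min_mean, , drop = FALSE]
}

#' @describeIn read-qc Remove reads with any contaminant hit at
#'   e-value <= `evalue_cutoff`. Hit rows referencing unknown read ids
#'   are ignored with a warning.
#' @param hit_table Contaminant hits in outfmt-6 layout (`qseqid` is
#'   the read id).
#' @param evalue_cutoff Significance cutoff for a contaminant match.
#' @export
screen_contaminants <- function(reads, hit_table, evalue_cutoff = 1e-25) {
  if (is.null(hit_table) || nrow(hit_table) == 0) return(reads)
  unknown <- setdiff(unique(hit_table$qseqid), reads$id)
  if (length(unknown)) {
    warning(length(unknown), " contaminant hit(s) reference unknown read ids")
  }
  bad <- unique(hit_table$qseqid[hit_table$evalue <= evalue_cutoff])
  reads[!(reads$id %in% bad), , drop = FALSE]
}

# length of the maximal terminal run of `base` allowing up to
# `allow` interior non-matching bases; the run must start and end on
# a matching base
terminal_run <- function(bases, allow) {
  n <- length(bases)
  if (n == 0 || !bases[n]) return(0L)
  mism <- 0L
  best <- 0L
  for (i in seq(n, 1L)) {
    if (bases[i]) {
      best <- n - i + 1L
    } else {
      mism <- mism + 1L
      if (mism > allow) break
    }
  }
  best
}

#' @describeIn read-qc Trim a terminal poly-A run from the 3' end and
#'   a poly-T run from the 5' end of each read, when the run is at
#'   least `min_run` bp long (allowing up to `mismatch_allowance`
#'   interior non-matching bases). Qualities are trimmed in register.
#' @param min_run Minimum run length to trim.
#' @param mismatch_allowance Interior non-matching bases tolerated
#'   within a run.
#' @export
trim_polyAT <- function(reads, min_run = 10, mismatch_allowance = 1) {
  for (i in seq_len(nrow(reads))) {
    s <- strsplit(reads$seq[i], "")[[1]]
    r3 <- terminal_run(s == "A", mismatch_allowance)
    if (r3 >= min_run) {
      s <- s[seq_len(length(s) - r3)]
    }
    r5 <- terminal_run(rev(s == "T"), mismatch_allowance)
    if (r5 >= min_run) {
      s <- s[-seq_len(r5)]
    }
    if (length(s) != nchar(reads$seq[i])) {
      keep_from <- if (r5 >= min_run) r5 + 1L else 1L
      reads$seq[i] <- paste(s, collapse = "")
      reads$qual[i] <- substr(reads$qual[i], keep_from,
                              keep_from + length(s) - 1L)
    }
  }
  reads
}

#' @describeIn read-qc Remove reads shorter than `floor` bp (reads of
#'   exactly `floor` bp are kept).
#' @param floor Minimum retained read length in bp.
#' @export
enforce_min_length <- function(reads, floor = 50) {
  reads[nchar(reads$seq) >= floor, , drop = FALSE]
}

#' N50 of a set of sequence lengths
#'
#' The smallest length L such that sequences of length >= L together
#' contain at least half of the total bases.
#'
#' @param lengths Positive sequence lengths in bp.
#' @return The N50, in bp.
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length vector")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Default QC configuration
#'
#' @param min_mean_quality Mean-Phred floor (filter 3).
#' @param contaminant_evalue E-value cutoff for the contaminant screen.
#' @param polyat_min_run,polyat_mismatch Poly-A/T trimming parameters.
#' @param min_length Read-length floor in bp.
#' @return A named list of QC parameters.
#' @export
qc_config <- function(min_mean_quality = 25, contaminant_evalue = 1e-25,
                      polyat_min_run = 10, polyat_mismatch = 1,
                      min_length = 50) {
  list(min_mean_quality = min_mean_quality,
       contaminant_evalue = contaminant_evalue,
       polyat_min_run = polyat_min_run, polyat_mismatch = polyat_mismatch,
       min_length = min_length)
}

#' Run the full read-cleaning pass
#'
#' Applies the filters in the contract order (ambiguous, duplicates,
#' mean quality, contaminants, poly-A/T trimming, length floor) and
#' tallies removals per step. The tallies are order-dependent, so the
#' order is part of the contract; conservation always holds:
#' `remaining + sum(removed) == input`.
#'
#' @param reads A read table.
#' @param contaminant_hits Optional contaminant hit table (outfmt 6).
#' @param config A list from [qc_config()].
#' @return A list of class `"qc_result"`: `reads` (the clean read
#'   table) and `report` (class `"qc_report"`: input count, per-step
#'   `removed`, number of reads trimmed, remaining count, and summary
#'   statistics: mean/median length, N50, mean %GC).
#' @export
run_qc <- function(reads, contaminant_hits = NULL, config = qc_config()) {
  n0 <- nrow(reads)
  removed <- c(ambiguous = 0L, duplicate = 0L, low_quality = 0L,
               contaminant = 0L, short = 0L)

  r <- filter_ambiguous(reads)
  removed["ambiguous"] <- n0 - nrow(r)
  n <- nrow(r)
  r <- remove_duplicates(r)
  removed["duplicate"] <- n - nrow(r)
  n <- nrow(r)
  r <- filter_mean_quality(r, config$min_mean_quality)
  removed["low_quality"] <- n - nrow(r)
  n <- nrow(r)
  r <- screen_contaminants(r, contaminant_hits, config$contaminant_evalue)
  removed["contaminant"] <- n - nrow(r)
  pre_trim <- r$seq
  r <- trim_polyAT(r, config$polyat_min_run, config$polyat_mismatch)
  n_trimmed <- sum(r$seq != pre_trim)
  n <- nrow(r)
  r <- enforce_min_length(r, config$min_length)
  removed["short"] <- n - nrow(r)

  lens <- nchar(r$seq)
  report <- structure(list(
    input = n0, removed = removed, trimmed_reads = n_trimmed,
    remaining = nrow(r),
    mean_length = if (nrow(r)) mean(lens) else NA_real_,
    median_length = if (nrow(r)) stats::median(lens) else NA_real_,
    n50 = if (nrow(r)) compute_n50(lens) else NA_real_,
    mean_gc = if (nrow(r)) mean(gc_percent(r$seq)) else NA_real_),
    class = "qc_report")
  structure(list(reads = r, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read-cleaning report\n")
  cat(sprintf("  input reads      %d\n", x$input))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", nm, x$removed[[nm]]))
  }
  cat(sprintf("  poly-A/T trimmed %d\n", x$trimmed_reads))
  cat(sprintf("  remaining        %d (%.2f%% removed)\n", x$remaining,
              100 * (x$input - x$remaining) / max(x$input, 1)))
  cat(sprintf("  mean length %.1f bp | median %.0f bp | N50 %d bp | GC %.1f%%\n",
              x$mean_length, x$median_length, x$n50, x$mean_gc))
  invisible(x)
}
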