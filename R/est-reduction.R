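#' Group assignments by reference gene
#'
#' Partitions the assignment table into one group per (gene, tier);
#' group sizes sum to the number of assigned ESTs.
#'
#' @param assignments Assignment data frame from [annotate_ests()].
#' @return A named list of assignment data frames, one per gene group.
#' @export
group_by_gene <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) return(list())
  split(assignments, paste(assignments$gene_id, assignments$tier, sep = "\r"))
}

#' Select the representative EST of a gene group
#'
#' Implements the length/identity trade-off rule. For tiers with a
#' positive identity cutoff: among members at or above the cutoff,
#' take the one with the longest alignment (ties: higher identity,
#' then est id); if no member reaches the cutoff, take the member with
#' the highest identity. For cutoff-0 tiers: take the member with the
#' highest identity among those with alignment length >= 50 bp (ties:
#' longer alignment, then est id); if none is >= 50 bp the group is
#' dropped (`NULL`).
#'
#' @param group Assignment rows of one gene group.
#' @param min_identity The tier's selection cutoff (percent; 0 for
#'   identity-only selection).
#' @return The representative's assignment row, or `NULL` when the
#'   cutoff-0 minimum-length requirement eliminates the group.
#' @export
select_representative <- function(group, min_identity) {
  if (is.null(group) || nrow(group) == 0) stop("empty gene group")
  if (min_identity > 0) {
    qual <- group[group$pident >= min_identity, , drop = FALSE]
    if (nrow(qual) > 0) {
      o <- order(-qual$aln_length, -qual$pident, qual$est_id)
      return(qual[o, , drop = FALSE][1, ])
    }
    o <- order(-group$pident, -group$aln_length, group$est_id)
    return(group[o, , drop = FALSE][1, ])
  }
  qual <- group[group$aln_length >= 50, , drop = FALSE]
  if (nrow(qual) == 0) return(NULL)
  o <- order(-qual$pident, -qual$aln_length, qual$est_id)
  qual[o, , drop = FALSE][1, ]
}

#' Genomic-overlap rule for genomic-tier hits
#'
#' A hit against the genomic database is only used if the majority
#' (strictly more than 50%) of the EST's aligned genomic span overlaps
#' annotated mRNA intervals. The denominator is the aligned span
#' length, since unaligned EST tails have no genomic placement.
#'
#' @param hit One assignment/hit row with `sstart`, `send` and the
#'   scaffold id in `gene_id` (assignment) or `sseqid` (hit table).
#' @param gff mRNA annotation data frame (`seqid`, `start`, `end`,
#'   `type`).
#' @return `TRUE` when the overlap fraction is > 0.5.
#' @export
genomic_overlap_filter <- function(hit, gff) {
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  if (any(mrna$end < mrna$start)) stop("malformed mRNA interval")
  scaffold <- if (!is.null(hit$gene_id)) hit$gene_id else hit$sseqid
  s <- min(hit$sstart, hit$send)
  e <- max(hit$sstart, hit$send)
  span <- IRanges::IRanges(start = s, end = e)
  here <- mrna[mrna$seqid == scaffold, , drop = FALSE]
  if (nrow(here) == 0) return(FALSE)
  ann <- IRanges::reduce(IRanges::IRanges(start = here$start,
                                          end = here$end))
  ov <- IRanges::intersect(span, ann)
  sum(IRanges::width(ov)) / IRanges::width(span) > 0.5
}

#' Trim an EST to its homology-supported span
#'
#' Cuts the EST down to the query start/stop coordinates of its
#' winning alignment (1-based inclusive, min/max-normalised so that
#' translated-search frames with reversed coordinates trim the same
#' substring), eliminating the variable 5'/3' ends.
#'
#' @param est_seq The source EST sequence (character scalar).
#' @param hit The winning assignment/hit row (`qstart`, `qend`).
#' @param est_id Source id; the trimmed id gets a `_trimmed` suffix.
#' @return A one-row data frame: `est_id`, `source_id`, `sequence`,
#'   `qstart`, `qend`, `length`, `bp_trimmed`.
#' @export
trim_to_alignment <- function(est_seq, hit, est_id = hit$est_id) {
  s <- min(hit$qstart, hit$qend)
  e <- max(hit$qstart, hit$qend)
  if (s < 1 || e > nchar(est_seq)) {
    stop("alignment coordinates fall outside the EST")
  }
  trimmed <- substr(est_seq, s, e)
  data.frame(est_id = paste0(est_id, "_trimmed"), source_id = est_id,
             sequence = trimmed, qstart = s, qend = e,
             length = nchar(trimmed),
             bp_trimmed = nchar(est_seq) - nchar(trimmed),
             stringsAsFactors = FALSE)
}

#' Reduce redundant EST groups to one trimmed representative per gene
#'
#' The central non-redundancy guarantee of the pipeline: genomic-tier
#' assignments failing the mRNA-overlap rule are dropped first, the
#' remaining assignments are grouped by reference gene, each group's
#' representative is selected by the length/identity trade-off, and
#' the representative is trimmed to its alignment span. Trimmed
#' products shorter than `min_length` bp are dropped (with the reason
#' logged in the summary).
#'
#' @param assignments Assignment data frame from [annotate_ests()].
#' @param sequences Named character vector (or `DNAStringSet`) of the
#'   source contigs/singletons.
#' @param tiers Tier table.
#' @param gff mRNA annotations for the genomic tier (may be `NULL`
#'   when no genomic-tier assignment exists).
#' @param min_length Minimum trimmed length in bp.
#' @return A list of class `"est_reduction"`: `ests` (trimmed-EST data
#'   frame with `gene_id` and `tier` attached) and `summary`
#'   (group-size distribution, mean bp trimmed, N50 before/after
#'   trimming, drop tallies).
#' @export
reduce_ests <- function(assignments, sequences, tiers = default_tiers(),
                        gff = NULL, min_length = 50) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  miss <- setdiff(assignments$est_id, names(sequences))
  if (length(miss)) {
    stop("assignments reference absent sequence(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  genomic_tiers <- tiers$name[tiers$genomic]
  dropped_overlap <- 0L
  if (length(genomic_tiers) && any(assignments$tier %in% genomic_tiers)) {
    if (is.null(gff)) stop("genomic-tier assignments need mRNA annotations")
    is_gen <- assignments$tier %in% genomic_tiers
    keep <- rep(TRUE, nrow(assignments))
    for (i in which(is_gen)) {
      keep[i] <- genomic_overlap_filter(assignments[i, ], gff)
    }
    dropped_overlap <- sum(!keep)
    assignments <- assignments[keep, , drop = FALSE]
  }
  groups <- group_by_gene(assignments)
  cutoffs <- stats::setNames(tiers$min_identity, tiers$name)
  out <- list()
  dropped_short <- 0L
  dropped_selection <- 0L
  for (grp in groups) {
    rep_row <- select_representative(grp, cutoffs[[grp$tier[1]]])
    if (is.null(rep_row)) {
      dropped_selection <- dropped_selection + 1L
      next
    }
    tr <- trim_to_alignment(sequences[[rep_row$est_id]], rep_row)
    if (tr$length < min_length) {
      dropped_short <- dropped_short + 1L
      next
    }
    tr$gene_id <- rep_row$gene_id
    tr$tier <- rep_row$tier
    out[[length(out) + 1L]] <- tr
  }
  ests <- if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  group_sizes <- vapply(groups, nrow, integer(1))
  summary <- list(
    n_groups = length(groups),
    group_size_mean = if (length(groups)) mean(group_sizes) else NA_real_,
    group_size_median = if (length(groups)) stats::median(group_sizes) else NA_real_,
    group_size_max = if (length(groups)) max(group_sizes) else NA_integer_,
    mean_bp_trimmed = if (nrow(ests)) mean(ests$bp_trimmed) else NA_real_,
    n50_before = if (nrow(assignments))
      compute_n50(nchar(sequences[unique(assignments$est_id)])) else NA_real_,
    n50_after = if (nrow(ests)) compute_n50(ests$length) else NA_real_,
    dropped_overlap = dropped_overlap,
    dropped_short = dropped_short,
    dropped_selection = dropped_selection)
  structure(list(ests = ests, summary = summary), class = "est_reduction")
}
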