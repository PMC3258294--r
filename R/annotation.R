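#' Default homology-search tier table
#'
#' The tiered database cascade used to annotate ESTs, ordered from the
#' conspecific mRNA set down to Swiss-Prot, with e-value cutoffs that
#' loosen as taxonomic distance increases. `min_identity` is the
#' percent-identity cutoff used later when selecting the representative
#' EST of a gene group (0 means identity-only selection), and
#' `genomic` flags the genomic tier, whose hits must additionally pass
#' the annotated-mRNA overlap rule.
#'
#' @return A data frame with columns `name`, `algorithm`
#'   (`nucleotide`/`translated`), `max_evalue`, `min_identity`,
#'   `priority`, `genomic`.
#' @export
default_tiers <- function() {
  data.frame(
    name = c("Ae_albopictus_mRNA", "Ae_aegypti_transcripts",
             "Ae_aegypti_genomic", "Ae_aegypti_peptides",
             "Cx_quinquefasciatus_peptides", "An_gambiae_peptides",
             "D_melanogaster_peptides", "C_elegans_peptides",
             "SwissProt"),
    algorithm = c("nucleotide", "nucleotide", "nucleotide", "translated",
                  "translated", "translated", "translated", "translated",
                  "translated"),
    max_evalue = c(1e-10, 1e-10, 1e-10, 1e-10, 1e-5, 1e-5, 1e-5, 1e-4,
                   1e-3),
    min_identity = c(85, 85, 85, 70, 0, 0, 0, 0, 0),
    priority = 1:9,
    genomic = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE),
    stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  need <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
            "evalue", "bitscore")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(hits)
}

#' Best hit among alignments of one query
#'
#' The match with the lowest e-value is retained; ties on e-value are
#' broken by the highest bitscore, and residual ties by subject id
#' (lexicographic), so the result is deterministic and invariant under
#' input permutation.
#'
#' @param hits Hit rows (outfmt-6 layout) for a single query.
#' @return The winning hit row.
#' @export
best_hit <- function(hits) {
  validate_hits(hits)
  if (nrow(hits) == 0) stop("best_hit: empty hit list")
  hits[order(hits$evalue, -hits$bitscore, hits$sseqid), , drop = FALSE][1, ]
}

#' Assign one EST through the tier cascade
#'
#' Walks the tiers in priority order and, within the first tier that
#' has at least one hit passing its e-value cutoff, returns the best
#' hit. ESTs qualifying in no tier return `NULL` (the "no hit" class).
#'
#' @param est_id Query id.
#' @param hits_by_tier Named list of hit tables, keyed by tier name;
#'   each may contain hits for many queries.
#' @param tiers Tier table (see [default_tiers()]).
#' @return A one-row assignment data frame (`est_id`, `gene_id`,
#'   `tier`, plus the winning hit's columns), or `NULL`.
#' @export
cascade_assign <- function(est_id, hits_by_tier, tiers = default_tiers()) {
  tiers <- tiers[order(tiers$priority), ]
  for (i in seq_len(nrow(tiers))) {
    h <- hits_by_tier[[tiers$name[i]]]
    if (is.null(h) || nrow(h) == 0) next
    h <- h[h$qseqid == est_id & h$evalue <= tiers$max_evalue[i], ,
           drop = FALSE]
    if (nrow(h) == 0) next
    win <- best_hit(h)
    return(data.frame(est_id = est_id, gene_id = win$sseqid,
                      tier = tiers$name[i], pident = win$pident,
                      aln_length = win$length, qstart = win$qstart,
                      qend = win$qend, sstart = win$sstart,
                      send = win$send, evalue = win$evalue,
                      bitscore = win$bitscore, stringsAsFactors = FALSE))
  }
  NULL
}

#' Assign every EST through the tier cascade
#'
#' Vectorised form of [cascade_assign()]: each EST is assigned in the
#' first (highest-priority) tier where it has a qualifying hit, using
#' the best-hit rule within that tier. ESTs with no qualifying hit
#' anywhere are reported in the `no_hit` element.
#'
#' @param hits_by_tier Named list of outfmt-6 hit tables keyed by tier
#'   name.
#' @param tiers Tier table.
#' @param est_ids Optional universe of EST ids (to report no-hit ESTs
#'   that appear in no table).
#' @return A list with `assignments` (one row per assigned EST) and
#'   `no_hit` (character vector of unassigned ids).
#' @export
annotate_ests <- function(hits_by_tier, tiers = default_tiers(),
                          est_ids = NULL) {
  tiers <- tiers[order(tiers$priority), ]
  pool <- list()
  for (i in seq_len(nrow(tiers))) {
    h <- hits_by_tier[[tiers$name[i]]]
    if (is.null(h) || nrow(h) == 0) next
    validate_hits(h)
    h <- h[h$evalue <= tiers$max_evalue[i], , drop = FALSE]
    if (nrow(h) == 0) next
    h$tier <- tiers$name[i]
    h$priority <- tiers$priority[i]
    pool[[length(pool) + 1L]] <- h
  }
  if (length(pool) == 0) {
    return(list(assignments = data.frame(), no_hit = est_ids %||% character(0)))
  }
  all_h <- do.call(rbind, c(pool, list(make.row.names = FALSE)))
  # first qualifying tier per query, then best hit within it
  o <- order(all_h$qseqid, all_h$priority, all_h$evalue, -all_h$bitscore,
             all_h$sseqid)
  all_h <- all_h[o, , drop = FALSE]
  win <- all_h[!duplicated(all_h$qseqid), , drop = FALSE]
  assignments <- data.frame(est_id = win$qseqid, gene_id = win$sseqid,
                            tier = win$tier, pident = win$pident,
                            aln_length = win$length, qstart = win$qstart,
                            qend = win$qend, sstart = win$sstart,
                            send = win$send, evalue = win$evalue,
                            bitscore = win$bitscore,
                            stringsAsFactors = FALSE)
  universe <- unique(c(est_ids,
                       unlist(lapply(hits_by_tier, function(h) h$qseqid),
                              use.names = FALSE)))
  list(assignments = assignments,
       no_hit = setdiff(universe, assignments$est_id))
}

#' Bootstrapped gene-accumulation curve
#'
#' Randomises the order of per-read homology outcomes `n_boot` times
#' and, for each permutation, counts the cumulative number of distinct
#' reference genes captured by each additional read; the per-rank mean
#' over permutations is returned. The curve is monotone non-decreasing
#' and its endpoint equals the total number of distinct genes hit,
#' whatever the permutation.
#'
#' @param gene_hits Per-read gene id, `NA` for reads without a hit, in
#'   input order.
#' @param n_boot Number of random orderings (>= 1).
#' @param seed Integer seed.
#' @return A data frame with `rank` and `mean_cumulative_genes`.
#' @export
accumulation_curve <- function(gene_hits, n_boot = 1000, seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- length(gene_hits)
  if (n == 0) stop("empty input")
  withr::with_seed(seed, {
    acc <- numeric(n)
    for (b in seq_len(n_boot)) {
      perm <- sample(gene_hits)
      acc <- acc + cumsum(!is.na(perm) & !duplicated(perm, incomparables = NA))
    }
    data.frame(rank = seq_len(n), mean_cumulative_genes = acc / n_boot)
  })
}
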