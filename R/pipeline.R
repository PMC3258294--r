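#' Build a bundled synthetic input set
#'
#' Generates every input the pipeline consumes, at one of two scales:
#' `"tiny"` (a smoke-test fixture that completes in seconds) or
#' `"paper-like"`, which mimics the shape of the original study at
#' roughly 1/1000 scale: two libraries with a modest size skew, EST
#' redundancy with mean 8.86 per gene, QC-defective reads at a few
#' percent each, and a subset of genes with true differential
#' expression.
#'
#' @param preset `"tiny"` or `"paper-like"`.
#' @param seed Integer seed; every generator seed is derived from it.
#' @return A list of class `"pipeline_fixture"`: `preset`, `seed`,
#'   `ref`, `contigs`, `reads`, `counts` and the ground `truth` (with
#'   contig provenance folded in).
#' @export
make_fixture <- function(preset = c("tiny", "paper-like"), seed = 1) {
  preset <- match.arg(preset)
  p <- switch(preset,
    tiny = list(n_genes = 40, n_de = 6, redundancy = list(mean = 3, size = 1),
                n_reads = 600, n_nohit = 3, skew = 1.1, n_unique = 2,
                mean_count = 40),
    `paper-like` = list(n_genes = 400, n_de = 20,
                        redundancy = list(mean = 8.86, size = 0.7),
                        n_reads = 4000, n_nohit = 20, skew = 1.1,
                        n_unique = 6, mean_count = 50))
  ref <- simulate_reference(p$n_genes, n_de = p$n_de, seed = seed)
  contigs <- simulate_redundant_contigs(ref, redundancy = p$redundancy,
                                        junk_tail_max = 80,
                                        error_rate = 0.01,
                                        n_nohit = p$n_nohit,
                                        seed = seed + 1L)
  reads <- simulate_qc_reads(ref, n_reads = p$n_reads, seed = seed + 2L)
  counts <- simulate_counts(contigs$ref$truth, skew = p$skew,
                            n_unique = p$n_unique,
                            mean_count = p$mean_count, seed = seed + 3L)
  structure(list(preset = preset, seed = seed, ref = ref,
                 contigs = contigs, reads = reads, counts = counts,
                 truth = contigs$ref$truth),
            class = "pipeline_fixture")
}

#' Run the full pipeline on a synthetic fixture
#'
#' Executes the stages in the study's order - read QC, tier-cascade
#' annotation, the read-level gene-accumulation curve, redundancy
#' reduction and trimming, count assembly on the reduced gene set,
#' differential expression under both normalisation paths, qPCR
#' simulation and quantification for a candidate panel, and finally
#' the cross-platform concordance statistics. Identical fixture and
#' configuration give identical reports.
#'
#' @param fixture A `"pipeline_fixture"` from [make_fixture()].
#' @param alpha Sequencing DE call threshold (adjusted p).
#' @param qpcr_alpha qPCR significance threshold (adjusted p).
#' @param n_qpcr Size of the qPCR candidate panel (DE calls topped up
#'   with non-significant genes, mirroring a panel that mixes
#'   predicted positives and negatives).
#' @param n_boot Permutations for the accumulation curve.
#' @param ct_noise_sd qPCR per-well noise (cycles).
#' @return A list of class `"run_report"` with per-stage results:
#'   `qc` (report and clean reads count), `annotation` (per-tier
#'   tallies, no-hit count, assignments), `curve`, `reduction`,
#'   `de_tmm`, `de_rpkm`, `qpcr`, `correlation`, `cv`,
#'   `concordance_tmm`, `concordance_rpkm`.
#' @export
run_all <- function(fixture, alpha = 0.001, qpcr_alpha = 0.05,
                    n_qpcr = 24, n_boot = 200, ct_noise_sd = 0.25) {
  stopifnot(inherits(fixture, "pipeline_fixture"))
  truth <- fixture$truth

  qc <- run_qc(fixture$reads$reads,
               contaminant_hits = fixture$reads$contaminant_hits)

  ann <- annotate_ests(fixture$contigs$hits,
                       est_ids = names(fixture$contigs$contigs))
  tier_tally <- table(ann$assignments$tier)

  clean_ids <- qc$reads$id
  manifest <- fixture$reads$manifest
  gene_hits <- manifest$source_gene[match(clean_ids, manifest$read_id)]
  curve <- accumulation_curve(gene_hits, n_boot = n_boot,
                              seed = fixture$seed + 4L)

  red <- reduce_ests(ann$assignments, fixture$contigs$contigs,
                     gff = fixture$ref$gff)

  counts <- fixture$counts
  keep <- counts$gene_id %in% red$ests$gene_id
  counts_red <- counts[keep, , drop = FALSE]
  counts_red$length <- red$ests$length[match(counts_red$gene_id,
                                             red$ests$gene_id)]
  attr(counts_red, "library_sizes") <- attr(counts, "library_sizes")

  de_tmm <- call_de(counts_red, method = "TMM", alpha = alpha)
  de_rpkm <- call_de(counts_red, method = "RPKM", alpha = alpha)

  called <- unique(c(de_tmm$gene_id[de_tmm$call != "ns"],
                     de_rpkm$gene_id[de_rpkm$call != "ns"]))
  ns_pool <- setdiff(de_tmm$gene_id, called)
  top_up <- utils::head(ns_pool, max(0, n_qpcr - length(called)))
  panel <- utils::head(c(called, top_up), n_qpcr)

  ct <- simulate_qpcr(truth, genes = panel, ct_noise_sd = ct_noise_sd,
                      seed = fixture$seed + 5L)
  quant <- qpcr_quantify(ct)
  qres <- qpcr_results(quant)

  norm_tmm <- tmm_factors(counts_red)
  expr_tmm <- data.frame(
    gene_id = counts_red$gene_id,
    DI = counts_red$count_DI / norm_tmm$effective_sizes[["DI"]],
    NDI = counts_red$count_NDI / norm_tmm$effective_sizes[["NDI"]])
  r <- rpkm(counts_red)
  expr_rpkm <- data.frame(gene_id = counts_red$gene_id, DI = r[, "DI"],
                          NDI = r[, "NDI"])
  in_panel <- function(x) x[x$gene_id %in% panel, , drop = FALSE]
  correlation <- rbind(
    cbind(method = "TMM",
          expression_correlation(in_panel(expr_tmm), qres)),
    cbind(method = "RPKM",
          expression_correlation(in_panel(expr_rpkm), qres)))

  structure(list(
    seed = fixture$seed, preset = fixture$preset,
    qc = qc$report,
    annotation = list(tier_tally = tier_tally,
                      n_assigned = nrow(ann$assignments),
                      n_no_hit = length(ann$no_hit),
                      assignments = ann$assignments),
    curve = curve,
    reduction = red$summary,
    ests = red$ests,
    de_tmm = de_tmm, de_rpkm = de_rpkm,
    qpcr = qres,
    cv = cv_comparison(qres),
    correlation = correlation,
    concordance_tmm = concordance(in_panel(de_tmm), qres,
                                  alpha = qpcr_alpha),
    concordance_rpkm = concordance(in_panel(de_rpkm), qres,
                                   alpha = qpcr_alpha)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (preset %s, seed %d)\n", x$preset, x$seed))
  cat(sprintf("  QC: %d -> %d reads\n", x$qc$input, x$qc$remaining))
  cat(sprintf("  annotation: %d assigned, %d no-hit\n",
              x$annotation$n_assigned, x$annotation$n_no_hit))
  cat(sprintf("  reduction: %d non-redundant trimmed ESTs\n",
              nrow(x$ests)))
  cat(sprintf("  DE (TMM): %d DI-up, %d NDI-up | DE (RPKM): %d DI-up, %d NDI-up\n",
              sum(x$de_tmm$call == "DI-up"), sum(x$de_tmm$call == "NDI-up"),
              sum(x$de_rpkm$call == "DI-up"), sum(x$de_rpkm$call == "NDI-up")))
  cat(sprintf("  qPCR panel: %d genes | CV paired p = %.3f\n",
              nrow(x$qpcr), x$cv$p_value))
  cat("  concordance (TMM): ")
  print(x$concordance_tmm$confusion)
  cat("  concordance (RPKM): ")
  print(x$concordance_rpkm$confusion)
  invisible(x)
}
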