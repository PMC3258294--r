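#' Simulate replicated qPCR Ct measurements
#'
#' Emulates a relative-quantification qPCR experiment with three
#' stable reference genes (`RpL34`, `HistoneH3`, `NAP`) whose expected
#' Ct is treatment-independent, and target genes whose expected Ct is
#' the reference level minus log2 of the ground-truth relative
#' abundance for that treatment, so that the 2^-dCt transform recovers
#' the true abundance exactly when `ct_noise_sd = 0`. Gaussian noise
#' of sd `ct_noise_sd` cycles is added independently to every well.
#'
#' @param truth A `"ground_truth"` object (supplies
#'   `qpcr_true_abundance`).
#' @param genes Target gene ids to assay (default: all genes in the
#'   truth).
#' @param n_bio Biological replicates per treatment (>= 2).
#' @param n_tech Technical replicates per well (>= 1).
#' @param ct_noise_sd Per-well Gaussian Ct noise, in cycles.
#' @param ref_ct Expected Ct of the reference genes.
#' @param seed Integer seed.
#' @return A long-format Ct data frame: `gene_id`, `role`
#'   (`target`/`reference`), `treatment` (`DI`/`NDI`), `bio_rep`,
#'   `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(truth, genes = NULL, n_bio = 5, n_tech = 3,
                          ct_noise_sd = 0.25, ref_ct = 20, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_bio < 2) stop("n_bio must be >= 2")
  if (n_tech < 1) stop("n_tech must be >= 1")
  genes <- genes %||% truth$gene_ids
  if (!all(genes %in% truth$gene_ids)) stop("unknown gene id(s)")
  refs <- c("RpL34", "HistoneH3", "NAP")
  withr::with_seed(seed, {
    grid <- expand.grid(treatment = c("DI", "NDI"),
                        bio_rep = seq_len(n_bio),
                        tech_rep = seq_len(n_tech),
                        stringsAsFactors = FALSE)
    one_gene <- function(gene, role) {
      mu <- if (role == "reference") {
        rep(ref_ct, nrow(grid))
      } else {
        ab <- truth$qpcr_true_abundance[gene, grid$treatment]
        ref_ct - log2(ab)
      }
      data.frame(gene_id = gene, role = role,
                 treatment = grid$treatment, bio_rep = grid$bio_rep,
                 tech_rep = grid$tech_rep,
                 ct = mu + stats::rnorm(nrow(grid), 0, ct_noise_sd),
                 stringsAsFactors = FALSE)
    }
    out <- rbind(
      do.call(rbind, lapply(refs, one_gene, role = "reference")),
      do.call(rbind, lapply(genes, one_gene, role = "target")))
    out <- out[order(out$gene_id, out$treatment, out$bio_rep, out$tech_rep), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
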