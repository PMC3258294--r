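#' Per-replicate delta-Ct and relative abundance
#'
#' The relative-quantification transform: for each biological
#' replicate, the geometric mean Ct of the three reference genes is
#' subtracted from the (tech-averaged) target Ct, and the difference
#' is transformed to a relative mRNA abundance, `2^-dCt`.
#'
#' @param target_ct Numeric vector of tech-averaged target Cts, one
#'   per biological replicate.
#' @param reference_ct Matrix of tech-averaged reference Cts,
#'   references x biological replicates (all three references
#'   required).
#' @return A data frame with `bio_rep`, `delta_ct`, `abundance`.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  if (is.null(dim(reference_ct)) || nrow(reference_ct) < 3) {
    stop("all three reference genes are required")
  }
  if (ncol(reference_ct) != length(target_ct)) {
    stop("reference and target replicate counts differ")
  }
  ref_geo <- exp(colMeans(log(reference_ct)))
  dct <- target_ct - ref_geo
  data.frame(bio_rep = seq_along(target_ct), delta_ct = dct,
             abundance = 2^(-dct))
}

#' Quantify a long-format Ct table
#'
#' Averages technical replicates arithmetically within each
#' (gene, treatment, biological replicate) cell, forms the geometric
#' mean of the three reference genes per cell, and applies the
#' delta-Ct transform to every target gene.
#'
#' @param ct Long-format Ct data frame (`gene_id`, `role`,
#'   `treatment`, `bio_rep`, `tech_rep`, `ct`).
#' @param reference_genes The three reference gene ids.
#' @return A data frame with one row per target gene x treatment x
#'   biological replicate: `gene_id`, `treatment`, `bio_rep`,
#'   `delta_ct`, `abundance`.
#' @export
qpcr_quantify <- function(ct,
                          reference_genes = c("RpL34", "HistoneH3", "NAP")) {
  miss <- setdiff(reference_genes, ct$gene_id)
  if (length(miss)) {
    stop("missing reference gene(s): ", paste(miss, collapse = ", "))
  }
  cell <- stats::aggregate(ct["ct"],
                           ct[c("gene_id", "treatment", "bio_rep")], mean)
  refs <- cell[cell$gene_id %in% reference_genes, , drop = FALSE]
  ref_geo <- stats::aggregate(list(ref_ct = log(refs$ct)),
                              refs[c("treatment", "bio_rep")],
                              function(x) exp(mean(x)))
  targets <- cell[!(cell$gene_id %in% reference_genes), , drop = FALSE]
  out <- merge(targets, ref_geo, by = c("treatment", "bio_rep"))
  out$delta_ct <- out$ct - out$ref_ct
  out$abundance <- 2^(-out$delta_ct)
  out <- out[order(out$gene_id, out$treatment, out$bio_rep),
             c("gene_id", "treatment", "bio_rep", "delta_ct", "abundance")]
  rownames(out) <- NULL
  out
}

#' qPCR log2 fold-change between treatments
#'
#' The log2 ratio of the mean relative abundance of DI replicates over
#' the mean of NDI replicates.
#'
#' @param abundance_di,abundance_ndi Per-replicate relative
#'   abundances.
#' @return log2 fold-change (DI vs NDI).
#' @export
qpcr_fold_change <- function(abundance_di, abundance_ndi) {
  if (length(abundance_di) == 0 || length(abundance_ndi) == 0) {
    stop("both treatments need at least one replicate")
  }
  m1 <- mean(abundance_di)
  m2 <- mean(abundance_ndi)
  if (m1 <= 0 || m2 <= 0) stop("mean abundance must be positive")
  log2(m1 / m2)
}

pooled_t_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Summarise a quantified qPCR experiment per gene
#'
#' For every target gene: mean relative abundance per treatment, the
#' log2 fold-change, a pooled-variance two-sample t-test on the
#' per-replicate abundances (DI vs NDI) with BH adjustment across
#' genes, and the per-treatment coefficient of variation (sample sd /
#' mean).
#'
#' @param quant Output of [qpcr_quantify()].
#' @return A data frame, one row per gene: `gene_id`, `mean_DI`,
#'   `mean_NDI`, `log2_fc`, `p_raw`, `p_adj`, `cv_DI`, `cv_NDI`.
#' @export
qpcr_results <- function(quant) {
  genes <- unique(quant$gene_id)
  rows <- lapply(genes, function(g) {
    di <- quant$abundance[quant$gene_id == g & quant$treatment == "DI"]
    ndi <- quant$abundance[quant$gene_id == g & quant$treatment == "NDI"]
    if (length(di) < 2 || length(ndi) < 2) {
      stop("gene ", g, ": need >= 2 biological replicates per treatment")
    }
    data.frame(gene_id = g, mean_DI = mean(di), mean_NDI = mean(ndi),
               log2_fc = qpcr_fold_change(di, ndi),
               p_raw = pooled_t_p(di, ndi),
               cv_DI = stats::sd(di) / mean(di),
               cv_NDI = stats::sd(ndi) / mean(ndi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- bh_adjust(out$p_raw)
  out[, c("gene_id", "mean_DI", "mean_NDI", "log2_fc", "p_raw", "p_adj",
          "cv_DI", "cv_NDI")]
}

#' Compare replicate variability between treatments
#'
#' Paired t-test on the per-gene coefficients of variation of mRNA
#' abundance between the two photoperiod treatments; reports per-
#' treatment medians. Equal CV vectors are flagged degenerate with
#' p = 1.
#'
#' @param results Per-gene results from [qpcr_results()] (uses `cv_DI`
#'   and `cv_NDI`).
#' @return A list: `median_cv_DI`, `median_cv_NDI`, `p_value`,
#'   `degenerate`, `n_genes`.
#' @export
cv_comparison <- function(results) {
  if (nrow(results) < 2) stop("need at least two genes")
  d <- results$cv_DI - results$cv_NDI
  degenerate <- stats::sd(d) == 0
  p <- if (degenerate) {
    if (isTRUE(all.equal(mean(d), 0))) 1 else 0
  } else {
    stats::t.test(results$cv_DI, results$cv_NDI, paired = TRUE)$p.value
  }
  list(median_cv_DI = stats::median(results$cv_DI),
       median_cv_NDI = stats::median(results$cv_NDI),
       p_value = p, degenerate = degenerate, n_genes = nrow(results))
}

#' Correlation between sequencing expression and qPCR abundance
#'
#' Ordinary least squares of mean qPCR abundance on the sequencing
#' expression measure, per treatment, reporting r-squared. An
#' exclusion list removes genes (e.g. a paralog-inflated outlier)
#' before fitting.
#'
#' @param expression Data frame `gene_id`, `DI`, `NDI` (sequencing
#'   expression values, any normalisation).
#' @param qpcr Per-gene results from [qpcr_results()] (uses `mean_DI`,
#'   `mean_NDI`).
#' @param exclude Gene ids dropped before fitting.
#' @return A data frame: `treatment`, `r_squared`, `n`.
#' @export
expression_correlation <- function(expression, qpcr, exclude = NULL) {
  d <- merge(expression, qpcr, by = "gene_id")
  if (!is.null(exclude)) d <- d[!(d$gene_id %in% exclude), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least three genes")
  fit_one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance in correlation input")
    }
    summary(stats::lm(y ~ x))$r.squared
  }
  data.frame(treatment = c("DI", "NDI"),
             r_squared = c(fit_one(d$DI, d$mean_DI),
                           fit_one(d$NDI, d$mean_NDI)),
             n = nrow(d), stringsAsFactors = FALSE)
}

#' Confusion summary from raw counts
#'
#' Sensitivity and specificity in their standard epidemiological
#' forms: `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)`.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return A list of class `"confusion_summary"`: the counts plus
#'   `TPR` and `TNR`.
#' @export
confusion_summary <- function(tp, tn, fp, fn) {
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 TPR = tp / (tp + fn), TNR = tn / (tn + fp)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d | sensitivity %.2f  specificity %.2f\n",
              x$TP, x$TN, x$FP, x$FN, x$TPR, x$TNR))
  invisible(x)
}

#' Concordance of sequencing DE calls with qPCR significance
#'
#' Genes called DE by the sequencing analysis are "positive". A true
#' positive is a positive gene whose qPCR result is significant in the
#' same direction; a false positive is a positive gene whose qPCR
#' result is non-significant or significant in the opposite direction.
#' True negatives are non-significant on both platforms; false
#' negatives are sequencing-negative genes that qPCR finds
#' significant. Directional consistency is, per sequencing category,
#' the fraction of genes whose mean qPCR fold-change sign matches the
#' predicted direction (significance not required).
#'
#' @param de Sequencing calls: data frame `gene_id`, `call` (`DI-up`,
#'   `NDI-up`, `ns`).
#' @param qpcr Per-gene qPCR results from [qpcr_results()] (uses
#'   `log2_fc`, `p_adj`).
#' @param alpha qPCR significance level on the adjusted p-value.
#' @return A list of class `"concordance"`: `confusion` (a
#'   [confusion_summary()]) and `directional_consistency` (named
#'   fractions for `DI-up` and `NDI-up` genes, `NA` when a category is
#'   empty).
#' @export
concordance <- function(de, qpcr, alpha = 0.05) {
  if (!setequal(de$gene_id, qpcr$gene_id)) {
    stop("sequencing and qPCR gene sets differ")
  }
  d <- merge(de[, c("gene_id", "call")],
             qpcr[, c("gene_id", "log2_fc", "p_adj")], by = "gene_id")
  positive <- d$call != "ns"
  pred_sign <- ifelse(d$call == "DI-up", 1, ifelse(d$call == "NDI-up", -1, 0))
  q_sig <- d$p_adj < alpha
  q_sign <- sign(d$log2_fc)
  tp <- sum(positive & q_sig & q_sign == pred_sign)
  fp <- sum(positive & (!q_sig | q_sign != pred_sign))
  tn <- sum(!positive & !q_sig)
  fn <- sum(!positive & q_sig)
  dc <- c(`DI-up` = if (any(d$call == "DI-up"))
            mean(q_sign[d$call == "DI-up"] == 1) else NA_real_,
          `NDI-up` = if (any(d$call == "NDI-up"))
            mean(q_sign[d$call == "NDI-up"] == -1) else NA_real_)
  structure(list(confusion = confusion_summary(tp, tn, fp, fn),
                 directional_consistency = dc, alpha = alpha,
                 n_genes = nrow(d)),
            class = "concordance")
}
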