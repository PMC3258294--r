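mk_ct <- function(genes_ct, n_bio = 3, n_tech = 2, ref_ct = 25) {
  # genes_ct: named list gene -> function(treatment, bio) expected Ct
  refs <- c("RpL34", "HistoneH3", "NAP")
  rows <- list()
  for (g in c(refs, names(genes_ct))) {
    for (tr in c("DI", "NDI")) for (b in seq_len(n_bio)) {
      for (tc in seq_len(n_tech)) {
        ct <- if (g %in% refs) ref_ct else genes_ct[[g]](tr, b)
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = g, role = if (g %in% refs) "reference" else "target",
          treatment = tr, bio_rep = b, tech_rep = tc, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("delta-Ct uses tech-rep means and the reference geometric mean", {
  # target Ct = refs -> dCt 0, abundance 1
  refs <- matrix(25, nrow = 3, ncol = 2)
  d <- delta_ct(c(25, 25), refs)
  expect_equal(d$delta_ct, c(0, 0))
  expect_equal(d$abundance, c(1, 1))
  # target one cycle later: abundance halves
  d <- delta_ct(c(26, 26), refs)
  expect_equal(d$abundance, c(0.5, 0.5))
  expect_error(delta_ct(c(25, 25), refs[1:2, ]), "three reference")

  # geometric (not arithmetic) mean over reference Cts
  refs <- matrix(c(20, 25, 32), nrow = 3, ncol = 1)
  d <- delta_ct(25, refs)
  expect_equal(d$delta_ct, 25 - exp(mean(log(c(20, 25, 32)))))

  # tech reps [24, 26] average to 25 before differencing
  ct <- mk_ct(list(goi = function(tr, b) 25), n_tech = 2)
  ct$ct[ct$gene_id == "goi" & ct$bio_rep == 1 & ct$treatment == "DI"] <-
    c(24, 26)
  q <- qpcr_quantify(ct)
  expect_equal(q$delta_ct[q$gene_id == "goi" & q$treatment == "DI" &
                            q$bio_rep == 1], 0)
  ct_bad <- ct[ct$gene_id != "RpL34", ]
  expect_error(qpcr_quantify(ct_bad), "RpL34")
})

test_that("qPCR fold-change is the log2 ratio of treatment means", {
  expect_equal(qpcr_fold_change(c(2, 2), c(1, 1)), 1)
  expect_equal(qpcr_fold_change(c(1.5, 0.5), c(0.5, 1.5)), 0)
  expect_error(qpcr_fold_change(numeric(0), 1), "replicate")

  # noiseless generator round-trip: true ratio 4 recovered exactly
  ref <- simulate_reference(12, n_de = 4, log2_fc = 2, seed = 41)
  ct <- simulate_qpcr(ref$truth, n_bio = 5, n_tech = 3, ct_noise_sd = 0,
                      seed = 42)
  # 15 rows per gene per treatment
  expect_equal(sum(ct$gene_id == "gene00001" & ct$treatment == "DI"), 15)
  q <- qpcr_results(qpcr_quantify(ct))
  expect_equal(q$log2_fc[match(ref$truth$gene_ids, q$gene_id)],
               ref$truth$true_log2_fc, tolerance = 1e-10)
})

test_that("qPCR significance uses a pooled-variance t-test with BH", {
  ct <- mk_ct(list(flat = function(tr, b) 25,
                   up = function(tr, b) if (tr == "DI") 22 + 0.1 * b
                        else 26 + 0.1 * b),
              n_bio = 4)
  q <- qpcr_results(qpcr_quantify(ct))
  # identical groups: degenerate, p = 1
  expect_equal(q$p_raw[q$gene_id == "flat"], 1)
  # closed-form pooled t oracle
  quant <- qpcr_quantify(ct)
  x <- quant$abundance[quant$gene_id == "up" & quant$treatment == "DI"]
  y <- quant$abundance[quant$gene_id == "up" & quant$treatment == "NDI"]
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_oracle <- 2 * pt(-abs(tstat), df = length(x) + length(y) - 2)
  expect_equal(q$p_raw[q$gene_id == "up"], p_oracle)
  # BH across genes matches the shared adjustment routine
  expect_equal(q$p_adj, bh_adjust(q$p_raw))
})

test_that("coefficients of variation are scale-invariant and compared pairwise", {
  quant <- data.frame(gene_id = "g", treatment = rep(c("DI", "NDI"), each = 2),
                      bio_rep = c(1, 2, 1, 2),
                      delta_ct = 0, abundance = c(2, 4, 1, 1))
  r <- qpcr_results(quant)
  expect_equal(r$cv_DI, sqrt(2) / 3)
  expect_equal(r$cv_NDI, 0)
  # scale invariance
  quant2 <- transform(quant, abundance = abundance * 7)
  expect_equal(qpcr_results(quant2)$cv_DI, r$cv_DI)

  res <- data.frame(gene_id = c("a", "b", "c"),
                    cv_DI = c(0.1, 0.2, 0.3), cv_NDI = c(0.1, 0.2, 0.3))
  cmp <- cv_comparison(res)
  expect_equal(cmp$p_value, 1)
  expect_true(cmp$degenerate)
  res$cv_NDI <- res$cv_NDI + c(0.05, 0.06, 0.04)
  cmp <- cv_comparison(res)
  expect_equal(cmp$p_value,
               t.test(res$cv_DI, res$cv_NDI, paired = TRUE)$p.value)
  expect_error(cv_comparison(res[1, ]), "two genes")
})

test_that("platform correlation reports r-squared per treatment", {
  qpcr <- data.frame(gene_id = sprintf("g%d", 1:6),
                     mean_DI = c(1, 2, 3, 4, 5, 6) * 0.01,
                     mean_NDI = c(6, 5, 4, 3, 2, 1) * 0.01)
  expr <- data.frame(gene_id = qpcr$gene_id,
                     DI = c(10, 20, 30, 40, 50, 60),
                     NDI = c(60, 50, 40, 30, 20, 10))
  r <- suppressWarnings(expression_correlation(expr, qpcr))
  expect_equal(r$r_squared, c(1, 1))
  # orthogonal noise: near-zero r-squared
  withr::with_seed(6, {
    expr2 <- data.frame(gene_id = qpcr$gene_id, DI = runif(6), NDI = runif(6))
    qpcr2 <- data.frame(gene_id = qpcr$gene_id,
                        mean_DI = runif(6), mean_NDI = runif(6))
  })
  expect_lt(max(expression_correlation(expr2, qpcr2)$r_squared), 0.5)
  # the exclusion list drops the named outlier before fitting
  expr$DI[1] <- 1e4
  r2 <- suppressWarnings(expression_correlation(expr, qpcr, exclude = "g1"))
  expect_equal(r2$r_squared[1], 1)
  expect_equal(r2$n[1], 5)
  expect_error(expression_correlation(expr[1:2, ], qpcr[1:2, ]), "three")
})

test_that("concordance classifies calls by direction and significance", {
  de <- data.frame(gene_id = sprintf("g%d", 1:6),
                   call = c("DI-up", "DI-up", "NDI-up", "ns", "ns", "ns"),
                   stringsAsFactors = FALSE)
  qp <- data.frame(gene_id = sprintf("g%d", 1:6),
                   log2_fc = c(1, -1, -2, 0.1, 2, -0.2),
                   p_adj = c(0.01, 0.01, 0.01, 0.9, 0.01, 0.8),
                   stringsAsFactors = FALSE)
  cc <- concordance(de, qp)
  # g1 TP; g2 significant opposite -> FP; g3 TP; g4 TN; g5 FN; g6 TN
  expect_equal(cc$confusion$TP, 2)
  expect_equal(cc$confusion$FP, 1)
  expect_equal(cc$confusion$TN, 2)
  expect_equal(cc$confusion$FN, 1)
  expect_equal(cc$confusion$TP + cc$confusion$TN + cc$confusion$FP +
                 cc$confusion$FN, 6)
  expect_equal(unname(cc$directional_consistency["DI-up"]), 0.5)
  expect_equal(unname(cc$directional_consistency["NDI-up"]), 1)
  expect_error(concordance(de[1:5, ], qp), "differ")

  # all-correct fixture
  qp2 <- transform(qp, log2_fc = c(1, 2, -2, 0, 0, 0),
                   p_adj = c(0.01, 0.01, 0.01, 0.9, 0.9, 0.9))
  cc2 <- concordance(de, qp2)
  expect_equal(cc2$confusion$TPR, 1)
  expect_equal(cc2$confusion$TNR, 1)
})
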