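mk_counts <- function(di, ndi, len = 500, ls = NULL) {
  x <- data.frame(gene_id = sprintf("g%03d", seq_along(di)), length = len,
                  count_DI = di, count_NDI = ndi, stringsAsFactors = FALSE)
  if (!is.null(ls)) attr(x, "library_sizes") <- ls
  x
}

test_that("mapping filter drops low-identity rows then non-unique reads", {
  maps <- data.frame(
    read_id = c("r1", "r1", "r2", "r3", "r3", "r4"),
    est_id = c("e1", "e2", "e1", "e1", "e2", "e2"),
    pct_identity = c(99, 99, 96, 98, 90, 97),
    library = c("DI", "DI", "DI", "NDI", "NDI", "NDI"),
    stringsAsFactors = FALSE)
  res <- unique_mapping_filter(maps, c(e1 = 300, e2 = 400))
  # r1 multi-maps at high identity -> discarded; r3's 90% row fails the
  # identity filter first, so r3 counts to e1
  expect_equal(res$discarded[["multi_mapped"]], 1)
  expect_equal(res$discarded[["low_identity"]], 1)
  expect_equal(res$counts$count_DI, c(1, 0))
  expect_equal(res$counts$count_NDI, c(1, 1))
  expect_equal(attr(res$counts, "library_sizes"), c(DI = 1, NDI = 2))
})

test_that("TMM factors are 1 for proportionally identical libraries", {
  withr::with_seed(1, x <- rpois(500, 80))
  same <- mk_counts(x, x)
  expect_equal(unname(tmm_factors(same)$factors), c(1, 1))
  # doubling every count changes sizes, not proportions
  doubled <- mk_counts(x, 2L * x)
  expect_equal(unname(tmm_factors(doubled)$factors), c(1, 1),
               tolerance = 1e-10)
  expect_error(tmm_factors(mk_counts(x, 0L * x)), "positive")
})

test_that("TMM recentres non-DE genes under one-sided DE skew", {
  withr::with_seed(7, {
    n <- 2000
    mu <- rlnorm(n, log(200), 0.5)
    de <- seq_len(n * 0.2)            # 20% DI-up only
    mu_di <- mu; mu_di[de] <- mu[de] * 4
    cnt <- mk_counts(rpois(n, mu_di), rpois(n, mu))
  })
  nf <- tmm_factors(cnt)
  eff <- nf$effective_sizes
  ratio <- (cnt$count_DI[-de] / eff[["DI"]]) / (cnt$count_NDI[-de] / eff[["NDI"]])
  # without normalisation the non-DE median ratio sits near 0.62 here;
  # TMM must bring it back to 1 within 5%
  expect_lt(abs(stats::median(ratio) - 1), 0.05)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  withr::with_seed(3, {
    m <- cbind(rpois(800, rlnorm(800, 4, 1)), rpois(800, rlnorm(800, 4.3, 1)))
  })
  keep <- rowSums(m) > 0
  cnt <- mk_counts(m[keep, 1], m[keep, 2])
  ours <- tmm_factors(cnt)$factors
  theirs <- edgeR::calcNormFactors(m[keep, ], method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("RPKM follows its defining formula and rescaling conserves totals", {
  cnt <- mk_counts(c(10, 0, 7), c(0, 0, 0), len = c(1000, 500, 350),
                   ls = c(DI = 1e6, NDI = 2e6))
  r <- rpkm(cnt)
  expect_equal(unname(r[, "DI"]), c(10, 0, 20))
  expect_equal(unname(r[1, "NDI"]), 0)
  cnt2 <- mk_counts(c(10, 0, 7), c(4, 2, 1), len = c(1000, 500, 350),
                    ls = c(DI = 1e6, NDI = 2e6))
  sc <- scale_rpkm_to_counts(rpkm(cnt2), 24)
  expect_equal(sum(sc$scaled), 24)
  # conservation holds to 1e-9 relative on random fixtures
  withr::with_seed(11, {
    for (i in 1:20) {
      cntr <- mk_counts(rpois(50, 40), rpois(50, 40),
                        len = sample(100:2000, 50, TRUE))
      tot <- sum(cntr$count_DI) + sum(cntr$count_NDI)
      s <- scale_rpkm_to_counts(rpkm(cntr), tot)
      expect_lt(abs(sum(s$scaled) - tot) / tot, 1e-9)
    }
  })
  expect_error(rpkm(mk_counts(1, 1, len = 0)), "positive")
  expect_error(scale_rpkm_to_counts(matrix(0, 2, 2), 10), "zero")
})

test_that("exact binomial test matches enumeration and stays symmetric", {
  # modal outcome has p = 1
  expect_equal(binom_exact_test(3, 3, 1e5, 1e5), 1, ignore_attr = TRUE)
  # hand enumeration: 5|0 at p0 = 1/2 -> 2/32
  expect_equal(binom_exact_test(5, 0, 7e5, 7e5), 0.0625, ignore_attr = TRUE)
  # x1 = x2 = 0 is undefined, returns 1 with a flag
  p <- binom_exact_test(0, 0, 1e5, 1e5)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "undefined"))

  # full pmf enumeration oracle across size ratios (binom.test uses the
  # same minimum-likelihood two-sided convention)
  ratios <- c(0.25, 0.5, 1, 2, 4)
  for (r in ratios) {
    n1 <- 1e5 * r; n2 <- 1e5
    for (n in 1:12) {
      for (x1 in 0:n) {
        ours <- as.numeric(binom_exact_test(x1, n - x1, n1, n2))
        oracle <- stats::binom.test(x1, n, p = n1 / (n1 + n2))$p.value
        expect_equal(ours, oracle, tolerance = 1e-12,
                     label = sprintf("x1=%d n=%d ratio=%g", x1, n, r))
      }
    }
  }

  # symmetry p(x1,x2|n1,n2) = p(x2,x1|n2,n1)
  withr::with_seed(5, {
    for (i in 1:50) {
      x <- sample(0:40, 2, TRUE); n <- runif(2, 1e4, 1e6)
      expect_equal(as.numeric(binom_exact_test(x[1], x[2], n[1], n[2])),
                   as.numeric(binom_exact_test(x[2], x[1], n[2], n[1])))
    }
  })
})

test_that("exact binomial test reproduces the SAGE-style reference", {
  skip_if_not_installed("statmod")
  withr::with_seed(9, {
    x1 <- sample(0:200, 40, TRUE); x2 <- sample(0:200, 40, TRUE)
  })
  ours <- as.numeric(binom_exact_test(x1, x2, 5e5, 4e5))
  theirs <- statmod::sage.test(x1, x2, 5e5, 4e5)
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("BH adjustment matches hand-computed step-up cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand step-up: sorted p (0.005, 0.04, 0.04); adj = min cummax rule
  expect_equal(bh_adjust(c(0.04, 0.005, 0.04)), c(0.04, 0.015, 0.04))
  p <- c(0.001, 0.2, 0.013, 0.9, 0.04)
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pseudocount fold-change handles zeros and is antisymmetric", {
  expect_equal(fold_change(10, 10, 1e5, 1e5), 0)
  expect_equal(fold_change(10, 0, 1e5, 1e5), log2(101))
  withr::with_seed(2, {
    for (i in 1:25) {
      x <- sample(0:100, 2, TRUE); n <- runif(2, 1e4, 1e6)
      expect_equal(fold_change(x[1], x[2], n[1], n[2]),
                   -fold_change(x[2], x[1], n[2], n[1]))
    }
  })
})

test_that("DE calling is calibrated under the null and recovers truth", {
  ref <- simulate_reference(800, n_de = 0, seed = 21)
  cnt <- simulate_counts(ref$truth, mean_count = 100, seed = 22)
  de <- call_de(cnt, method = "TMM")
  expect_equal(sum(de$call != "ns"), 0)
  # raw p < 0.05 at most at the nominal rate (exact test is conservative)
  frac <- mean(de$p_raw < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(de)))

  ref <- simulate_reference(800, n_de = 10, log2_fc = 2.5, seed = 23)
  cnt <- simulate_counts(ref$truth, skew = 1.1, seed = 24)
  for (m in c("TMM", "RPKM")) {
    de <- call_de(cnt, method = m)
    truth_up <- ref$truth$true_log2_fc > 0
    called_up <- de$call == "DI-up"
    called_dn <- de$call == "NDI-up"
    hits <- sum(called_up & truth_up) +
      sum(called_dn & ref$truth$true_log2_fc < 0)
    expect_gte(hits / 10, 0.8)
    # sign of M matches the call for every called gene
    expect_true(all(de$M[called_up] > 0))
    expect_true(all(de$M[called_dn] < 0))
  }
})

test_that("library-unique genes are flagged and keep finite fold-changes", {
  ref <- simulate_reference(300, seed = 31)
  cnt <- simulate_counts(ref$truth, n_unique = 5, seed = 32)
  uniq <- attr(cnt, "unique_genes")
  expect_equal(nrow(uniq), 5)
  zero_rows <- cnt$count_DI == 0 | cnt$count_NDI == 0
  expect_equal(sort(cnt$gene_id[zero_rows]), sort(uniq$gene_id))
  de <- call_de(cnt, method = "TMM")
  expect_equal(sort(de$gene_id[de$unique_to != "none"]),
               sort(uniq$gene_id))
  expect_true(all(is.finite(de$M)))
})
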