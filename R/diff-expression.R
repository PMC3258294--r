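#' Build a count matrix from read-to-EST mappings
#'
#' Applies the mapping filter of the expression stage: alignment rows
#' below `min_identity` percent identity are discarded first, then any
#' read still mapping to more than one EST is discarded entirely
#' (non-unique mapping), and the surviving unique assignments are
#' tallied per EST and library.
#'
#' @param mappings Data frame with `read_id`, `est_id`,
#'   `pct_identity`, `library`.
#' @param est_lengths Named vector of EST lengths (defines the gene
#'   universe; ESTs without surviving reads get zero counts).
#' @return A list with `counts` (gene_id, length, count_DI, count_NDI;
#'   `library_sizes` attribute = surviving unique reads per library)
#'   and `discarded` (named tally: `low_identity` rows,
#'   `multi_mapped` reads).
#' @export
unique_mapping_filter <- function(mappings, est_lengths,
                                  min_identity = 95) {
  stopifnot(all(c("read_id", "est_id", "pct_identity", "library") %in%
                  names(mappings)))
  ok <- mappings$pct_identity >= min_identity
  low_identity <- sum(!ok)
  m <- mappings[ok, , drop = FALSE]
  # a read surviving with more than one alignment row (several ESTs,
  # or several locations on one EST) is non-unique and dropped whole
  n_targets <- table(m$read_id)
  multi <- names(n_targets)[n_targets > 1]
  m <- m[!(m$read_id %in% multi), , drop = FALSE]
  genes <- names(est_lengths)
  tab <- table(factor(m$est_id, levels = genes), factor(m$library,
                                                        levels = c("DI", "NDI")))
  counts <- data.frame(gene_id = genes,
                       length = as.integer(est_lengths),
                       count_DI = as.integer(tab[, "DI"]),
                       count_NDI = as.integer(tab[, "NDI"]),
                       stringsAsFactors = FALSE)
  attr(counts, "library_sizes") <- c(DI = sum(counts$count_DI),
                                     NDI = sum(counts$count_NDI))
  list(counts = counts,
       discarded = c(low_identity = low_identity,
                     multi_mapped = length(multi)))
}

count_matrix <- function(counts) {
  m <- as.matrix(counts[, c("count_DI", "count_NDI")])
  dimnames(m) <- list(counts$gene_id, c("DI", "NDI"))
  m
}

lib_sizes_of <- function(counts, lib_sizes = NULL) {
  ls <- lib_sizes %||% attr(counts, "library_sizes") %||%
    c(DI = sum(counts$count_DI), NDI = sum(counts$count_NDI))
  if (any(ls <= 0)) stop("library sizes must be positive")
  vapply(ls[c("DI", "NDI")], as.numeric, numeric(1))
}

# single-pair TMM factor: weighted mean of per-gene log ratios after
# double trimming, weights = inverse asymptotic (delta-method) variance
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  n_obs <- as.numeric(n_obs); n_ref <- as.numeric(n_ref)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(0)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1
  hiS <- n + 1 - loS
  rL <- rank(logR)
  rS <- rank(absE)
  keep <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  if (!any(keep)) return(0)
  sum(logR[keep] / v[keep]) / sum(1 / v[keep])
}

#' Trimmed-mean-of-M-values (TMM) normalisation factors
#'
#' Estimates between-library scaling factors from doubly trimmed
#' per-gene log ratios of count proportions, implemented from first
#' principles. The reference library is the one whose upper quartile
#' of count proportions is closest to the mean upper quartile. Genes
#' with a zero count in either library are excluded; log ratios (M)
#' are trimmed by `trim_m` on each side and log abundances (A) by
#' `trim_a`; the factor is the precision-weighted mean of the
#' surviving M values, and factors are rescaled to multiply to 1.
#' Effective library size = raw size x factor.
#'
#' @param counts Count data frame (gene_id, length, count_DI,
#'   count_NDI).
#' @param lib_sizes Optional named library sizes (defaults to the
#'   `library_sizes` attribute, else column sums).
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return A list of class `"norm_factors"`: `method`, `factors`
#'   (named, product 1), `effective_sizes`, `reference`.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  m <- count_matrix(counts)
  ls <- lib_sizes_of(counts, lib_sizes)
  if (any(colSums(m) == 0)) stop("a library has no positive counts")
  uq <- apply(sweep(m, 2, ls, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref) return(0)
    tmm_pair(m[, k], m[, ref], ls[k], ls[ref], trim_m, trim_a)
  }, numeric(1))
  factors <- 2^f
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(m)
  structure(list(method = "TMM", factors = factors,
                 effective_sizes = ls * factors,
                 reference = colnames(m)[ref]),
            class = "norm_factors")
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM(g, lib) = count * 1e9 / (length_bp * library_size)`, using
#' the trimmed EST length as the transcript length.
#'
#' @inheritParams tmm_factors
#' @return A gene x library matrix of RPKM values.
#' @export
rpkm <- function(counts, lib_sizes = NULL) {
  if (any(counts$length <= 0)) stop("lengths must be positive")
  ls <- lib_sizes_of(counts, lib_sizes)
  m <- count_matrix(counts)
  sweep(m * 1e9 / counts$length, 2, ls, "/")
}

#' Rescale RPKM values to conserve the total read count
#'
#' Multiplies the whole RPKM matrix by a single global constant so
#' that its grand sum equals the original mapped-read total from both
#' libraries, making the exact-binomial significance comparable with
#' the raw-count path.
#'
#' @param rpkm_values Gene x library RPKM matrix.
#' @param total_reads Original both-library mapped read total.
#' @return A list: `scaled` (matrix summing exactly to `total_reads`)
#'   and `constant`.
#' @export
scale_rpkm_to_counts <- function(rpkm_values, total_reads) {
  s <- sum(rpkm_values)
  if (s <= 0) stop("all RPKM values are zero")
  const <- total_reads / s
  list(scaled = rpkm_values * const, constant = const)
}

#' Exact binomial test for two-library count differences
#'
#' Conditions on the gene's total count n = x1 + x2: under the null of
#' equal relative expression, x1 ~ Binomial(n, p0) with p0 =
#' n1/(n1+n2) set by the effective library sizes. The two-sided
#' p-value follows the minimum-likelihood convention: the sum of all
#' point probabilities not exceeding that of the observed outcome.
#'
#' @param x1,x2 Observed counts (vectors, DI and NDI).
#' @param n1,n2 Effective library sizes (scalars or vectors).
#' @return P-values in (0, 1]; a gene with x1 = x2 = 0 is undefined
#'   and returns 1 (flagged via the `"undefined"` attribute).
#' @export
binom_exact_test <- function(x1, x2, n1, n2) {
  stopifnot(length(x1) == length(x2), all(x1 >= 0), all(x2 >= 0),
            all(n1 > 0), all(n2 > 0))
  n1 <- rep_len(n1, length(x1))
  n2 <- rep_len(n2, length(x1))
  p0 <- n1 / (n1 + n2)
  p <- numeric(length(x1))
  undef <- logical(length(x1))
  for (i in seq_along(x1)) {
    n <- x1[i] + x2[i]
    if (n == 0) {
      p[i] <- 1
      undef[i] <- TRUE
      next
    }
    d <- stats::dbinom(0:n, n, p0[i])
    p[i] <- min(1, sum(d[d <= d[x1[i] + 1] * (1 + 1e-7)]))
  }
  attr(p, "undefined") <- undef
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: p-values sorted ascending,
#' `adj_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1, original
#' order restored (delegates to [stats::p.adjust()]).
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pseudocount log2 fold-change
#'
#' `M = log2((xDI + c)/N_DI) - log2((xNDI + c)/N_NDI)` with
#' pseudocount `c = 0.1`, so genes unique to one library still have a
#' defined fold-change. The pseudocount enters the fold-change only,
#' never the significance test.
#'
#' @param x_di,x_ndi Raw counts.
#' @param n_di,n_ndi Effective (normalised) library sizes.
#' @param pseudocount Added to every count.
#' @return M, the DI-minus-NDI log2 fold-change.
#' @export
fold_change <- function(x_di, x_ndi, n_di, n_ndi, pseudocount = 0.1) {
  stopifnot(all(n_di > 0), all(n_ndi > 0))
  log2((x_di + pseudocount) / n_di) - log2((x_ndi + pseudocount) / n_ndi)
}

#' Call differential expression between the two libraries
#'
#' Runs the full per-gene pipeline for either normalisation path.
#' `method = "TMM"`: the exact binomial test is applied to the raw
#' counts with TMM-corrected effective library sizes. `method =
#' "RPKM"`: RPKM values are rescaled to conserve the both-library read
#' total, rounded to integers, and tested with their own column
#' totals. P-values are BH-adjusted; genes with adjusted p below
#' `alpha` are called DI-up or NDI-up by the sign of M.
#'
#' @param counts Count data frame (gene_id, length, count_DI,
#'   count_NDI; optional `library_sizes` attribute).
#' @param method `"TMM"` or `"RPKM"`.
#' @param alpha Adjusted-p call threshold.
#' @param lib_sizes Optional raw library sizes.
#' @param pseudocount Fold-change pseudocount.
#' @param exclude Gene ids to drop before testing (e.g. an exclude
#'   list of viral/bacterial annotations).
#' @return A data frame (one row per gene): `gene_id`, `count_DI`,
#'   `count_NDI`, `M`, `A`, `p_raw`, `p_adj`, `call` (`DI-up`,
#'   `NDI-up`, `ns`), `unique_to` (`DI`, `NDI`, `none`).
#' @export
call_de <- function(counts, method = c("TMM", "RPKM"), alpha = 0.001,
                    lib_sizes = NULL, pseudocount = 0.1, exclude = NULL) {
  method <- match.arg(method)
  if (!is.null(exclude)) {
    counts <- counts[!(counts$gene_id %in% exclude), , drop = FALSE]
  }
  ls <- lib_sizes_of(counts, lib_sizes)
  if (method == "TMM") {
    nf <- tmm_factors(counts, ls)
    eff <- nf$effective_sizes
    x1 <- counts$count_DI
    x2 <- counts$count_NDI
  } else {
    r <- rpkm(counts, ls)
    sc <- scale_rpkm_to_counts(r, sum(ls))
    pseudo <- round(sc$scaled)
    x1 <- pseudo[, "DI"]
    x2 <- pseudo[, "NDI"]
    eff <- c(DI = sum(pseudo[, "DI"]), NDI = sum(pseudo[, "NDI"]))
  }
  p_raw <- binom_exact_test(x1, x2, eff[["DI"]], eff[["NDI"]])
  p_adj <- bh_adjust(as.numeric(p_raw))
  M <- fold_change(x1, x2, eff[["DI"]], eff[["NDI"]], pseudocount)
  A <- (log2((x1 + pseudocount) / eff[["DI"]]) +
          log2((x2 + pseudocount) / eff[["NDI"]])) / 2
  call <- rep("ns", nrow(counts))
  call[p_adj < alpha & M > 0] <- "DI-up"
  call[p_adj < alpha & M < 0] <- "NDI-up"
  unique_to <- rep("none", nrow(counts))
  unique_to[counts$count_DI > 0 & counts$count_NDI == 0] <- "DI"
  unique_to[counts$count_NDI > 0 & counts$count_DI == 0] <- "NDI"
  data.frame(gene_id = counts$gene_id, count_DI = counts$count_DI,
             count_NDI = counts$count_NDI, M = M, A = A,
             p_raw = as.numeric(p_raw), p_adj = p_adj, call = call,
             unique_to = unique_to, stringsAsFactors = FALSE)
}
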