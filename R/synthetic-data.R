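#' Simulate a reference gene set with ground truth
#'
#' Generates a synthetic reference transcriptome standing in for the
#' annotated transcripts of a closely related model species: `n_genes`
#' random nucleotide sequences, their placement as mRNA features on a
#' synthetic genomic scaffold (for the genomic-overlap rule), and a
#' ground-truth manifest carrying the per-gene true DI-vs-NDI log2
#' fold-changes and relative abundances used by every downstream
#' generator.
#'
#' @param n_genes Number of reference genes (>= 1).
#' @param length_params Gene-length model: a list with `dist` equal to
#'   `"lognormal"` (fields `meanlog`, `sdlog`) or `"fixed"` (field
#'   `length`). Lengths are floored at `min` (default 100 bp).
#' @param n_de Number of genes with true differential expression.
#' @param log2_fc Magnitude of the true log2 fold-change given to DE
#'   genes; signs alternate DI-up / NDI-up.
#' @param library_sizes Named vector `c(DI =, NDI =)` of target reads
#'   per library, recorded in the ground truth.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `"synthetic_reference"` with elements
#'   `sequences` (named character), `gff` (mRNA feature data frame) and
#'   `truth` (class `"ground_truth"`: `gene_ids`, `gene_lengths`,
#'   `true_log2_fc`, `de_flags`, `library_sizes`,
#'   `qpcr_true_abundance`, and later `contig_provenance`).
#' @export
simulate_reference <- function(n_genes,
                               length_params = list(dist = "lognormal",
                                                    meanlog = log(700),
                                                    sdlog = 0.45),
                               n_de = 0, log2_fc = 2,
                               library_sizes = c(DI = 1e5, NDI = 1e5),
                               seed = 1) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  n_genes <- as.integer(n_genes)
  if (n_de > n_genes) stop("n_de cannot exceed n_genes")
  withr::with_seed(seed, {
    min_len <- length_params$min %||% 100L
    lengths <- switch(length_params$dist %||% "lognormal",
      lognormal = round(stats::rlnorm(n_genes, length_params$meanlog,
                                      length_params$sdlog)),
      fixed = rep(length_params$length, n_genes),
      stop("unknown length distribution: ", length_params$dist))
    lengths <- as.integer(pmax(lengths, min_len))
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    seqs <- stats::setNames(random_dna(n_genes, lengths), gene_ids)

    fc <- rep(0, n_genes)
    de <- rep(FALSE, n_genes)
    if (n_de > 0) {
      idx <- sample.int(n_genes, n_de)
      de[idx] <- TRUE
      fc[idx] <- log2_fc * rep_len(c(1, -1), n_de)
    }

    # relative abundance on the qPCR scale (2^-dCt); DE ratio = 2^fc
    base_ab <- 2^stats::runif(n_genes, -8, -2)
    qpcr_ab <- cbind(DI = base_ab * 2^(fc / 2), NDI = base_ab * 2^(-fc / 2))
    rownames(qpcr_ab) <- gene_ids

    # tile genes along one scaffold with intergenic gaps
    gaps <- sample(200:1000, n_genes, replace = TRUE)
    starts <- cumsum(gaps + c(0L, lengths[-n_genes]))
    gff <- data.frame(seqid = "scaffold_1", start = starts,
                      end = starts + lengths - 1L, strand = "+",
                      type = "mRNA", ID = gene_ids,
                      stringsAsFactors = FALSE)

    truth <- structure(list(gene_ids = gene_ids, gene_lengths = lengths,
                            true_log2_fc = fc, de_flags = de,
                            library_sizes = library_sizes,
                            contig_provenance = NULL,
                            qpcr_true_abundance = qpcr_ab),
                       class = "ground_truth")
    structure(list(sequences = seqs, gff = gff, truth = truth),
              class = "synthetic_reference")
  })
}

# deterministic e-value model: monotone decreasing in alignment
# length x identity, floored well below every tier cutoff
model_evalue <- function(aln_length, pident) {
  pmax(10^(-(aln_length * pident / 100) / 4), 1e-180)
}

mutate_dna <- function(seq, error_rate) {
  if (error_rate <= 0) return(list(seq = seq, mismatches = 0L))
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < error_rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  list(seq = paste(bases, collapse = ""), mismatches = length(hit))
}

#' Simulate redundant EST groups with constructed homology hits
#'
#' Emulates the redundancy of a de novo 454 assembly: each reference
#' gene gives rise to a variable number of overlapping contigs
#' ("ESTs") with ragged 5'/3' ends and optional per-base substitution
#' error. Homology hit tables (BLAST outfmt 6 layout) are constructed
#' directly from the known provenance rather than by running an
#' aligner: percent identity reflects the injected errors, and the
#' e-value is a deterministic decreasing function of alignment length
#' times identity. Optional no-hit contigs (random sequence, no hit
#' rows) and chimeric contigs (two subjects, neither covering more
#' than 60% of the contig) exercise the failure classes.
#'
#' @param ref A `"synthetic_reference"` from [simulate_reference()].
#' @param redundancy Per-gene EST count model: `1 + NB(mu = mean - 1,
#'   size = size)`, so `mean` is the expected ESTs per gene (the
#'   assembly-scale default is 8.86) and `size` controls the tail.
#' @param end_variability Maximum bp by which contig ends stray from
#'   the gene ends.
#' @param junk_tail_max Maximum bp of non-homologous sequence appended
#'   to each contig end (the "variable 5'/3' ends" that trimming to
#'   the alignment span later removes); 0 disables tails.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param n_nohit Number of extra contigs designed to fail every tier.
#' @param n_chimeric Number of chimeric contigs spanning two genes.
#' @param tier Name of the tier whose hit table receives the
#'   provenance-derived rows.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_contigs"`: `contigs` (named
#'   character), `hits` (named list of outfmt-6 data frames keyed by
#'   tier), `provenance` (contig to source gene, with the true query
#'   span), `chimeras` (ids), and `ref` with the provenance folded
#'   into its ground truth.
#' @export
simulate_redundant_contigs <- function(ref,
                                       redundancy = list(mean = 8.86,
                                                         size = 0.7),
                                       end_variability = 150,
                                       junk_tail_max = 0,
                                       error_rate = 0.01,
                                       n_nohit = 0, n_chimeric = 0,
                                       tier = "Ae_aegypti_transcripts",
                                       seed = 1) {
  stopifnot(inherits(ref, "synthetic_reference"))
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (redundancy$mean < 1) stop("redundancy mean must be >= 1")
  truth <- ref$truth
  withr::with_seed(seed, {
    n_est <- 1L + stats::rnbinom(length(truth$gene_ids),
                                 mu = redundancy$mean - 1,
                                 size = redundancy$size)
    contigs <- character(0)
    prov <- list()
    hits <- list()
    k <- 0L
    for (g in seq_along(truth$gene_ids)) {
      gene <- truth$gene_ids[g]
      L <- truth$gene_lengths[g]
      for (j in seq_len(n_est[g])) {
        k <- k + 1L
        id <- sprintf("contig%06d", k)
        max_off <- min(end_variability, max(L - 60L, 0L))
        s <- 1L + sample.int(max_off + 1L, 1L) - 1L
        e <- L - (sample.int(max_off + 1L, 1L) - 1L)
        if (e - s + 1L < 50L) { s <- 1L; e <- L }
        mut <- mutate_dna(substr(ref$sequences[[gene]], s, e), error_rate)
        alen <- e - s + 1L
        pid <- 100 * (1 - mut$mismatches / alen)
        j5 <- if (junk_tail_max > 0) sample(0:junk_tail_max, 1L) else 0L
        j3 <- if (junk_tail_max > 0) sample(0:junk_tail_max, 1L) else 0L
        contigs[id] <- paste0(if (j5 > 0) random_dna(1, j5) else "",
                              mut$seq,
                              if (j3 > 0) random_dna(1, j3) else "")
        qs <- j5 + 1L
        qe <- j5 + alen
        prov[[id]] <- data.frame(contig_id = id, gene_id = gene,
                                 qstart = qs, qend = qe,
                                 sstart = s, send = e,
                                 stringsAsFactors = FALSE)
        hits[[id]] <- data.frame(qseqid = id, sseqid = gene, pident = pid,
                                 length = alen, mismatch = mut$mismatches,
                                 gapopen = 0L, qstart = qs, qend = qe,
                                 sstart = s, send = e,
                                 evalue = model_evalue(alen, pid),
                                 bitscore = round(2 * alen * pid / 100, 1),
                                 stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(n_nohit)) {
      id <- sprintf("nohit%04d", j)
      contigs[id] <- random_dna(1, sample(100:400, 1))
    }
    chimeras <- character(0)
    if (n_chimeric > 0) {
      if (length(truth$gene_ids) < 2) stop("chimeras need >= 2 genes")
      for (j in seq_len(n_chimeric)) {
        id <- sprintf("chimera%04d", j)
        gs <- sample(truth$gene_ids, 2)
        halves <- lapply(gs, function(gg) {
          L <- nchar(ref$sequences[[gg]])
          substr(ref$sequences[[gg]], 1, min(L, 150))
        })
        contigs[id] <- paste0(halves[[1]], halves[[2]])
        clen <- nchar(contigs[id])
        for (h in 1:2) {
          alen <- nchar(halves[[h]])
          # each subject covers < 60% of the chimeric query
          alen_cov <- min(alen, floor(0.55 * clen))
          qs <- if (h == 1) 1L else clen - alen_cov + 1L
          qe <- qs + alen_cov - 1L
          hits[[paste0(id, "_", h)]] <-
            data.frame(qseqid = id, sseqid = gs[h], pident = 100,
                       length = alen_cov, mismatch = 0L, gapopen = 0L,
                       qstart = qs, qend = qe, sstart = 1L, send = alen_cov,
                       evalue = model_evalue(alen_cov, 100),
                       bitscore = round(2 * alen_cov, 1),
                       stringsAsFactors = FALSE)
        }
        chimeras <- c(chimeras, id)
      }
    }
    provenance <- do.call(rbind, c(prov, list(make.row.names = FALSE)))
    truth$contig_provenance <- provenance
    ref$truth <- truth
    hit_tab <- do.call(rbind, c(unname(hits), list(make.row.names = FALSE)))
    structure(list(contigs = contigs,
                   hits = stats::setNames(list(hit_tab), tier),
                   provenance = provenance, chimeras = chimeras, ref = ref),
              class = "synthetic_contigs")
  })
}

#' Simulate a two-library count matrix from ground truth
#'
#' Draws per-gene read counts for the DI and NDI libraries from a
#' negative-binomial model (Poisson at `dispersion = 0`) with per-gene
#' means proportional to gene length x expression level x library
#' size, applying the ground-truth log2 fold-changes symmetrically to
#' the two libraries. A chosen number of genes can be made strictly
#' library-unique (zero count in the other library); all remaining
#' genes are floored at one read so the unique set is exactly the
#' designated one.
#'
#' @param truth A `"ground_truth"` object.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson sampling, matching the read-sampling noise the
#'   downstream exact binomial test models.
#' @param skew DI/NDI library-size ratio applied on top of the truth's
#'   library sizes.
#' @param n_unique Number of genes present in only one library
#'   (alternating DI-only / NDI-only), drawn from the non-DE genes.
#' @param mean_count Target mean count per gene per library.
#' @param expr_sdlog Log-normal sd of the per-gene expression level.
#' @param min_de_mean Floor on the base mean of true-DE genes, so DE
#'   genes are testable at the simulated depth.
#' @param seed Integer seed.
#' @return A count data frame (`gene_id`, `length`, `count_DI`,
#'   `count_NDI`) with attributes `library_sizes` (total reads per
#'   library) and `unique_genes` (data frame `gene_id`, `library`).
#' @export
simulate_counts <- function(truth, dispersion = 0, skew = 1,
                            n_unique = 0, mean_count = 50,
                            expr_sdlog = 1, min_de_mean = 50, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (skew <= 0) stop("skew must be > 0")
  n <- length(truth$gene_ids)
  withr::with_seed(seed, {
    expr <- stats::rlnorm(n, 0, expr_sdlog)
    w <- expr * truth$gene_lengths
    mu_base <- w / mean(w) * mean_count
    boost <- truth$de_flags & mu_base < min_de_mean
    mu_base[boost] <- min_de_mean * 1.2
    fc <- truth$true_log2_fc
    mu_di <- mu_base * 2^(fc / 2) * sqrt(skew)
    mu_ndi <- mu_base * 2^(-fc / 2) / sqrt(skew)
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    }
    count_di <- draw(mu_di)
    count_ndi <- draw(mu_ndi)

    uniq <- data.frame(gene_id = character(0), library = character(0),
                       stringsAsFactors = FALSE)
    if (n_unique > 0) {
      cand <- which(!truth$de_flags)
      if (length(cand) < n_unique) stop("not enough non-DE genes for n_unique")
      pick <- sample(cand, n_unique)
      side <- rep_len(c("DI", "NDI"), n_unique)
      count_di[pick[side == "NDI"]] <- 0L
      count_ndi[pick[side == "DI"]] <- 0L
      count_di[pick[side == "DI"]] <- pmax(count_di[pick[side == "DI"]], 1L)
      count_ndi[pick[side == "NDI"]] <- pmax(count_ndi[pick[side == "NDI"]], 1L)
      uniq <- data.frame(gene_id = truth$gene_ids[pick], library = side,
                         stringsAsFactors = FALSE)
    }
    # genes not designated unique always appear in both libraries
    other <- !(truth$gene_ids %in% uniq$gene_id)
    count_di[other] <- pmax(count_di[other], 1L)
    count_ndi[other] <- pmax(count_ndi[other], 1L)

    out <- data.frame(gene_id = truth$gene_ids,
                      length = truth$gene_lengths,
                      count_DI = as.integer(count_di),
                      count_NDI = as.integer(count_ndi),
                      stringsAsFactors = FALSE)
    attr(out, "library_sizes") <- c(DI = sum(out$count_DI),
                                    NDI = sum(out$count_NDI))
    attr(out, "unique_genes") <- uniq
    out
  })
}
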