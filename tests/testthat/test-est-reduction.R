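test_that("grouping by gene partitions the assignments", {
  a <- rbind(random_group(2), random_group(1, "f"))
  a$gene_id <- c("g1", "g1", "g2")
  g <- group_by_gene(a)
  expect_equal(sort(vapply(g, nrow, integer(1)), decreasing = TRUE),
               c(2, 1), ignore_attr = TRUE)
  expect_equal(sum(vapply(g, nrow, integer(1))), nrow(a))
  expect_equal(group_by_gene(a[0, ]), list())
})

test_that("representative selection trades identity for length per the rule", {
  grp <- data.frame(est_id = c("a", "b", "c"), gene_id = "g1",
                    tier = "Ae_aegypti_transcripts",
                    pident = c(90, 86, 95), aln_length = c(300, 500, 200),
                    stringsAsFactors = FALSE)
  expect_equal(select_representative(grp, 85)$est_id, "b")

  # no member reaches the cutoff: highest identity wins
  grp <- data.frame(est_id = c("a", "b"), pident = c(80, 84),
                    aln_length = c(400, 100), stringsAsFactors = FALSE)
  expect_equal(select_representative(grp, 85)$est_id, "b")

  # singleton
  expect_equal(select_representative(grp[1, ], 85)$est_id, "a")

  # cutoff-0 tier: identity-only, subject to the 50 bp minimum
  grp <- data.frame(est_id = c("a", "b", "c"), pident = c(99, 70, 60),
                    aln_length = c(30, 200, 700), stringsAsFactors = FALSE)
  expect_equal(select_representative(grp, 0)$est_id, "b")
  expect_null(select_representative(grp[grp$aln_length < 50, ], 0))
  expect_error(select_representative(grp[0, ], 85), "empty")
})

test_that("selection matches exhaustive rule evaluation on random groups", {
  withr::with_seed(42, {
    for (i in 1:500) {
      n <- sample(1:8, 1)
      grp <- random_group(n)
      cutoff <- sample(c(0, 70, 85), 1)
      got <- select_representative(grp, cutoff)
      want <- oracle_select(grp, cutoff)
      if (is.null(want)) expect_null(got) else {
        expect_equal(got$est_id, want$est_id,
                     label = sprintf("case %d (cutoff %g)", i, cutoff))
      }
    }
  })
})

test_that("genomic hits require majority containment within annotated mRNA", {
  gff <- data.frame(seqid = "scaf1", start = c(1000, 5000),
                    end = c(1999, 5999), strand = "+", type = "mRNA",
                    ID = c("m1", "m2"), stringsAsFactors = FALSE)
  hit <- function(s, e) list(sseqid = "scaf1", sstart = s, send = e)
  expect_true(genomic_overlap_filter(hit(1400, 2399), gff))   # 600/1000
  expect_false(genomic_overlap_filter(hit(1500, 2499), gff))  # exactly 500/1000
  expect_true(genomic_overlap_filter(hit(1100, 1300), gff))   # fully inside
  expect_false(genomic_overlap_filter(hit(3000, 3999), gff))  # intergenic
  expect_error(genomic_overlap_filter(hit(1400, 2399),
                                      transform(gff, end = start - 10)),
               "malformed")
})

test_that("trimming returns the exact 1-based inclusive substring", {
  est <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  tr <- trim_to_alignment(est, list(est_id = "e1", qstart = 11, qend = 60))
  expect_equal(tr$sequence, substr(est, 11, 60))
  expect_equal(tr$length, 50)
  expect_equal(tr$bp_trimmed, 50)
  expect_equal(tr$est_id, "e1_trimmed")

  tr <- trim_to_alignment(est, list(est_id = "e1", qstart = 1, qend = 100))
  expect_equal(tr$bp_trimmed, 0)

  # translated-frame reversed coordinates normalise by min/max
  a <- trim_to_alignment(est, list(est_id = "e1", qstart = 60, qend = 11))
  b <- trim_to_alignment(est, list(est_id = "e1", qstart = 11, qend = 60))
  expect_equal(a$sequence, b$sequence)
  expect_error(trim_to_alignment(est, list(est_id = "e1", qstart = 10,
                                           qend = 101)),
               "outside")
})

test_that("reduction yields one trimmed substring per gene", {
  ref <- simulate_reference(25, seed = 8)
  ctg <- simulate_redundant_contigs(ref, error_rate = 0, seed = 9)
  ann <- annotate_ests(ctg$hits)
  red <- reduce_ests(ann$assignments, ctg$contigs, gff = ref$gff)

  expect_equal(anyDuplicated(red$ests$gene_id), 0)
  expect_equal(sort(red$ests$gene_id), sort(unique(ann$assignments$gene_id)))
  # every output is an exact contiguous substring of its source contig
  for (i in seq_len(nrow(red$ests))) {
    src <- ctg$contigs[[red$ests$source_id[i]]]
    expect_equal(red$ests$sequence[i],
                 substr(src, red$ests$qstart[i], red$ests$qend[i]))
    expect_true(grepl(red$ests$sequence[i], src, fixed = TRUE))
    expect_true(red$ests$length[i] >= 50)
    expect_lte(red$ests$length[i], nchar(src))
  }
  # N50 in the summary agrees with an independent call
  expect_equal(red$summary$n50_after, compute_n50(red$ests$length))

  # redundancy 1 per gene: output count equals assigned gene count
  ctg1 <- simulate_redundant_contigs(ref, redundancy = list(mean = 1,
                                                            size = 1),
                                     error_rate = 0, seed = 10)
  ann1 <- annotate_ests(ctg1$hits)
  red1 <- reduce_ests(ann1$assignments, ctg1$contigs, gff = ref$gff)
  expect_equal(nrow(red1$ests), length(unique(ann1$assignments$gene_id)))
})
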