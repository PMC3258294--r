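#!/usr/bin/env Rscript
# Generate the paper-like synthetic dataset and write every pipeline
# input to results/fixture/: a reference gene set (FASTA + GFF3 +
# ground-truth manifest), redundant contigs with their homology hit
# table, QC-defective reads with a contaminant hit table, the
# two-library count table, and a qPCR Ct table for the full gene set.
# All downstream drivers regenerate the same fixture from the same
# seed, so the files here are for inspection and external reuse.

suppressPackageStartupMessages(library(diapauseTx))

seed <- 1
out <- "results/fixture"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fx <- make_fixture("paper-like", seed = seed)

write_fasta(fx$ref$sequences, file.path(out, "reference_genes.fa"))
write_gff3(fx$ref$gff, file.path(out, "reference_genes.gff3"))
write_fasta(fx$contigs$contigs, file.path(out, "contigs.fa"))
write_hits(fx$contigs$hits[[1]],
           file.path(out, "hits_Ae_aegypti_transcripts.m8"))
write_fastq(fx$reads$reads, file.path(out, "reads.fastq"))
write_hits(fx$reads$contaminant_hits, file.path(out, "contaminant_hits.m8"))
write_counts(fx$counts, file.path(out, "counts.tsv"))
utils::write.table(fx$reads$manifest, file.path(out, "read_manifest.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
write_manifest(list(
  preset = fx$preset, seed = fx$seed,
  n_genes = length(fx$truth$gene_ids),
  n_de = sum(fx$truth$de_flags),
  de_genes = fx$truth$gene_ids[fx$truth$de_flags],
  true_log2_fc = fx$truth$true_log2_fc[fx$truth$de_flags],
  n_contigs = length(fx$contigs$contigs),
  n_reads = nrow(fx$reads$reads),
  library_sizes = as.list(attr(fx$counts, "library_sizes"))),
  file.path(out, "ground_truth.json"))

cat(sprintf("fixture written to %s\n", out))
cat(sprintf("  %d genes (%d true DE), %d contigs, %d reads\n",
            length(fx$truth$gene_ids), sum(fx$truth$de_flags),
            length(fx$contigs$contigs), nrow(fx$reads$reads)))
cat(sprintf("  mean ESTs per gene: %.2f\n",
            nrow(fx$contigs$provenance) /
              length(unique(fx$contigs$provenance$gene_id))))
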