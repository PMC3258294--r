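#!/usr/bin/env Rscript
# Clean the synthetic read set with the four-filter pass (ambiguous
# bases, duplicates, mean quality < 25, contaminant homology) plus
# poly-A/T trimming and the 50 bp floor, and compare the per-step
# removals with the generator's defect manifest. Writes the QC report
# and a per-library summary table in the style of a read-statistics
# table.

suppressPackageStartupMessages(library(diapauseTx))

seed <- 1
dir.create("results", showWarnings = FALSE)
fx <- make_fixture("paper-like", seed = seed)

res <- run_qc(fx$reads$reads, contaminant_hits = fx$reads$contaminant_hits)
print(res$report)

# per-step removals vs injected defects
inj <- table(fx$reads$manifest$defect)
cat("\ninjected defects:\n")
print(inj)
stopifnot(res$report$remaining + sum(res$report$removed) == res$report$input)

per_lib <- do.call(rbind, lapply(c("DI", "NDI"), function(lb) {
  inp <- fx$reads$reads[fx$reads$reads$library == lb, ]
  kept <- res$reads[res$reads$library == lb, ]
  data.frame(library = lb, total_reads = nrow(inp),
             pct_removed = round(100 * (1 - nrow(kept) / nrow(inp)), 2),
             remaining = nrow(kept),
             mean_length = round(mean(nchar(kept$seq)), 2),
             mean_gc = round(mean(diapauseTx:::gc_percent(kept$seq)), 2))
}))
utils::write.table(per_lib, "results/qc_per_library.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
write_manifest(list(input = res$report$input,
                    removed = as.list(res$report$removed),
                    trimmed_reads = res$report$trimmed_reads,
                    remaining = res$report$remaining,
                    mean_length = res$report$mean_length,
                    n50 = res$report$n50,
                    mean_gc = res$report$mean_gc),
               "results/qc_report.json")
write_fastq(res$reads, "results/clean_reads.fastq")
cat("\nwrote results/qc_report.json, results/qc_per_library.tsv\n")
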