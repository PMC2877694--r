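#!/usr/bin/env Rscript
# Stage 1: simulate the two-sample study with known truth.
#
# Generates a toy genome (with one duplicated segment and a silent
# Y-analog chromosome), a gene/exon annotation with probe selection
# regions, strand-aware 50-base reads with qualities for two samples
# (including junction-spanning and background reads), and triplicate
# array signals with detection p-values. Everything is written in
# standard text formats under results/data/.

suppressMessages(library(exonconcord))

seed <- as.integer(Sys.getenv("EXONCONCORD_SEED", "7"))
outdir <- "results/data"

cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg, outdir = outdir)

cat("Simulated dataset (seed ", seed, ") written to ", outdir, "\n", sep = "")
cat("  chromosomes: ", paste(names(ds$genome), collapse = ", "), "\n")
cat("  genes: ", nrow(ds$annotation$genes),
    " (", sum(ds$annotation$genes$status == "predicted"), " predicted)\n",
    sep = "")
cat("  exons: ", nrow(ds$annotation$exons),
    "; probesets: ", nrow(ds$annotation$probesets), "\n", sep = "")
for (k in 1:2) {
  s <- ds[[paste0("sample", k)]]$summary
  cat(sprintf("  sample %d reads: %d signal + %d background + %d junction = %d\n",
              k, s["signal"], s["background"], s["junction"], s["total"]))
}
cat("  planted novel junctions: ", nrow(ds$truth$novel_junctions), "\n",
    sep = "")
cat("  planted intergenic loci: ", nrow(ds$truth$loci), "\n", sep = "")
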