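#!/usr/bin/env Rscript
# Stage 6: exon-exon junction search.
#
# Builds the known junction database (last 49 bases of the donor exon +
# first 49 of the acceptor, <= 98 nt) and the putative database of all
# permuted within-gene exon pairs. Reads absent from the genomic
# alignments (the unmapped set) are matched exactly against the known
# database; the leftovers cascade to the putative database. Putative
# hits with >= 5 reads, >= 2 start sites and >= 12-base boundary
# overlap are reported as high-confidence novel junctions.

suppressMessages(library(exonconcord))

genome <- read_genome_fasta("results/data/genome.fa")
annotation <- read_annotation_gff3("results/data/annotation.gff3")

known <- build_known_junctions(annotation, genome)
putative <- build_putative_junctions(annotation, genome, known)
cat(sprintf("junction databases: %d known, %d putative\n",
            nrow(known), nrow(putative)))
dir.create("results/junctions", showWarnings = FALSE, recursive = TRUE)
write_junctions_fasta(known, "results/junctions/known.fa")
write_junctions_fasta(putative, "results/junctions/putative.fa")

all_hits <- list(known = NULL, putative = NULL)
for (k in 1:2) {
  reads <- read_reads_fastq(
    file.path("results/data", sprintf("reads_s%d.fastq", k)))
  aln <- read_alignments_bed(
    file.path("results/data", sprintf("alignments_s%d.bed", k)))
  unmapped <- reads[!reads$read_id %in% aln$read_id, ]
  cat(sprintf("sample %d: %d reads unmapped to the genome\n",
              k, nrow(unmapped)))

  kh <- map_junction_reads(unmapped, known)
  in_known <- vapply(unmapped$seq, function(s)
    any(grepl(s, known$seq, fixed = TRUE)), logical(1), USE.NAMES = FALSE)
  ph <- map_junction_reads(unmapped[!in_known, ], putative)
  cat(sprintf(
    "  known junctions hit: %d (%d sense reads, %d antisense)\n",
    nrow(kh), sum(kh$count), sum(kh$antisense_count)))
  cat(sprintf("  putative junctions hit: %d (%d reads)\n",
              nrow(ph), sum(ph$count)))
  hc <- high_confidence_filter(ph)
  cat(sprintf("  high-confidence novel junctions: %d\n", nrow(hc)))
  write_tsv(kh, sprintf("results/junctions/known_hits_s%d.tsv", k))
  write_tsv(ph, sprintf("results/junctions/putative_hits_s%d.tsv", k))
  write_tsv(hc, sprintf("results/junctions/high_confidence_s%d.tsv", k))
  all_hits[[1]] <- kh
}

# folding junction evidence back into exon detection
counts <- read_tsv("results/expression/exon_expression.tsv")
aug <- augment_exon_counts(
  data.frame(exon_id = counts$exon_id, count = counts$S_s1,
             stringsAsFactors = FALSE),
  all_hits[[1]])
gained <- sum(aug$count > 0 & counts$S_s1 == 0)
cat(sprintf(
  "junction evidence lifts %d exon(s) from zero to nonzero count in sample 1\n",
  gained))
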