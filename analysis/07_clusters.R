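#!/usr/bin/env Rscript
# Stage 7: novel transcribed loci from read clusters.
#
# Groups sample-1 unique reads into clusters (overlap union, gaps <= 50
# merged), labels each against the annotation, picks the exon-calling
# read-count threshold that maximizes CS between exonic and intronic
# clusters, and filters intergenic candidates by length, open reading
# frame, and proximity to probe selection regions (+/- 300 bases).

suppressMessages(library(exonconcord))

genome <- read_genome_fasta("results/data/genome.fa")
annotation <- read_annotation_gff3("results/data/annotation.gff3")
probesets <- read_probesets_bed("results/data/probesets.bed")
array <- read_tsv("results/data/array.tsv")

aln <- read_alignments_bed("results/data/alignments_s1.bed")
aln <- aln[aln$multiplicity == 1L, ]
clusters <- label_clusters(build_clusters(aln, merge_gap = 50L),
                           annotation)
cat(sprintf("%d read clusters: %s\n", nrow(clusters),
            paste(names(table(clusters$label)), table(clusters$label),
                  sep = "=", collapse = ", ")))
dir.create("results/clusters", showWarnings = FALSE, recursive = TRUE)
write_tsv(clusters, "results/clusters/clusters.tsv")

thr <- optimal_cluster_threshold(clusters)
cat(sprintf("exon-calling read-count threshold t* = %d (CS = %.3f)\n",
            thr$t_star, thr$cs))

known_len <- with(annotation$exons[annotation$exons$status == "known", ],
                  end - start)
cands <- intergenic_candidates(clusters, thr$t_star, known_len)
cat(sprintf(
  "%d intergenic candidates (count >= %d, length >= %d bases)\n",
  nrow(cands), thr$t_star, round(attr(cands, "min_length"))))

orf <- orf_filter(cands, genome)
cat(sprintf("%d candidate(s) with a stop-free reading frame\n", nrow(orf)))
if (nrow(orf) > 0) {
  write_peptides_fasta(orf, "results/clusters/peptides.fa")
}

# probeset proximity, using sample-1 majority Present calls
dabg <- as.matrix(array[, sprintf("dabg_s1_r%d", 1:3)])
present <- setNames(rowSums(dabg < 0.01) >= 2, array$probeset_id)
calls <- unname(present[probesets$probeset_id])
calls[is.na(calls)] <- FALSE
ov <- probeset_overlap(cands, probesets, calls, pad = 300L)
cat(sprintf(
  "%.0f%% of candidates lie within 300 bases of a probeset; %.0f%% of those probesets are Present\n",
  100 * ov$matched_fraction, 100 * ov$present_fraction))
write_tsv(cbind(cands[, c("cluster_id", "chrom", "start", "end", "count",
                          "strand", "length")],
                matched = ov$matched, probeset_present = ov$present),
          "results/clusters/candidates.tsv")
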