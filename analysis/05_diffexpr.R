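#!/usr/bin/env Rscript
# Stage 5: differential expression and length bias.
#
# Calls exon differential expression from counts with the
# Audic-Claverie Poisson test (single replicate per condition) and from
# fold changes; the array side uses a plain two-sample t-test on the
# triplicate log2 signals. Threshold grids aligned by CS locate the
# best-corresponding threshold pair per measure, and the DE call rate
# is stratified by exon-length quartile to expose the length bias of
# count-based testing.

suppressMessages(library(exonconcord))

tab <- read_tsv("results/expression/exon_expression.tsv")
tab <- tab[tab$L - tab$U > 0, ]
array <- read_tsv("results/data/array.tsv")
qc <- read_tsv("results/qc/summary.tsv")
T1 <- sum(tab$S_s1); T2 <- sum(tab$S_s2)  # exonic library sizes

common <- intersect(tab$exon_id, array$exon_id)
et <- tab[match(common, tab$exon_id), ]
arr <- array[match(common, array$exon_id), ]

ac_p <- ac_pvalue(et$S_s1, et$S_s2, T1, T2)
seq_fc <- fold_change(et$E_s1, et$E_s2)
tt <- array_de_ttest(arr)
array_fc <- tt$fc

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
write_tsv(data.frame(exon_id = common, S_s1 = et$S_s1, S_s2 = et$S_s2,
                     seq_fc = seq_fc, ac_p = ac_p,
                     array_fc = array_fc, array_p = tt$p),
          "results/de/per_exon.tsv")

fc_grid <- de_threshold_grid(seq_fc, array_fc,
                             seq(0.5, 4, 0.5), seq(0.5, 4, 0.5),
                             seq_mode = "fc", array_mode = "fc")
cat(sprintf(
  "fold-change grid optimum: RNA-Seq %.1f vs array %.1f (CS = %.3f)\n",
  fc_grid$optimum$seq_threshold, fc_grid$optimum$array_threshold,
  fc_grid$optimum$cs))

p_grid <- de_threshold_grid(ac_p, tt$p,
                            10^seq(-7, -1), 10^seq(-7, -1),
                            seq_mode = "p", array_mode = "p")
cat(sprintf(
  "p-value grid optimum: AC %.0e vs array t-test %.0e (CS = %.3f)\n",
  p_grid$optimum$seq_threshold, p_grid$optimum$array_threshold,
  p_grid$optimum$cs))

de_ac <- ac_p < p_grid$optimum$seq_threshold
lb <- length_bias(de_ac, et$L)
cat(sprintf(
  "AC DE rate: %.1f%% overall; %.1f%% upper length quartile (> %d b) vs %.1f%% lower (< %d b)\n",
  100 * lb$overall, 100 * lb$upper_quartile, round(lb$q_upper),
  100 * lb$lower_quartile, round(lb$q_lower)))
lb_fc <- length_bias(abs(seq_fc) >= fc_grid$optimum$seq_threshold, et$L)
cat(sprintf(
  "FC DE rate: %.1f%% overall; %.1f%% upper quartile vs %.1f%% lower\n",
  100 * lb_fc$overall, 100 * lb_fc$upper_quartile,
  100 * lb_fc$lower_quartile))
write_tsv(cbind(measure = "ac", lb$table), "results/de/length_bias_ac.tsv")
write_tsv(cbind(measure = "fc", lb_fc$table),
          "results/de/length_bias_fc.tsv")
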