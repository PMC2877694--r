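#!/usr/bin/env Rscript
# Stage 4: Present/Absent concordance with the array.
#
# Varies the RNA-Seq read-count threshold t and the array detection
# p-value cutoff independently and scores each combination with the
# correspondence score CS (modified Matthews correlation). Then, at the
# optimum, compares log2 fold changes between platforms: correlation in
# the everywhere-Present class and direction agreement among
# Absent-to-Present exons.

suppressMessages(library(exonconcord))

tab <- local({
  df <- read_tsv("results/expression/exon_expression.tsv")
  df$effective_length <- df$L - df$U
  df$eligible <- df$effective_length > 0
  df
})
array <- read_tsv("results/data/array.tsv")

grid <- detection_grid(tab, array, t_values = 0:5,
                       alpha_values = c(0.1, 0.05, 0.01, 0.001))
dir.create("results/concordance", showWarnings = FALSE, recursive = TRUE)
gm <- as.data.frame(grid$cs)
gm <- cbind(t = rownames(grid$cs), gm)
write_tsv(gm, "results/concordance/detection_grid.tsv")
cat(sprintf("detection optimum: t = %s, alpha = %s, CS = %.3f\n",
            grid$optimum$threshold, grid$optimum$alpha, grid$optimum$cs))

calls <- lapply(1:2, function(s)
  call_detection(tab, array, t = grid$optimum$threshold,
                 alpha = grid$optimum$alpha, sample = s))
universe <- intersect(calls[[1]]$exon_id, calls[[2]]$exon_id)
et <- tab[match(universe, tab$exon_id), ]
seq_fc <- fold_change(et$E_s1, et$E_s2)
arr <- array[match(universe, array$exon_id), ]
array_fc <- rowMeans(arr[, sprintf("signal_s2_r%d", 1:3)]) -
  rowMeans(arr[, sprintf("signal_s1_r%d", 1:3)])
i1 <- match(universe, calls[[1]]$exon_id)
i2 <- match(universe, calls[[2]]$exon_id)
res <- fc_correspondence(seq_fc, array_fc,
                         calls[[1]]$seq_present[i1],
                         calls[[2]]$seq_present[i2],
                         calls[[1]]$array_present[i1],
                         calls[[2]]$array_present[i2])
cat(sprintf("fold-change correlation (Present everywhere): r = %.3f\n",
            res$r_pp))
cat(sprintf(
  "direction agreement among %d Absent-to-Present exons: %.1f%%\n",
  res$n_absent_to_present, 100 * res$direction_agreement))
cls <- transition_categories(calls[[1]]$seq_present[i1],
                             calls[[2]]$seq_present[i2],
                             calls[[1]]$array_present[i1],
                             calls[[2]]$array_present[i2])
write_tsv(data.frame(exon_id = universe, seq_fc = seq_fc,
                     array_fc = array_fc, category = as.character(cls)),
          "results/concordance/fold_changes.tsv")
write_tsv(data.frame(
  statistic = c("t_opt", "alpha_opt", "cs_opt", "r_pp",
                "direction_agreement", "n_absent_to_present"),
  value = c(grid$optimum$threshold, grid$optimum$alpha, grid$optimum$cs,
            res$r_pp, res$direction_agreement, res$n_absent_to_present)),
  "results/concordance/summary.tsv")
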