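## End-to-end driver chaining the full cascade on a simulated dataset:
## read filtering -> mappability -> assignment/counting -> junction
## search -> Present/Absent concordance -> differential expression ->
## read-cluster discovery. Produces one machine-readable report holding
## every headline statistic; deterministic under the configuration seed.

#' Run the full analysis cascade on a simulated dataset
#'
#' @param config a [sim_config()]; all stage parameters below default to
#'   the values used throughout the package (expected-error threshold 6,
#'   junction contributions 49, detection p-value ladder
#'   0.1/0.05/0.01/0.001, high-confidence junction filter 5 reads /
#'   2 start sites / 12-base overlap, cluster merge gap 50, probeset pad
#'   300, silent-chromosome eligibility 100).
#' @param dataset optionally, a pre-built [simulate_dataset()] result
#'   (must match `config`); built when NULL.
#' @param qc_threshold expected-error discard threshold.
#' @param t_values,alpha_values detection grid axes.
#' @param fc_thresholds_seq,fc_thresholds_array DE fold-change grid axes.
#' @param merge_gap cluster merge gap, bases.
#' @param pad probeset padding, bases.
#' @param verbose print stage-by-stage progress.
#' @return a `concord_report` list: per-stage summaries plus every
#'   headline statistic (category tallies, grid optima, CS values,
#'   correlations, DE counts, junction counts, candidate counts).
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         qc_threshold = 6,
                         t_values = 0:5,
                         alpha_values = c(0.1, 0.05, 0.01, 0.001),
                         fc_thresholds_seq = seq(0.5, 4, by = 0.5),
                         fc_thresholds_array = seq(0.5, 4, by = 0.5),
                         merge_gap = 50L, pad = 300L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("simulate")
  ds <- if (is.null(dataset)) simulate_dataset(config) else dataset

  say("read filtering")
  qc <- stage("read_qc", lapply(list(ds$sample1$reads, ds$sample2$reads),
                                filter_reads, threshold = qc_threshold))

  say("mappability")
  profile <- stage("mappability",
                   build_mappability_profile(ds$genome,
                                             k = config$read_length))

  say("assignment and counting")
  asg <- stage("expression", lapply(1:2, function(k) {
    assign_reads(ds[[paste0("sample", k)]]$alignments, ds$annotation,
                 mode = "unique",
                 retained_ids = qc[[k]]$retained_ids)
  }))
  T1 <- asg[[1]]$n_unique_reads; T2 <- asg[[2]]$n_unique_reads
  exon_table <- stage("expression", exon_expression_table(
    ds$annotation, profile, asg[[1]]$exon_counts, asg[[2]]$exon_counts,
    T1, T2))

  say("silent-chromosome background")
  background <- if (!is.na(config$silent_chromosome)) {
    stage("expression", silent_chromosome_background(
      exon_table, config$silent_chromosome))
  } else NULL

  say("junctions")
  known_db <- stage("junctions",
                    build_known_junctions(ds$annotation, ds$genome))
  putative_db <- stage("junctions", build_putative_junctions(
    ds$annotation, ds$genome, known_db))
  jx_reads <- rbind(ds$sample1$reads, ds$sample2$reads)
  jx_ids <- c(if (!is.null(ds$sample1$junction_reads))
                ds$sample1$junction_reads$read_id,
              if (!is.null(ds$sample2$junction_reads))
                ds$sample2$junction_reads$read_id)
  jx_reads <- jx_reads[jx_reads$read_id %in% jx_ids, , drop = FALSE]
  known_hits <- stage("junctions", map_junction_reads(jx_reads, known_db))
  # cascade: the putative search sees only reads unmatched by the known DB
  in_known <- vapply(jx_reads$seq, function(s)
    any(grepl(s, known_db$seq, fixed = TRUE)), logical(1),
    USE.NAMES = FALSE)
  putative_hits <- stage("junctions", map_junction_reads(
    jx_reads[!in_known, , drop = FALSE], putative_db))
  hc <- stage("junctions", high_confidence_filter(putative_hits))

  say("concordance")
  grid <- stage("concordance", detection_grid(
    exon_table, ds$array, t_values = t_values,
    alpha_values = alpha_values,
    replicates = config$n_array_replicates))
  calls1 <- call_detection(exon_table, ds$array, t = grid$optimum$threshold,
                           alpha = grid$optimum$alpha, sample = 1L,
                           replicates = config$n_array_replicates)
  calls2 <- call_detection(exon_table, ds$array, t = grid$optimum$threshold,
                           alpha = grid$optimum$alpha, sample = 2L,
                           replicates = config$n_array_replicates)
  universe <- intersect(calls1$exon_id, calls2$exon_id)
  et <- exon_table[match(universe, exon_table$exon_id), ]
  seq_fc <- fold_change(et$E_s1, et$E_s2)
  arr <- ds$array[match(universe, ds$array$exon_id), ]
  r <- config$n_array_replicates
  a1 <- rowMeans(arr[, sprintf("signal_s1_r%d", seq_len(r)), drop = FALSE])
  a2 <- rowMeans(arr[, sprintf("signal_s2_r%d", seq_len(r)), drop = FALSE])
  array_fc <- a2 - a1
  i1 <- match(universe, calls1$exon_id); i2 <- match(universe, calls2$exon_id)
  fc_corr <- stage("concordance", fc_correspondence(
    seq_fc, array_fc, calls1$seq_present[i1], calls2$seq_present[i2],
    calls1$array_present[i1], calls2$array_present[i2]))

  say("differential expression")
  ac_p <- stage("diffexpr", ac_pvalue(et$S_s1, et$S_s2, T1, T2))
  array_tt <- stage("diffexpr", array_de_ttest(
    arr, replicates = config$n_array_replicates))
  fc_grid <- stage("diffexpr", de_threshold_grid(
    seq_fc, array_fc, fc_thresholds_seq, fc_thresholds_array,
    seq_mode = "fc", array_mode = "fc"))
  lb <- stage("diffexpr", length_bias(ac_p < 0.01, et$L))

  say("clusters")
  clusters <- stage("clusters", label_clusters(
    build_clusters(ds$sample1$alignments[
      ds$sample1$alignments$multiplicity == 1L, , drop = FALSE],
      merge_gap = merge_gap),
    ds$annotation))
  thr <- stage("clusters", optimal_cluster_threshold(clusters))
  known_len <- with(ds$annotation$exons[ds$annotation$exons$status ==
                                          "known", ], end - start)
  cands <- stage("clusters", intergenic_candidates(
    clusters, thr$t_star, known_len))
  cands_orf <- stage("clusters", orf_filter(cands, ds$genome))
  ps_calls <- array_present_calls(ds$array, sample = 1L, alpha = 0.01,
                                  replicates = config$n_array_replicates)
  ps_ov <- stage("clusters", probeset_overlap(
    cands, ds$annotation$probesets, ps_calls, pad = pad))

  report <- list(
    seed = config$seed,
    qc = list(sample1 = qc[[1]]$summary, sample2 = qc[[2]]$summary),
    nonunique_loci_fraction = mean(unlist(lapply(profile, as.logical))),
    tally = list(sample1 = asg[[1]]$tally, sample2 = asg[[2]]$tally),
    library_sizes = c(T1 = T1, T2 = T2),
    background = background,
    detection_grid = grid,
    fc_correspondence = fc_corr,
    de = list(n_ac_de = sum(ac_p < 0.01),
              fc_grid_optimum = fc_grid$optimum,
              length_bias = lb),
    junctions = list(n_known = nrow(known_db),
                     n_putative = nrow(putative_db),
                     known_hits = known_hits,
                     putative_hits = putative_hits,
                     high_confidence = hc),
    clusters = list(n_clusters = nrow(clusters),
                    t_star = thr$t_star, cs = thr$cs,
                    n_candidates = nrow(cands),
                    n_orf_retained = nrow(cands_orf),
                    probeset_overlap = ps_ov[c("matched_fraction",
                                               "present_fraction")]),
    exon_table = exon_table
  )
  class(report) <- "concord_report"
  report
}

#' @export
print.concord_report <- function(x, ...) {
  cat("exonconcord pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  library sizes: ", paste(x$library_sizes, collapse = " / "), "\n")
  cat("  detection optimum: t = ", x$detection_grid$optimum$threshold,
      ", alpha = ", x$detection_grid$optimum$alpha,
      ", CS = ", round(x$detection_grid$optimum$cs, 3), "\n", sep = "")
  cat("  fold-change r (all-Present class): ",
      round(x$fc_correspondence$r_pp, 3), "\n", sep = "")
  cat("  clusters: ", x$clusters$n_clusters, " (t* = ",
      x$clusters$t_star, ")\n", sep = "")
  invisible(x)
}
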