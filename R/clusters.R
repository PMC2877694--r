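## Novel transcribed-locus discovery from read clusters: overlapping
## reads union into clusters, clusters separated by at most a small gap
## merge, each cluster is labelled against the annotation, a read-count
## threshold separating exon-like from intron-like clusters is chosen by
## maximizing the correspondence score, and surviving intergenic
## clusters pass length, open-reading-frame and probeset-proximity
## filters.

#' Build read clusters
#'
#' Overlapping reads union into clusters; adjacent clusters separated by
#' at most `merge_gap` bases merge (the inclusive reading of "separated
#' by 50 bases": a gap of exactly `merge_gap` merges). Counts are
#' additive under merging, so the cluster counts sum to the number of
#' clustered reads. Clustering ignores strand; the consensus strand of
#' each cluster is the majority strand of its reads (`"mixed"` on ties).
#'
#' @param alignments BED6-style data.frame (`chrom`, `start`, `end`,
#'   `read_id`, `strand`); unsorted input is sorted internally.
#' @param merge_gap maximum separating gap to merge, bases (default 50).
#' @return data.frame `cluster_id`, `chrom`, `start`, `end`, `count`,
#'   `strand` (0-based half-open).
#' @export
build_clusters <- function(alignments, merge_gap = 50L) {
  if (nrow(alignments) == 0) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      count = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- intervals_to_granges(
    alignments[, c("chrom", "start", "end")], use_strand = FALSE)
  cl <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                              ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(gr, cl)
  j <- S4Vectors::subjectHits(hit)
  count <- tabulate(j, nbins = length(cl))
  strand <- vapply(seq_along(cl), function(k) {
    s <- alignments$strand[S4Vectors::queryHits(hit)[j == k]]
    n_plus <- sum(s == "+"); n_minus <- sum(s == "-")
    if (n_plus > n_minus) "+" else if (n_minus > n_plus) "-" else "mixed"
  }, character(1))
  out <- data.frame(
    cluster_id = sprintf("cl_%05d", seq_along(cl)),
    chrom = as.character(GenomicRanges::seqnames(cl)),
    start = GenomicRanges::start(cl) - 1L,
    end = GenomicRanges::end(cl),
    count = as.integer(count), strand = strand,
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}

#' Label read clusters against the annotation
#'
#' One label per cluster by precedence: exonic (at least one base
#' overlapping a known exon) > predicted-exonic (overlapping a
#' predicted/EST exon) > intronic (inside a known gene) >
#' predicted-intronic (inside a predicted gene) > intergenic. Labels
#' partition the clusters. Labelling ignores strand (transcription
#' evidence on either strand marks the locus).
#'
#' @param clusters data.frame from [build_clusters()].
#' @param annotation an [exon_annotation].
#' @return `clusters` with a `label` column.
#' @export
label_clusters <- function(clusters, annotation) {
  if (nrow(clusters) == 0) {
    clusters$label <- character(0)
    return(clusters)
  }
  gr <- intervals_to_granges(clusters[, c("chrom", "start", "end")],
                             use_strand = FALSE)
  hits_any <- function(features) {
    if (nrow(features) == 0) return(rep(FALSE, nrow(clusters)))
    f <- intervals_to_granges(features[, c("chrom", "start", "end")],
                              use_strand = FALSE)
    GenomicRanges::countOverlaps(gr, f, minoverlap = 1L,
                                 ignore.strand = TRUE) > 0
  }
  ex <- annotation$exons
  genes <- annotation$genes
  exonic <- hits_any(ex[ex$status == "known", , drop = FALSE])
  pred_exonic <- hits_any(ex[ex$status != "known", , drop = FALSE])
  intronic <- hits_any(genes[genes$status == "known", , drop = FALSE])
  pred_intronic <- hits_any(genes[genes$status != "known", , drop = FALSE])
  clusters$label <- ifelse(exonic, "exonic",
                    ifelse(pred_exonic, "predicted_exonic",
                    ifelse(intronic, "intronic",
                    ifelse(pred_intronic, "predicted_intronic",
                           "intergenic"))))
  clusters
}

#' Optimal exon-calling read-count threshold
#'
#' Scans integer thresholds t, classifying a cluster exon-like when its
#' read count is at least t, and scores each t against the known labels:
#' A = exonic clusters with count >= t, B = intronic clusters with
#' count < t, C = exonic below t, D = intronic at or above t. Returns
#' the smallest t maximizing the correspondence score (brute force over
#' all achievable thresholds).
#'
#' @param clusters labelled clusters from [label_clusters()].
#' @return list with `t_star`, `cs` (score at the optimum) and `scores`
#'   (data.frame t, cs).
#' @export
optimal_cluster_threshold <- function(clusters) {
  ex <- clusters$count[clusters$label == "exonic"]
  intr <- clusters$count[clusters$label == "intronic"]
  if (length(ex) == 0 || length(intr) == 0) {
    stop("need at least one exonic and one intronic cluster")
  }
  ts <- 0:(max(c(ex, intr)) + 1L)
  cs <- vapply(ts, function(t) {
    correspondence_score(A = sum(ex >= t), B = sum(intr < t),
                         C = sum(ex < t), D = sum(intr >= t),
                         na_on_undefined = TRUE)
  }, numeric(1))
  if (all(is.nan(cs))) stop("correspondence score undefined at every t")
  best <- which(cs == max(cs, na.rm = TRUE))[1]
  list(t_star = ts[best], cs = cs[best],
       scores = data.frame(t = ts, cs = cs))
}

#' Select intergenic novel-exon candidates
#'
#' Keeps intergenic clusters (optionally intronic too) whose read count
#' reaches the exon-calling threshold and whose length is at least the
#' lower quartile of the known-exon length distribution (short clusters
#' are unlikely to be complete exons).
#'
#' @param clusters labelled clusters.
#' @param t_star read-count threshold from
#'   [optimal_cluster_threshold()].
#' @param known_exon_lengths lengths of known exons, bases.
#' @param include_intronic also consider intronic clusters
#'   (default FALSE).
#' @return subset of `clusters` with a `length` column.
#' @export
intergenic_candidates <- function(clusters, t_star, known_exon_lengths,
                                  include_intronic = FALSE) {
  q1 <- quantile(known_exon_lengths, 0.25, names = FALSE)
  labels <- if (include_intronic) c("intergenic", "intronic") else
    "intergenic"
  out <- clusters[clusters$label %in% labels &
                    clusters$count >= t_star &
                    (clusters$end - clusters$start) >= q1, , drop = FALSE]
  out$length <- out$end - out$start
  attr(out, "min_length") <- q1
  rownames(out) <- NULL
  out
}

translate_frames <- function(seq, frames = 0:2) {
  vapply(frames, function(f) {
    s <- substr(seq, f + 1L, nchar(seq))
    s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
    if (nchar(s) < 3) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }, character(1))
}

#' Open-reading-frame filter on candidate clusters
#'
#' Translates each candidate's genomic sequence in the three reading
#' frames of its consensus strand (all six frames, with a warning, when
#' the strand is mixed) and retains candidates with at least one
#' stop-free frame; peptides of the stop-free frames are returned for
#' external domain scanning.
#'
#' @param candidates data.frame from [intergenic_candidates()].
#' @param genome a named `DNAStringSet` or character vector.
#' @return `candidates` restricted to retained rows, with list-columns
#'   `stop_free_frames` (integer vectors, 0-based frame offsets;
#'   negative-strand frames count on the reverse complement) and
#'   `peptides` (character vectors, one per stop-free frame).
#' @export
orf_filter <- function(candidates, genome) {
  genome_str <- if (methods::is(genome, "DNAStringSet"))
    as.character(genome) else genome
  if (nrow(candidates) == 0) {
    candidates$stop_free_frames <- list()
    candidates$peptides <- list()
    return(candidates)
  }
  frames_l <- vector("list", nrow(candidates))
  peps_l <- vector("list", nrow(candidates))
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cl <- candidates[i, ]
    s <- substr(genome_str[[cl$chrom]], cl$start + 1L, cl$end)
    seqs <- if (cl$strand == "+") s
            else if (cl$strand == "-") revcomp_chr(s)
            else { warning("mixed-strand cluster ", cl$cluster_id,
                           ": translating both strands")
                   c(s, revcomp_chr(s)) }
    peps <- unlist(lapply(seqs, translate_frames))
    ok <- !grepl("*", peps, fixed = TRUE) & nchar(peps) > 0
    keep[i] <- any(ok)
    frames_l[[i]] <- (seq_along(peps) - 1L)[ok]
    peps_l[[i]] <- peps[ok]
  }
  out <- candidates[keep, , drop = FALSE]
  out$stop_free_frames <- frames_l[keep]
  out$peptides <- peps_l[keep]
  rownames(out) <- NULL
  out
}

#' Write candidate peptides as FASTA
#'
#' @param candidates output of [orf_filter()].
#' @param path output FASTA file; headers are
#'   `<cluster_id>|frame<k>`.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(candidates, path) {
  ids <- character(0); peps <- character(0)
  for (i in seq_len(nrow(candidates))) {
    fr <- candidates$stop_free_frames[[i]]
    ids <- c(ids, sprintf("%s|frame%d", candidates$cluster_id[i], fr))
    peps <- c(peps, candidates$peptides[[i]])
  }
  x <- Biostrings::AAStringSet(peps)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Probeset proximity of candidate clusters
#'
#' A candidate matches when its interval intersects any probe selection
#' region extended by `pad` bases at either end. Reports the matched
#' fraction, the Present fraction among matched candidates, and the
#' count-stratified trend (candidates binned by read-count tercile).
#'
#' @param candidates data.frame of candidate clusters.
#' @param probesets data.frame of probe selection regions
#'   (`probeset_id`, `chrom`, `start`, `end`).
#' @param present_calls logical vector, one per probeset row: its
#'   Present call.
#' @param pad extension in bases at each end (default 300).
#' @return list with `matched_fraction`, `present_fraction`,
#'   `by_count_bin` (data.frame) and the per-candidate `matched` /
#'   `present` flags.
#' @export
probeset_overlap <- function(candidates, probesets, present_calls,
                             pad = 300L) {
  if (nrow(candidates) == 0) {
    return(list(matched_fraction = NA_real_, present_fraction = NA_real_,
                by_count_bin = NULL, matched = logical(0),
                present = logical(0)))
  }
  gr_c <- intervals_to_granges(candidates[, c("chrom", "start", "end")],
                               use_strand = FALSE)
  gr_p <- intervals_to_granges(probesets[, c("chrom", "start", "end")],
                               use_strand = FALSE)
  # a separating gap of exactly `pad` bases still matches; pad + 1 does not
  hit <- GenomicRanges::findOverlaps(gr_c, gr_p, maxgap = pad,
                                     ignore.strand = TRUE)
  matched <- rep(FALSE, nrow(candidates))
  present <- rep(FALSE, nrow(candidates))
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  matched[unique(q)] <- TRUE
  for (i in unique(q)) {
    present[i] <- any(present_calls[s[q == i]])
  }
  counts <- candidates$count
  br <- unique(quantile(counts, c(0, 1 / 3, 2 / 3, 1), names = FALSE))
  bin <- if (length(br) > 2) {
    cut(counts, breaks = br, include.lowest = TRUE)
  } else factor(rep("all", length(counts)))
  by_bin <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    matched_fraction = as.numeric(tapply(matched, bin, mean,
                                         default = NA_real_)),
    present_fraction = as.numeric(tapply(present & matched, bin,
                                         function(z) NA_real_)),
    stringsAsFactors = FALSE)
  # present rate among matched, per bin
  by_bin$present_fraction <- vapply(levels(bin), function(lv) {
    sel <- bin == lv & matched
    if (!any(sel)) return(NA_real_)
    mean(present[sel])
  }, numeric(1))
  list(matched_fraction = mean(matched),
       present_fraction = if (any(matched)) mean(present[matched])
                          else NA_real_,
       by_count_bin = by_bin,
       matched = matched, present = present)
}
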