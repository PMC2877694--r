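# Read clustering, labelling, threshold selection and candidate filters.

test_that("overlapping reads union and the merge gap is inclusive at 50", {
  r <- rbind(toy_read("chrA", 100L, id = "a"),
             toy_read("chrA", 140L, id = "b"))
  cl <- build_clusters(r)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start, 100L)
  expect_identical(cl$end, 190L)
  expect_identical(cl$count, 2L)

  # gap of exactly 50 bases merges ...
  r2 <- rbind(toy_read("chrA", 100L, id = "a", len = 90L),
              toy_read("chrA", 240L, id = "b", len = 50L))
  expect_identical(nrow(build_clusters(r2)), 1L)
  expect_identical(build_clusters(r2)$count, 2L)
  # ... a gap of 51 does not
  r3 <- rbind(toy_read("chrA", 100L, id = "a", len = 90L),
              toy_read("chrA", 241L, id = "b", len = 50L))
  expect_identical(nrow(build_clusters(r3)), 2L)
})

test_that("cluster counts conserve reads and shrinking the gap never
           merges more", {
  aln <- default_dataset()$sample1$alignments
  aln <- aln[aln$multiplicity == 1L, ]
  for (gap in c(0L, 25L, 50L)) {
    cl <- build_clusters(aln, merge_gap = gap)
    expect_identical(sum(cl$count), nrow(aln))
  }
  n0 <- nrow(build_clusters(aln, merge_gap = 0L))
  n25 <- nrow(build_clusters(aln, merge_gap = 25L))
  n50 <- nrow(build_clusters(aln, merge_gap = 50L))
  expect_gte(n0, n25); expect_gte(n25, n50)
})

test_that("strand consensus is the majority strand with ties mixed", {
  r <- rbind(toy_read("chrA", 100L, "+", id = "a"),
             toy_read("chrA", 110L, "+", id = "b"),
             toy_read("chrA", 120L, "-", id = "c"))
  expect_identical(build_clusters(r)$strand, "+")
  r2 <- rbind(toy_read("chrA", 100L, "+", id = "a"),
              toy_read("chrA", 110L, "-", id = "b"))
  expect_identical(build_clusters(r2)$strand, "mixed")
})

test_that("labels follow the precedence and partition the clusters", {
  ann <- toy_annotation()
  # add a predicted gene with one exon inside an intergenic region, and a
  # predicted (EST) exon inside gA's first intron
  intron1 <- c(ann$exons$end[1], ann$exons$start[2])
  ann$exons <- rbind(ann$exons, data.frame(
    exon_id = c("pg.e1", "est.e1"),
    gene_id = c("pg", "est"), transcript_id = c("pg.t1", "est.t1"),
    chrom = "chrA", start = c(5000L, intron1[1] + 40L),
    end = c(5200L, intron1[1] + 90L), strand = "+",
    status = "predicted", exon_rank = 1L, stringsAsFactors = FALSE))
  ann$genes <- rbind(ann$genes, data.frame(
    gene_id = c("pg", "est"), chrom = "chrA",
    start = c(4800L, intron1[1] + 40L),
    end = c(5400L, intron1[1] + 90L),
    strand = "+", status = "predicted", stringsAsFactors = FALSE))

  cl <- data.frame(
    cluster_id = paste0("c", 1:5), chrom = "chrA",
    start = c(ann$exons$end[1] - 1L,      # 1 base of known exon
              intron1[1] + 50L,           # inside EST exon within intron
              intron1[1] + 5L,            # known intron only
              5250L,                      # predicted gene intron
              5900L),                     # outside everything
    end = c(ann$exons$end[1] + 30L,
            intron1[1] + 60L,
            intron1[1] + 30L,
            5300L,
            5950L),
    count = 5L, strand = "+", stringsAsFactors = FALSE)
  lab <- label_clusters(cl, ann)
  expect_identical(lab$label,
                   c("exonic", "predicted_exonic", "intronic",
                     "predicted_intronic", "intergenic"))
})

test_that("the optimal threshold is the smallest maximizer of the
           correspondence score", {
  cl <- data.frame(cluster_id = paste0("c", 1:6), chrom = "chrA",
                   start = 0L, end = 10L,
                   count = c(20L, 25L, 30L, 1L, 2L, 3L),
                   strand = "+",
                   label = rep(c("exonic", "intronic"), each = 3L),
                   stringsAsFactors = FALSE)
  res <- optimal_cluster_threshold(cl)
  expect_identical(res$t_star, 4L)
  expect_equal(res$cs, 1)

  # identical count sets are degenerate: the best achievable score is 0
  cl$count <- rep(c(1L, 2L, 3L), 2L)
  res2 <- optimal_cluster_threshold(cl)
  expect_equal(res2$cs, 0)

  cl$label <- "exonic"
  expect_error(optimal_cluster_threshold(cl), "intronic")
})

test_that("the threshold scan equals an independent brute-force search", {
  set.seed(31)
  for (rep in 1:5) {
    counts_ex <- rpois(40, 25); counts_in <- rpois(60, 3)
    cl <- data.frame(
      cluster_id = seq_len(100), chrom = "chrA", start = 0L, end = 10L,
      count = c(counts_ex, counts_in), strand = "+",
      label = rep(c("exonic", "intronic"), c(40L, 60L)),
      stringsAsFactors = FALSE)
    res <- optimal_cluster_threshold(cl)
    # independent oracle: direct formula, loop over every threshold
    best_cs <- -Inf; best_t <- NA
    for (t in 0:(max(cl$count) + 1L)) {
      A <- sum(counts_ex >= t); C <- sum(counts_ex < t)
      B <- sum(counts_in < t); D <- sum(counts_in >= t)
      den <- sqrt(prod(c(A + C, A + D, B + C, B + D)))
      if (den == 0) next
      cs <- (A * B - C * D) / den
      if (cs > best_cs) { best_cs <- cs; best_t <- t }
    }
    expect_identical(res$t_star, best_t)
    expect_equal(res$cs, best_cs)
  }
})

test_that("well-separated count populations are recovered with a high
           score", {
  set.seed(32)
  cl <- data.frame(
    cluster_id = seq_len(200), chrom = "chrA", start = 0L, end = 10L,
    count = c(rpois(100, 30), rpois(100, 2)), strand = "+",
    label = rep(c("exonic", "intronic"), each = 100L),
    stringsAsFactors = FALSE)
  res <- optimal_cluster_threshold(cl)
  expect_gt(res$cs, 0.9)
  expect_gt(res$t_star, 2L)
  expect_lt(res$t_star, 30L)
})

test_that("candidate selection applies label, threshold and length
           filters", {
  cl <- data.frame(
    cluster_id = paste0("c", 1:4), chrom = "chrA",
    start = c(0L, 0L, 0L, 0L),
    end = c(200L, 100L, 200L, 200L),
    count = c(20L, 20L, 3L, 20L), strand = "+",
    label = c("intergenic", "intergenic", "intergenic", "exonic"),
    stringsAsFactors = FALSE)
  known_lengths <- c(rep(120, 26), rep(200, 49), rep(400, 25))
  out <- intergenic_candidates(cl, t_star = 10L, known_lengths)
  expect_identical(out$cluster_id, "c1")   # c2 short, c3 weak, c4 exonic
  expect_identical(attr(out, "min_length"), 120)
})

test_that("ORF filtering matches a brute-force codon scan", {
  # brute-force oracle: scan codons per frame for stop triplets
  has_stop <- function(seq, frame) {
    s <- substr(seq, frame + 1, nchar(seq))
    codons <- substring(s, seq(1, nchar(s) - 2, by = 3),
                        seq(3, nchar(s), by = 3))
    any(codons %in% c("TAA", "TAG", "TGA"))
  }
  set.seed(41)
  genome <- c(chrA = random_dna_str(4000))
  for (i in 1:10) {
    start <- sample(1:3600, 1) - 1L
    len <- 3L * sample(60:120, 1)
    cand <- data.frame(cluster_id = "c", chrom = "chrA",
                       start = start, end = start + len,
                       count = 20L, strand = "+", label = "intergenic",
                       length = len, stringsAsFactors = FALSE)
    res <- orf_filter(cand, genome)
    seq <- substr(genome[["chrA"]], start + 1L, start + len)
    oracle_free <- !vapply(0:2, function(f) has_stop(seq, f), logical(1))
    expect_identical(nrow(res) == 1L, any(oracle_free))
    if (nrow(res) == 1L) {
      expect_identical(res$stop_free_frames[[1]], (0:2)[oracle_free])
    }
  }
})

test_that("ORF filtering respects strand and emits clean peptides", {
  orf <- paste(rep("ATGGCCGCA", 30), collapse = "")      # stop-free
  genome <- c(chrA = orf)
  cand <- data.frame(cluster_id = "c", chrom = "chrA", start = 0L,
                     end = nchar(orf), count = 20L, strand = "+",
                     label = "intergenic", length = nchar(orf),
                     stringsAsFactors = FALSE)
  res <- orf_filter(cand, genome)
  expect_identical(nrow(res), 1L)
  expect_true(0L %in% res$stop_free_frames[[1]])
  expect_false(any(grepl("\\*", unlist(res$peptides))))

  # all-frames-stopped sequence is removed (TTAA repeats place an
  # in-frame TAA in every frame)
  stopper <- strrep("TTAA", 60)
  genome2 <- c(chrA = stopper)
  cand2 <- cand; cand2$end <- nchar(stopper)
  expect_identical(nrow(orf_filter(cand2, genome2)), 0L)

  # mixed strand translates six frames with a warning
  cand3 <- cand; cand3$strand <- "mixed"
  expect_warning(orf_filter(cand3, genome), "mixed")
})

test_that("probeset proximity respects the padding boundary", {
  ps <- data.frame(probeset_id = "p1", chrom = "chrA",
                   start = 1000L, end = 1100L, stringsAsFactors = FALSE)
  near <- data.frame(cluster_id = "c1", chrom = "chrA",
                     start = 1200L, end = 1400L, count = 10L,
                     strand = "+", stringsAsFactors = FALSE)
  far <- near; far$start <- 1401L; far$end <- 1600L
  expect_true(probeset_overlap(near, ps, TRUE, pad = 300L)$matched)
  # exactly 300 bases away still matches; 301 does not
  at300 <- near; at300$start <- 1400L
  expect_true(probeset_overlap(at300, ps, TRUE, pad = 300L)$matched)
  expect_false(probeset_overlap(far, ps, TRUE, pad = 300L)$matched)
})

test_that("planted intergenic loci always carry a matched Present
           probeset", {
  ds <- default_dataset()
  aln <- ds$sample1$alignments[ds$sample1$alignments$multiplicity == 1L, ]
  cl <- label_clusters(build_clusters(aln), ds$annotation)
  thr <- optimal_cluster_threshold(cl)
  lens <- with(ds$annotation$exons[ds$annotation$exons$status == "known", ],
               end - start)
  cands <- intergenic_candidates(cl, thr$t_star, lens)
  expect_gt(nrow(cands), 0L)
  calls <- rep(TRUE, nrow(ds$annotation$probesets))
  ov <- probeset_overlap(cands, ds$annotation$probesets, calls)
  expect_identical(ov$matched_fraction, 1)
})
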