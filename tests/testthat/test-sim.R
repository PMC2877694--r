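# Synthetic-data generator: determinism, conservation, truth alignment.

test_that("fixed seed reproduces every artifact byte-for-byte", {
  cfg <- small_config(seed = 23)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("duplicated blocks are copied with 100% identity at two loci", {
  ds <- small_dataset()
  dup <- ds$duplications
  expect_gte(nrow(dup), 1L)
  g <- as.character(ds$genome)
  for (i in seq_len(nrow(dup))) {
    src <- substr(g[[dup$src_chrom[i]]], dup$src_start[i] + 1L,
                  dup$src_start[i] + dup$length[i])
    dst <- substr(g[[dup$dst_chrom[i]]], dup$dst_start[i] + 1L,
                  dup$dst_start[i] + dup$length[i])
    expect_identical(src, dst)
  }
})

test_that("duplication block longer than the chromosome is rejected", {
  expect_error(sim_config(chromosome_length = 400L,
                          duplication_length = 500L),
               "configuration")
})

test_that("a genome without duplications has an all-zero profile", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2L,
                    chromosome_length = 10000L, n_genes = 2L,
                    duplication_blocks = 0L,
                    intergenic_expressed_loci = 0L)
  g <- generate_genome(cfg)
  prof <- build_mappability_profile(g$genome, k = 50L)
  expect_false(any(unlist(prof)))
})

test_that("read conservation: total = signal + background + junction", {
  for (s in paste0("sample", 1:2)) {
    sm <- small_dataset()[[s]]$summary
    expect_identical(unname(sm["total"]),
                     unname(sm["signal"] + sm["background"] + sm["junction"]))
    expect_identical(nrow(small_dataset()[[s]]$reads), unname(sm["total"]))
  }
})

test_that("with zero background the silent chromosome is empty and all
           genomic reads land on annotated or planted regions", {
  cfg <- sim_config(seed = 3, n_chromosomes = 3L,
                    chromosome_length = 60000L, n_genes = 9L,
                    sequencing_depth = 4000L, background_rate = 0,
                    intronic_rate_factor = 0, duplication_blocks = 0L)
  ds <- simulate_dataset(cfg)
  aln <- ds$sample1$alignments
  expect_identical(sum(aln$chrom == "chrY"), 0L)
  regions <- rbind(
    ds$annotation$exons[, c("chrom", "start", "end")],
    ds$annotation$intergenic_loci[, c("chrom", "start", "end")])
  gr_reads <- intervals_to_granges(aln[, c("chrom", "start", "end")],
                                   use_strand = FALSE)
  gr_reg <- intervals_to_granges(regions, use_strand = FALSE)
  n_hit <- GenomicRanges::countOverlaps(gr_reads, gr_reg,
                                        ignore.strand = TRUE)
  expect_true(all(n_hit > 0))
})

test_that("exons with zero truth expression receive zero signal reads", {
  cfg <- sim_config(seed = 3, background_rate = 0,
                    duplication_blocks = 0L, sequencing_depth = 5000L)
  ds <- simulate_dataset(cfg)
  counts <- assign_reads(ds$sample1$alignments, ds$annotation,
                         mode = "unique")$exon_counts
  silent <- ds$truth$exons$exon_id[ds$truth$exons$expr_s1 == 0 &
                                     ds$truth$exons$expr_s2 == 0]
  expect_true(all(counts$count[counts$exon_id %in% silent] == 0L))
})

test_that("per-exon counts are Poisson with mean expression x length x
           depth scale", {
  cfg <- sim_config(seed = 101, n_chromosomes = 2L,
                    chromosome_length = 40000L, n_genes = 4L,
                    sequencing_depth = 2000L, background_rate = 0,
                    duplication_blocks = 0L, novel_junction_count = 0L,
                    intergenic_expressed_loci = 0L,
                    antisense_fraction = 0, error_rate_per_base = 0)
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  et <- ann$truth$exons
  lam_mass <- sum(et$expr_s1 * et$length)
  scale <- cfg$sequencing_depth / lam_mass
  target <- which.max(et$expr_s1 * et$length)   # best-covered exon
  lambda <- et$expr_s1[target] * et$length[target] * scale
  n_rep <- 150L
  counts <- vapply(seq_len(n_rep), function(r) {
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    s <- simulate_reads(g$genome, ann$annotation, ann$truth, cfg_r, 1L)
    gr <- intervals_to_granges(
      s$alignments[, c("chrom", "start", "end", "strand")])
    ex <- ann$annotation$exons[target, ]
    sum(GenomicRanges::countOverlaps(
      intervals_to_granges(ex[, c("chrom", "start", "end", "strand")]),
      gr))
  }, numeric(1))
  se <- sqrt(lambda / n_rep)     # Poisson standard error of the mean
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("detection p-values are uniform for unexpressed probesets and
           concentrated near zero for expressed ones", {
  ds <- default_dataset()
  cfg <- ds$config
  null_p <- c(); expr_p <- c()
  for (s in 1:40) {                 # many replicate arrays of one truth
    cfg_s <- cfg; cfg_s$seed <- 5000L + s
    arr <- simulate_array(ds$annotation, ds$truth, cfg_s)
    et <- ds$truth$exons[match(arr$exon_id, ds$truth$exons$exon_id), ]
    for (r in 1:3) {
      on1 <- !is.na(et$expr_s1) & et$expr_s1 > 0
      p <- arr[[sprintf("dabg_s1_r%d", r)]]
      null_p <- c(null_p, p[!is.na(et$expr_s1) & et$expr_s1 == 0])
      expr_p <- c(expr_p, p[on1 & et$expr_s1 > 5])
    }
  }
  frac <- mean(null_p < 0.01)
  se <- sqrt(0.01 * 0.99 / length(null_p))
  expect_lt(abs(frac - 0.01), 3 * se + 1e-6)
  expect_gt(mean(expr_p < 0.01), 0.95)   # Beta(0.01, 1): 0.01^0.01 = 0.955
})

test_that("planted novel junctions join non-adjacent exons of one gene and
           truth covers every exon", {
  ds <- default_dataset()
  nj <- ds$truth$novel_junctions
  exons <- ds$annotation$exons
  expect_gt(nrow(nj), 0L)
  for (i in seq_len(nrow(nj))) {
    d <- exons[exons$exon_id == nj$donor_exon[i], ]
    a <- exons[exons$exon_id == nj$acceptor_exon[i], ]
    expect_identical(d$gene_id, a$gene_id)
    expect_gt(abs(d$exon_rank - a$exon_rank), 1L)
  }
  expect_setequal(ds$truth$exons$exon_id, exons$exon_id)
})
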