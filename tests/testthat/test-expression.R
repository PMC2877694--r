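# Read assignment, category tallies, normalized expression and the
# silent-chromosome background measure.

test_that("a unique read inside a known exon counts for it and tallies as
           exonic", {
  ann <- toy_annotation()
  ex <- ann$exons[1, ]                      # gA.e1, + strand
  r <- toy_read("chrA", ex$start + 10L, "+")
  res <- assign_reads(r, ann, mode = "unique")
  expect_identical(res$exon_counts$count[res$exon_counts$exon_id ==
                                           "gA.e1"], 1L)
  expect_identical(unname(res$tally["known_exon"]), 1L)
  expect_identical(sum(res$tally), res$n_reads)
})

test_that("multi-locus reads are excluded in unique mode and credited at
           every locus in all mode", {
  ann <- toy_annotation()
  e1 <- ann$exons[1, ]; e4 <- ann$exons[4, ]
  r <- rbind(toy_read("chrA", e1$start, "+", id = "m1", mult = 2L),
             toy_read("chrA", e4$start, "+", id = "m1", mult = 2L))
  uniq <- assign_reads(r, ann, mode = "unique")
  expect_true(all(uniq$exon_counts$count == 0L))
  expect_identical(uniq$n_excluded_multi, 1L)
  both <- assign_reads(r, ann, mode = "all")
  cnt <- setNames(both$exon_counts$count, both$exon_counts$exon_id)
  expect_identical(unname(cnt["gA.e1"]), 1L)
  expect_identical(unname(cnt["gA.e4"]), 1L)
  # the read is one read: tallied once
  expect_identical(sum(both$tally), 1L)
})

test_that("one base of exon overlap wins over 49 bases of intron", {
  ann <- toy_annotation()
  e2 <- ann$exons[2, ]                      # gA.e2 at [start, end)
  r <- toy_read("chrA", e2$end - 1L, "+")   # 1 base in exon, 49 in intron
  res <- assign_reads(r, ann)
  expect_identical(res$exon_counts$count[res$exon_counts$exon_id ==
                                           "gA.e2"], 1L)
  expect_identical(unname(res$tally["known_exon"]), 1L)
  # brute-force interval check agrees
  expect_true(e2$end - 1L < e2$end && e2$end - 1L + 50L > e2$start)
})

test_that("strand-aware assignment drops antisense reads unless
           disabled", {
  ann <- toy_annotation()
  ex <- ann$exons[1, ]
  anti <- toy_read("chrA", ex$start + 5L, "-")
  strict <- assign_reads(anti, ann)
  expect_true(all(strict$exon_counts$count == 0L))
  loose <- assign_reads(anti, ann, strand_check = FALSE)
  expect_identical(loose$exon_counts$count[1], 1L)
})

test_that("reads on unknown chromosomes are rejected with the record", {
  expect_error(assign_reads(toy_read("chrZZ", 100L, id = "bad"),
                            toy_annotation()),
               "bad")
})

test_that("unique-mode counts never exceed all-mode counts and tallies
           conserve reads", {
  ds <- default_dataset()
  aln <- ds$sample1$alignments
  uniq <- assign_reads(aln, ds$annotation, mode = "unique")
  all_m <- assign_reads(aln, ds$annotation, mode = "all")
  expect_true(all(uniq$exon_counts$count <= all_m$exon_counts$count))
  expect_identical(sum(uniq$tally), uniq$n_reads)
  expect_identical(uniq$n_reads + uniq$n_excluded_multi,
                   length(unique(aln$read_id)))
  expect_identical(sum(all_m$tally), all_m$n_reads)
})

test_that("with no background or duplications every read is annotated", {
  cfg <- sim_config(seed = 3, background_rate = 0, duplication_blocks = 0L,
                    intergenic_expressed_loci = 0L,
                    sequencing_depth = 5000L)
  ds <- simulate_dataset(cfg)
  res <- assign_reads(ds$sample1$alignments, ds$annotation)
  expect_identical(unname(res$tally["unannotated"]), 0L)
})

test_that("normalized expression follows E = C*S/((L-U)*T)", {
  expect_equal(normalized_expression(10, 1100, 100, 1e7), 1.0)
  expect_equal(normalized_expression(0, 500, 10, 1e7), 0)
  # a production-scale library: T = 28,371,318 uniquely mappable reads
  expect_equal(normalized_expression(3, 150, 0, 28371318),
               1e9 * 3 / (150 * 28371318))
  expect_equal(round(normalized_expression(3, 150, 0, 28371318), 3), 0.705)
  expect_error(normalized_expression(5, 50, 50, 1e7), "effective length")
  expect_error(normalized_expression(5, 100, 0, 0), "T_total")
})

test_that("normalized expression is linear in S and inverse in T", {
  S <- c(1, 5, 20)
  expect_equal(normalized_expression(2 * S, 300, 10, 1e6),
               2 * normalized_expression(S, 300, 10, 1e6))
  expect_equal(normalized_expression(S, 300, 10, 2e6),
               normalized_expression(S, 300, 10, 1e6) / 2)
})

test_that("expression table excludes exons with non-positive effective
           length", {
  ann <- toy_annotation()
  # force U = L on one exon with a saturated fake profile
  prof <- build_mappability_profile(toy_genome(), k = 50L)
  ex <- ann$exons[1, ]
  prof[[ex$chrom]][(ex$start + 1L):ex$end] <- TRUE
  counts <- data.frame(exon_id = ann$exons$exon_id,
                       count = 1L, stringsAsFactors = FALSE)
  tab <- exon_expression_table(ann, prof, counts, counts, 1e6, 1e6)
  expect_false(tab$eligible[tab$exon_id == "gA.e1"])
  expect_true(is.na(tab$E_s1[tab$exon_id == "gA.e1"]))
  expect_true(all(tab$eligible[tab$exon_id != "gA.e1"]))
})

test_that("silent-chromosome background is zero without background reads
           and reproduces the eligibility mechanics", {
  cfg <- sim_config(seed = 3, background_rate = 0,
                    duplication_blocks = 0L, sequencing_depth = 5000L)
  ds <- simulate_dataset(cfg)
  counts <- assign_reads(ds$sample1$alignments, ds$annotation)$exon_counts
  tab <- exon_expression_table(ds$annotation, NULL, counts, counts,
                               5000, 5000)
  bg <- silent_chromosome_background(tab, "chrY")
  expect_identical(bg$proportion, 0)
  expect_identical(bg$n_detected, 0L)

  # constructed analog of 3 detected among 1178 eligible of 1835 total
  n_total <- 1835L; n_eligible <- 1178L
  tab2 <- toy_exon_table(rep(0L, n_total), rep(0L, n_total), L = 300L)
  tab2$chrom <- "chrS"
  tab2$effective_length <- c(rep(300L, n_eligible),
                             rep(90L, n_total - n_eligible))
  tab2$S_s1[1:3] <- 1L
  bg2 <- silent_chromosome_background(tab2, "chrS")
  expect_identical(bg2$n_eligible, n_eligible)
  expect_equal(round(100 * bg2$proportion, 2), 0.25)

  tab2$effective_length <- 90L
  expect_error(silent_chromosome_background(tab2, "chrS"), "eligible")
})
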