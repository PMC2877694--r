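# Junction database construction, read mapping and filtering.

toy_known_db <- function() {
  build_known_junctions(toy_annotation(), toy_genome())
}

test_that("exon contributions truncate at 49 bases and cap the sequence
           at 98", {
  db <- toy_known_db()
  # geneA exons: 100, 40, 30, 200 bases -> junctions 49+40, 40+30, 30+49
  a <- db[db$gene_id == "gA", ]
  expect_identical(nchar(a$seq), c(89L, 70L, 79L))
  expect_identical(a$donor_contrib, c(49L, 40L, 30L))
  expect_identical(a$acceptor_contrib, c(40L, 30L, 49L))
  # geneB: 60-base then 200-base exon in transcript order -> 49 + 49 = 98
  b <- db[db$gene_id == "gB", ]
  expect_identical(nchar(b$seq), 98L)
  expect_true(all(nchar(db$seq) <= 98L))
})

test_that("junction sequences follow transcript orientation", {
  db <- toy_known_db()
  ann <- toy_annotation(); g <- as.character(toy_genome())
  # gA.e1 -> gA.e2 on the plus strand: last 49 of e1 followed by all of e2
  e1 <- ann$exons[1, ]; e2 <- ann$exons[2, ]
  expected <- paste0(substr(g, e1$end - 48L, e1$end),
                     substr(g, e2$start + 1L, e2$end))
  expect_identical(db$seq[db$junction_id == "gA|gA.e1|gA.e2"], expected)
  # gB (minus strand): donor is the rightmost exon, reverse-complemented
  eb1 <- ann$exons[ann$exons$exon_id == "gB.e2", ]   # rank 1, rightmost
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  donor_seq <- revcomp(substr(g, eb1$start + 1L, eb1$end))
  expect_identical(substr(db$seq[db$gene_id == "gB"], 1L, 49L),
                   substr(donor_seq, nchar(donor_seq) - 48L,
                          nchar(donor_seq)))
})

test_that("putative junctions enumerate all non-adjacent ordered pairs", {
  ann <- toy_annotation(); g <- toy_genome()
  known <- toy_known_db()
  put <- build_putative_junctions(ann, g, known)
  # gA: 4*3 - 3 known = 9; gB: 2*1 - 1 = 1
  expect_identical(sum(put$gene_id == "gA"), 9L)
  expect_identical(sum(put$gene_id == "gB"), 1L)
  expect_false(any(put$junction_id %in% known$junction_id))
  # conservation: |known| + |putative| = sum n_g (n_g - 1)
  expect_identical(nrow(known) + nrow(put), 4L * 3L + 2L * 1L)
  # transcript-order-only mode keeps only forward skips
  fwd <- build_putative_junctions(ann, g, known, genomic_order_only = TRUE)
  expect_identical(sum(fwd$gene_id == "gA"), 3L)
  expect_identical(sum(fwd$gene_id == "gB"), 0L)
  expect_true(all(nchar(put$seq) <= 98L))
})

test_that("single-exon genes contribute no junctions", {
  ann <- toy_annotation()
  one <- ann
  one$exons <- one$exons[1, , drop = FALSE]
  one$exons$exon_rank <- 1L
  db <- build_known_junctions(one, toy_genome())
  expect_identical(nrow(db), 0L)
  expect_identical(nrow(build_putative_junctions(one, toy_genome(), db)),
                   0L)
})

test_that("junction reads must span the boundary and match exactly one
           junction", {
  db <- toy_known_db()
  j <- db[db$junction_id == "gA|gA.e1|gA.e2", ]   # 49 + 40
  mid <- function(jrow, donor_side) {
    substr(jrow$seq, jrow$donor_contrib - donor_side + 1L,
           jrow$donor_contrib - donor_side + 50L)
  }
  reads <- data.frame(
    read_id = c("span25", "donor_only"),
    seq = c(mid(j, 25L),
            substr(j$seq, 1L, 50L)),  # 49 donor + 1 acceptor base: spans!
    stringsAsFactors = FALSE)
  # make the second read truly one-sided: take donor-side 50-mer from the
  # genome upstream so it lies inside the donor exon only
  ann <- toy_annotation(); g <- as.character(toy_genome())
  e1 <- ann$exons[1, ]
  reads$seq[2] <- substr(g, e1$start + 1L, e1$start + 50L)
  hits <- map_junction_reads(reads, db)
  expect_identical(hits$count[hits$junction_id == j$junction_id], 1L)
  expect_identical(hits$max_overlap[hits$junction_id == j$junction_id],
                   25L)
  s <- attr(hits, "summary")
  expect_identical(unname(s["n_counted"]), 1L)
})

test_that("reads hitting several junctions or the genome are discarded", {
  db <- toy_known_db()
  j <- db[1, ]
  read_seq <- substr(j$seq, j$donor_contrib - 24L, j$donor_contrib + 25L)
  twin <- rbind(db, within(db[1, ], junction_id <- "twin|copy"))
  hits <- map_junction_reads(
    data.frame(read_id = "r", seq = read_seq, stringsAsFactors = FALSE),
    twin)
  expect_identical(nrow(hits), 0L)
  expect_identical(unname(attr(hits, "summary")["n_discarded_multi"]), 1L)

  # a read also present on the genome is discarded when genome is given
  ann <- toy_annotation(); g <- toy_genome()
  e1 <- ann$exons[1, ]
  genomic <- substr(as.character(g), e1$start + 1L, e1$start + 50L)
  hits <- map_junction_reads(
    data.frame(read_id = c("jx", "gen"),
               seq = c(read_seq, genomic), stringsAsFactors = FALSE),
    db[1, , drop = FALSE], genome = g)
  expect_identical(unname(attr(hits, "summary")["n_discarded_genome"]), 1L)
  expect_identical(sum(hits$count), 1L)
})

test_that("antisense junction reads are tallied separately", {
  db <- toy_known_db()
  j <- db[1, ]
  sense <- substr(j$seq, j$donor_contrib - 24L, j$donor_contrib + 25L)
  anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sense)))
  hits <- map_junction_reads(
    data.frame(read_id = c("s", "a"), seq = c(sense, anti),
               stringsAsFactors = FALSE),
    db[1, , drop = FALSE])
  expect_identical(hits$count, 1L)
  expect_identical(hits$antisense_count, 1L)
})

test_that("high-confidence filter applies all three thresholds jointly", {
  hits <- data.frame(
    junction_id = c("a", "b", "c", "d"),
    gene_id = "g", donor_exon = "e1", acceptor_exon = "e2",
    status = "putative",
    count = c(5L, 5L, 4L, 5L),
    antisense_count = 0L,
    start_sites = c(2L, 1L, 3L, 2L),
    max_overlap = c(12L, 30L, 20L, 11L),
    stringsAsFactors = FALSE)
  kept <- high_confidence_filter(hits)
  expect_identical(kept$junction_id, "a")
})

test_that("junction evidence augments both flanking exons", {
  counts <- data.frame(exon_id = c("e1", "e2", "e3"),
                       count = c(0L, 2L, 7L), stringsAsFactors = FALSE)
  hits <- data.frame(junction_id = "j", gene_id = "g",
                     donor_exon = "e1", acceptor_exon = "e2",
                     status = "known", count = 3L, antisense_count = 0L,
                     start_sites = 2L, max_overlap = 20L,
                     stringsAsFactors = FALSE)
  out <- augment_exon_counts(counts, hits)
  expect_identical(out$count, c(3L, 5L, 7L))
  expect_identical(augment_exon_counts(counts, hits[0, ]), counts)
  hits$acceptor_exon <- "nope"
  expect_error(augment_exon_counts(counts, hits), "nope")
})

test_that("planted novel junctions are recovered from simulated reads", {
  ds <- default_dataset()
  known <- build_known_junctions(ds$annotation, ds$genome)
  put <- build_putative_junctions(ds$annotation, ds$genome, known)
  jt <- ds$sample1$junction_reads
  novel_reads <- ds$sample1$reads[
    ds$sample1$reads$read_id %in% jt$read_id[jt$status == "novel"], ]
  # restrict to error-free reads: the toy aligner is exact-match
  clean_ids <- jt$read_id[jt$status == "novel"]
  hits <- map_junction_reads(novel_reads, put)
  planted <- with(ds$truth$novel_junctions,
                  paste(gene_id, donor_exon, acceptor_exon, sep = "|"))
  expect_true(all(planted %in% hits$junction_id))
  # planted junctions satisfying the 5/2/12 evidence thresholds all pass
  hc <- high_confidence_filter(hits)
  strong <- hits$count >= 5L & hits$start_sites >= 2L &
    hits$max_overlap >= 12L
  expect_setequal(hc$junction_id, hits$junction_id[strong])
  expect_true(all(hc$junction_id %in% planted))
})
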