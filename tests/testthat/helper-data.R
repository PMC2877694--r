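# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# the default simulated study: two samples, triplicate arrays, known truth
default_dataset <- function() {
  memo("ds_default", function() simulate_dataset(sim_config(seed = 7)))
}

default_profile <- function() {
  memo("profile_default", function()
    build_mappability_profile(default_dataset()$genome, k = 50L))
}

# small dataset for fast determinism / conservation checks
small_config <- function(seed = 11) {
  sim_config(seed = seed, n_chromosomes = 2L, chromosome_length = 40000L,
             n_genes = 8L, sequencing_depth = 3000L,
             duplication_blocks = 1L, duplication_length = 200L,
             intergenic_expressed_loci = 1L, novel_junction_count = 2L)
}

small_dataset <- function() {
  memo("ds_small", function() simulate_dataset(small_config()))
}

# hand-built two-gene annotation over an explicit genome, for junction,
# assignment and cluster unit tests
toy_genome <- function() {
  memo("toy_genome", function() {
    set.seed(99)
    g <- Biostrings::DNAStringSet(c(chrA = random_dna_str(6000)))
    g
  })
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# geneA (+): 4 exons of lengths 100, 40, 30, 200 with 150-base introns
# geneB (-): 2 exons of lengths 200, 60
toy_annotation <- function() {
  memo("toy_annotation", function() {
    exA_len <- c(100L, 40L, 30L, 200L)
    exA_start <- 500L + cumsum(c(0L, head(exA_len, -1L) + 150L))
    exB_len <- c(200L, 60L)
    exB_start <- 3500L + cumsum(c(0L, head(exB_len, -1L) + 150L))
    exons <- rbind(
      data.frame(exon_id = paste0("gA.e", 1:4), gene_id = "gA",
                 transcript_id = "gA.t1", chrom = "chrA",
                 start = exA_start, end = exA_start + exA_len,
                 strand = "+", status = "known", exon_rank = 1:4,
                 stringsAsFactors = FALSE),
      data.frame(exon_id = paste0("gB.e", 1:2), gene_id = "gB",
                 transcript_id = "gB.t1", chrom = "chrA",
                 start = exB_start, end = exB_start + exB_len,
                 strand = "-", status = "known", exon_rank = 2:1,
                 stringsAsFactors = FALSE))
    genes <- data.frame(
      gene_id = c("gA", "gB"), chrom = "chrA",
      start = c(min(exA_start), min(exB_start)),
      end = c(max(exA_start + exA_len), max(exB_start + exB_len)),
      strand = c("+", "-"), status = "known", stringsAsFactors = FALSE)
    probesets <- data.frame(
      probeset_id = paste0("ps", seq_len(nrow(exons))),
      chrom = exons$chrom, start = exons$start, end = exons$end,
      strand = exons$strand, target_exon = exons$exon_id,
      target_locus = NA_character_, stringsAsFactors = FALSE)
    exon_annotation(genes, exons, probesets)
  })
}

toy_read <- function(chrom, start, strand = "+", id = "r1", mult = 1L,
                     len = 50L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), read_id = id,
             multiplicity = as.integer(mult), strand = strand,
             stringsAsFactors = FALSE)
}

# exon expression table + matching array rows built directly from numbers
toy_exon_table <- function(counts1, counts2, L = 200L, U = 0L,
                           T1 = 1e6, T2 = 1e6) {
  n <- length(counts1)
  data.frame(
    exon_id = sprintf("e%03d", seq_len(n)),
    gene_id = "g", chrom = "chrA", status = "known",
    L = rep_len(L, n), U = rep_len(U, n),
    effective_length = rep_len(L - U, n),
    eligible = rep_len(L - U > 0, n),
    S_s1 = counts1, S_s2 = counts2,
    E_s1 = 1e9 * counts1 / (pmax(L - U, 1) * T1),
    E_s2 = 1e9 * counts2 / (pmax(L - U, 1) * T2),
    stringsAsFactors = FALSE)
}

toy_array <- function(exon_ids, dabg1, dabg2 = dabg1, replicates = 3L) {
  out <- data.frame(probeset_id = paste0("ps_", exon_ids),
                    exon_id = exon_ids, stringsAsFactors = FALSE)
  for (s in 1:2) for (r in seq_len(replicates)) {
    out[[sprintf("signal_s%d_r%d", s, r)]] <- 5
    out[[sprintf("dabg_s%d_r%d", s, r)]] <- if (s == 1) dabg1 else dabg2
  }
  out
}
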