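## Synthetic-data generator: toy genome, annotation, strand-aware aligned
## reads with qualities, junction reads, and triplicate array data with
## known truth. Defaults encode the statistical structure the downstream
## analyses assume: Poisson counts given truth expression, a near-zero
## uniform background, an entirely silent (Y-analog) chromosome, duplicated
## segments creating non-unique 50-mers, and log-scale array signals with
## detection p-values concentrated near zero for expressed probesets.

#' Simulation configuration
#'
#' All knobs of the synthetic dataset, with defaults chosen as the study
#' conditions for the pipeline's validation suite. The seed fixes every
#' output bit-for-bit.
#'
#' @param seed integer; master seed for all stages.
#' @param n_chromosomes number of chromosomes (the last is named `"chrY"`
#'   and is silent by default).
#' @param chromosome_length bases per chromosome.
#' @param n_genes total gene count, distributed round-robin over
#'   chromosomes.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_length_meanlog,exon_length_sdlog log-normal parameters of
#'   exon length (median ~150 bases).
#' @param exon_length_min,exon_length_max hard clamps on exon length.
#' @param read_length read length in bases.
#' @param sequencing_depth expected signal reads per sample.
#' @param background_rate fraction of `sequencing_depth` placed uniformly
#'   at random over the genome.
#' @param error_rate_per_base substitution probability per sequenced base.
#' @param antisense_fraction probability a read reports the opposite
#'   strand to its transcript.
#' @param duplication_blocks number of segments copied elsewhere in the
#'   genome (creates non-unique 50-mers).
#' @param duplication_length length of each duplicated segment, bases.
#' @param silent_chromosome name of the chromosome that generates no
#'   signal reads (Y-analog); `NA` disables.
#' @param predicted_gene_fraction fraction of genes whose exons are
#'   flagged predicted-only (Genscan/EST-analog models).
#' @param silent_gene_fraction fraction of non-silent-chromosome genes
#'   unexpressed in both samples.
#' @param transition_fraction fraction of genes expressed in only one of
#'   the two samples (each direction).
#' @param fold_change_fraction fraction of expressed genes with a true
#'   log2 change between samples.
#' @param fold_change_range absolute log2 effect-size range
#'   `c(min, max)`; sign is random.
#' @param overdispersion negative-binomial over-dispersion of read counts
#'   (0 = pure Poisson, the default model).
#' @param low_quality_fraction fraction of reads emitted with low base
#'   qualities (exercises expected-error filtering).
#' @param qv_high_mean,qv_low_mean,qv_sd Phred quality value generator
#'   parameters for ordinary and low-quality reads.
#' @param n_array_replicates array replicates per sample.
#' @param array_intercept,array_slope,array_noise_sd log2-scale array
#'   signal model: `intercept + slope*log2(expr+1) + N(0, sd)` per
#'   replicate.
#' @param dabg_shape Beta(shape, 1) shape for detection p-values of
#'   expressed probesets (< 1 concentrates mass near 0); unexpressed
#'   probesets draw Uniform(0,1).
#' @param intronic_rate_factor per-base sampling rate of a gene's
#'   introns relative to its exons (pre-mRNA carry-over; gives introns
#'   the low but non-zero coverage that read-cluster thresholding
#'   calibrates against). Set to 0 for mature-transcript-only reads.
#' @param junction_rate_factor fraction of an exon boundary's per-base
#'   sampling rate realized as junction-spanning reads (keeps the
#'   junction channel at a few percent of the signal reads, as seen in
#'   stranded short-read libraries).
#' @param novel_junction_count planted non-adjacent exon joins.
#' @param novel_junction_expression expression level driving reads over
#'   each planted novel junction.
#' @param intergenic_expressed_loci count of expressed regions outside
#'   any gene (each carries a probeset).
#' @param n_extra_intronic_probesets decoy probesets placed inside known
#'   introns.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 150000L,
                       n_genes = 42L,
                       exons_per_gene = c(2L, 8L),
                       exon_length_meanlog = log(150),
                       exon_length_sdlog = 0.45,
                       exon_length_min = 60L,
                       exon_length_max = 1500L,
                       read_length = 50L,
                       sequencing_depth = 30000L,
                       background_rate = 5e-4,
                       error_rate_per_base = 0.002,
                       antisense_fraction = 1e-4,
                       duplication_blocks = 1L,
                       duplication_length = 500L,
                       silent_chromosome = "chrY",
                       predicted_gene_fraction = 0.15,
                       silent_gene_fraction = 0.2,
                       transition_fraction = 0.08,
                       fold_change_fraction = 0.25,
                       fold_change_range = c(1, 3),
                       overdispersion = 0,
                       low_quality_fraction = 0.02,
                       qv_high_mean = 35, qv_low_mean = 7, qv_sd = 3,
                       n_array_replicates = 3L,
                       array_intercept = 2, array_slope = 1,
                       array_noise_sd = 0.25,
                       dabg_shape = 0.01,
                       intronic_rate_factor = 0.05,
                       junction_rate_factor = 0.15,
                       novel_junction_count = 5L,
                       novel_junction_expression = 30,
                       intergenic_expressed_loci = 3L,
                       n_extra_intronic_probesets = 6L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$background_rate < 0 || cfg$background_rate > 1) {
    stop("background_rate must lie in [0, 1]")
  }
  if (cfg$read_length < 1) stop("read_length must be >= 1")
  if (cfg$duplication_blocks > 0 &&
      cfg$duplication_length >= cfg$chromosome_length) {
    stop("configuration error: duplication block longer than chromosome")
  }
  if (!is.na(cfg$silent_chromosome) &&
      !cfg$silent_chromosome %in% chromosome_names(cfg)) {
    stop("silent_chromosome must name an existing chromosome")
  }
  invisible(cfg)
}

chromosome_names <- function(cfg) {
  n <- cfg$n_chromosomes
  if (n >= 2) c(paste0("chr", seq_len(n - 1L)), "chrY") else "chr1"
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome with duplicated segments
#'
#' Uniform random sequence per chromosome; each requested duplication
#' block is copied verbatim to a second locus, so exactly the k-mers of
#' those blocks become non-unique (random 50-mers collide with
#' probability ~4^-50 at these scales).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named `DNAStringSet`) and `duplications`
#'   (data.frame of source/destination intervals, 0-based half-open).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- chromosome_names(config)
  seqs <- vapply(chroms, function(ch) random_dna(config$chromosome_length),
                 character(1))

  dup <- data.frame(src_chrom = character(), src_start = integer(),
                    dst_chrom = character(), dst_start = integer(),
                    length = integer(), stringsAsFactors = FALSE)
  if (config$duplication_blocks > 0) {
    len <- config$duplication_length
    # place copies on the first chromosome, away from each other
    non_silent <- setdiff(chroms, config$silent_chromosome)
    if (length(non_silent) == 0) non_silent <- chroms
    for (b in seq_len(config$duplication_blocks)) {
      src_chrom <- non_silent[1L]
      dst_chrom <- non_silent[min(2L, length(non_silent))]
      span <- config$chromosome_length
      src_start <- sample.int(span - 2L * len - 2L, 1L) - 1L
      dst_start <- if (dst_chrom == src_chrom) {
        src_start + len + sample.int(span - src_start - 2L * len - 1L, 1L)
      } else sample.int(span - len, 1L) - 1L
      block <- substr(seqs[[src_chrom]], src_start + 1L, src_start + len)
      substr(seqs[[dst_chrom]], dst_start + 1L, dst_start + len) <- block
      dup <- rbind(dup, data.frame(
        src_chrom = src_chrom, src_start = src_start,
        dst_chrom = dst_chrom, dst_start = dst_start, length = len,
        stringsAsFactors = FALSE))
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  list(genome = genome, duplications = dup)
}

#' Generate annotation and expression truth over a toy genome
#'
#' Places non-overlapping multi-exon genes (a configurable fraction
#' predicted-only), one probeset per exon plus decoy intronic and
#' intergenic probesets, planted expressed intergenic loci, and planted
#' non-adjacent (novel) exon junctions. Truth assigns every exon a true
#' expression level in each of two samples; genes on the silent
#' chromosome are unexpressed by construction.
#'
#' @param genome_obj the list returned by [generate_genome()].
#' @param config a [sim_config()].
#' @return list with `annotation` (an [exon_annotation]), `truth`
#'   (a `sim_truth` list: `exons`, `loci`, `novel_junctions`,
#'   `duplications`) and `genome` (the input genome with planted
#'   intergenic loci rewritten as stop-free codons on their strand, so
#'   the open-reading-frame filter has true positives).
#' @export
generate_annotation <- function(genome_obj, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  genome <- genome_obj$genome
  chroms <- names(genome)
  chrom_len <- setNames(Biostrings::width(genome), chroms)

  gene_chrom <- chroms[(seq_len(config$n_genes) - 1L) %% length(chroms) + 1L]
  genes_l <- list(); exons_l <- list()
  cursor <- setNames(rep(1000L, length(chroms)), chroms)
  for (i in seq_len(config$n_genes)) {
    ch <- gene_chrom[i]
    k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    ex_len <- pmin(config$exon_length_max,
                   pmax(config$exon_length_min,
                        round(rlnorm(k, config$exon_length_meanlog,
                                     config$exon_length_sdlog))))
    intron_len <- if (k > 1) round(runif(k - 1L, 300, 1500)) else integer(0)
    gene_len <- sum(ex_len) + sum(intron_len)
    start <- cursor[ch]
    if (start + gene_len > chrom_len[ch] - 1000L) {
      stop("configuration error: genes do not fit in chromosome ", ch)
    }
    strand <- sample(c("+", "-"), 1L)
    status <- if (runif(1) < config$predicted_gene_fraction) "predicted"
              else "known"
    gid <- sprintf("gene%03d", i)
    ex_start <- start + cumsum(c(0L, head(ex_len, -1L) + intron_len))
    ranks <- if (strand == "+") seq_len(k) else rev(seq_len(k))
    exons_l[[i]] <- data.frame(
      exon_id = sprintf("%s.e%02d", gid, seq_len(k)),
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      chrom = ch, start = as.integer(ex_start),
      end = as.integer(ex_start + ex_len),
      strand = strand, status = status, exon_rank = ranks,
      stringsAsFactors = FALSE)
    genes_l[[i]] <- data.frame(
      gene_id = gid, chrom = ch, start = as.integer(start),
      end = as.integer(start + gene_len), strand = strand, status = status,
      stringsAsFactors = FALSE)
    cursor[ch] <- as.integer(start + gene_len + round(runif(1, 800, 2000)))
  }
  genes <- do.call(rbind, genes_l)
  exons <- do.call(rbind, exons_l)

  # planted expressed intergenic loci, in the tail gap of non-silent chroms
  loci_l <- list()
  non_silent <- setdiff(chroms, config$silent_chromosome)
  for (j in seq_len(config$intergenic_expressed_loci)) {
    ch <- non_silent[(j - 1L) %% length(non_silent) + 1L]
    len <- as.integer(round(runif(1, 220, 400)))
    start <- cursor[ch] + 500L
    if (start + len > chrom_len[ch]) {
      stop("configuration error: intergenic locus does not fit on ", ch)
    }
    cursor[ch] <- start + len
    loci_l[[j]] <- data.frame(
      locus_id = sprintf("igl%02d", j), chrom = ch, start = start,
      end = start + len, strand = sample(c("+", "-"), 1L),
      stringsAsFactors = FALSE)
  }
  loci <- if (length(loci_l)) do.call(rbind, loci_l) else
    data.frame(locus_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)

  # planted loci emulate protein-coding novel exons: rewrite their
  # genomic sequence as stop-free codons on the locus strand so that
  # downstream open-reading-frame filtering has true positives
  genome_out <- genome
  if (nrow(loci) > 0) {
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    codons <- setdiff(codons, stops)
    gstr <- as.character(genome)
    for (j in seq_len(nrow(loci))) {
      len <- loci$end[j] - loci$start[j]
      orf <- paste(sample(codons, len %/% 3L, replace = TRUE),
                   collapse = "")
      tail_n <- len - nchar(orf)
      if (tail_n > 0) {
        orf <- paste0(orf, substr(sample(codons, 1L), 1L, tail_n))
      }
      if (loci$strand[j] == "-") orf <- revcomp_chr(orf)
      substr(gstr[[loci$chrom[j]]], loci$start[j] + 1L, loci$end[j]) <- orf
    }
    genome_out <- Biostrings::DNAStringSet(gstr)
    names(genome_out) <- names(genome)
  }

  # probesets: one per exon, one per intergenic locus, plus intronic decoys
  ps_exon <- data.frame(
    probeset_id = sprintf("ps_%04d", seq_len(nrow(exons))),
    chrom = exons$chrom, start = exons$start, end = exons$end,
    strand = exons$strand, target_exon = exons$exon_id,
    target_locus = NA_character_, stringsAsFactors = FALSE)
  ps_loc <- if (nrow(loci)) data.frame(
    probeset_id = sprintf("ps_l%03d", seq_len(nrow(loci))),
    chrom = loci$chrom, start = loci$start, end = loci$end,
    strand = loci$strand, target_exon = NA_character_,
    target_locus = loci$locus_id, stringsAsFactors = FALSE) else NULL
  introns <- annotation_introns(
    exon_annotation(genes, exons, ps_exon), status = "known")
  ps_int <- NULL
  n_int <- min(config$n_extra_intronic_probesets, nrow(introns))
  if (n_int > 0) {
    pick <- introns[sample.int(nrow(introns), n_int), , drop = FALSE]
    w <- pmin(80L, pick$end - pick$start)
    ps_int <- data.frame(
      probeset_id = sprintf("ps_i%03d", seq_len(n_int)),
      chrom = pick$chrom, start = pick$start,
      end = pick$start + w, strand = pick$strand,
      target_exon = NA_character_, target_locus = NA_character_,
      stringsAsFactors = FALSE)
  }
  probesets <- rbind(ps_exon, ps_loc, ps_int)
  rownames(probesets) <- NULL

  annotation <- exon_annotation(genes, exons, probesets,
                                intergenic_loci = loci)

  # --- expression truth -----------------------------------------------------
  ng <- nrow(genes)
  on_silent <- genes$chrom %in% config$silent_chromosome
  base <- rlnorm(ng, log(8), 0.8)
  u <- runif(ng)
  g1 <- base; g2 <- base
  effect <- numeric(ng)
  silent <- u < config$silent_gene_fraction
  off_on <- !silent & u < config$silent_gene_fraction + config$transition_fraction
  on_off <- !silent & !off_on &
    u < config$silent_gene_fraction + 2 * config$transition_fraction
  changing <- !silent & !off_on & !on_off &
    u < config$silent_gene_fraction + 2 * config$transition_fraction +
        config$fold_change_fraction
  g1[silent | off_on] <- 0
  g2[silent | on_off] <- 0
  eff <- sample(c(-1, 1), sum(changing), replace = TRUE) *
    runif(sum(changing), config$fold_change_range[1],
          config$fold_change_range[2])
  effect[changing] <- eff
  g2[changing] <- g1[changing] * 2^eff
  g1[on_silent] <- 0; g2[on_silent] <- 0; effect[on_silent] <- 0

  mult <- rlnorm(nrow(exons), 0, 0.25)   # per-exon share of gene expression
  gidx <- match(exons$gene_id, genes$gene_id)
  exon_truth <- data.frame(
    exon_id = exons$exon_id, gene_id = exons$gene_id,
    length = exons$end - exons$start,
    expr_s1 = g1[gidx] * mult, expr_s2 = g2[gidx] * mult,
    effect_log2 = effect[gidx], stringsAsFactors = FALSE)

  locus_truth <- if (nrow(loci)) data.frame(
    locus_id = loci$locus_id,
    expr_s1 = rlnorm(nrow(loci), log(15), 0.4),
    expr_s2 = rlnorm(nrow(loci), log(15), 0.4),
    stringsAsFactors = FALSE) else
    data.frame(locus_id = character(), expr_s1 = numeric(),
               expr_s2 = numeric(), stringsAsFactors = FALSE)

  # planted novel junctions: skip-one pairs within expressed known genes
  expressed <- genes$gene_id[g1 > 0 & genes$status == "known" & !on_silent]
  nj <- list()
  for (gid in sample(expressed)) {
    if (length(nj) >= config$novel_junction_count) break
    ex <- exons[exons$gene_id == gid, ]
    ex <- ex[order(ex$exon_rank), ]
    if (nrow(ex) < 3) next
    k <- sample.int(nrow(ex) - 2L, 1L)
    nj[[length(nj) + 1L]] <- data.frame(
      gene_id = gid, donor_exon = ex$exon_id[k],
      acceptor_exon = ex$exon_id[k + 2L], stringsAsFactors = FALSE)
  }
  novel_junctions <- if (length(nj)) do.call(rbind, nj) else
    data.frame(gene_id = character(), donor_exon = character(),
               acceptor_exon = character(), stringsAsFactors = FALSE)

  truth <- structure(
    list(exons = exon_truth, loci = locus_truth,
         novel_junctions = novel_junctions,
         duplications = genome_obj$duplications,
         silent_chromosome = config$silent_chromosome),
    class = "sim_truth")
  list(annotation = annotation, truth = truth, genome = genome_out)
}

## -- read simulation --------------------------------------------------------

apply_sequencing_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  w <- nchar(seqs)
  n_err <- rbinom(length(seqs), w, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(w[i], n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seqs
}

make_quality_strings <- function(n, width, config) {
  if (n == 0) return(character(0))
  low <- runif(n) < config$low_quality_fraction
  means <- ifelse(low, config$qv_low_mean, config$qv_high_mean)
  qv <- matrix(round(rnorm(n * width, rep(means, each = width), config$qv_sd)),
               nrow = width)
  qv <- pmin(pmax(qv, 2L), 40L)
  vapply(seq_len(n), function(i) qv_to_string(qv[, i]), character(1))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate strand-aware aligned reads, background and junction reads
#'
#' Per-exon read counts are Poisson with mean proportional to true
#' expression times exon length (negative-binomial if `overdispersion`
#' > 0); read starts are uniform within the exon; the read strand matches
#' the transcript except for `antisense_fraction`. Background reads fall
#' uniformly over the genome at `background_rate`. Junction reads span
#' adjacent exon junctions of expressed transcripts and all planted novel
#' junctions, covering the boundary by at least one base on each side;
#' they appear in the FASTQ but not in the genomic alignments. Reads
#' falling inside a duplicated segment are reported at both loci with
#' multiplicity 2.
#'
#' @param genome a named `DNAStringSet`.
#' @param annotation an [exon_annotation].
#' @param truth a `sim_truth` from [generate_annotation()].
#' @param config a [sim_config()].
#' @param sample sample index (1 or 2).
#' @return list with `alignments` (BED6-writable data.frame), `reads`
#'   (FASTQ-writable: `read_id`, `seq`, `qual`), `junction_reads`
#'   (truth table of planted junction-spanning reads) and `summary`
#'   (named counts: signal, background, junction, total).
#' @export
simulate_reads <- function(genome, annotation, truth, config, sample = 1L) {
  validate_sim_config(config)
  set.seed(config$seed + 100L + sample)
  rl <- config$read_length
  exons <- annotation$exons
  et <- truth$exons[match(exons$exon_id, truth$exons$exon_id), ]
  expr <- if (sample == 1L) et$expr_s1 else et$expr_s2
  chrom_str <- as.character(genome)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))

  # per-(expression * base) sampling rate giving the requested depth
  lam_mass <- sum(expr * (exons$end - exons$start))
  loc_expr <- if (nrow(truth$loci)) {
    if (sample == 1L) truth$loci$expr_s1 else truth$loci$expr_s2
  } else numeric(0)
  if (nrow(truth$loci)) {
    lam_mass <- lam_mass +
      sum(loc_expr * (annotation$intergenic_loci$end -
                        annotation$intergenic_loci$start))
  }
  scale <- if (lam_mass > 0) config$sequencing_depth / lam_mass else 0

  draw_counts <- function(lambda) {
    if (config$overdispersion > 0) {
      stats::rnbinom(length(lambda), mu = lambda,
                     size = 1 / config$overdispersion)
    } else rpois(length(lambda), lambda)
  }

  sample_region_reads <- function(regions, expr, prefix) {
    lambda <- expr * (regions$end - regions$start) * scale
    n <- draw_counts(lambda)
    idx <- rep.int(seq_len(nrow(regions)), n)
    total <- length(idx)
    if (total == 0) {
      return(list(aln = NULL, reads = NULL))
    }
    span <- pmax(1L, regions$end[idx] - regions$start[idx] - rl + 1L)
    start <- regions$start[idx] + floor(runif(total) * span)
    start <- pmin(start, chrom_len[regions$chrom[idx]] - rl)
    strand <- regions$strand[idx]
    flip <- runif(total) < config$antisense_fraction
    strand[flip] <- ifelse(strand[flip] == "+", "-", "+")
    id <- sprintf("s%d_%s_%06d", sample, prefix, seq_len(total))
    aln <- data.frame(chrom = regions$chrom[idx], start = as.integer(start),
                      end = as.integer(start + rl), read_id = id,
                      multiplicity = 1L, strand = strand,
                      stringsAsFactors = FALSE)
    seqs <- substring(chrom_str[aln$chrom], aln$start + 1L, aln$end)
    minus <- aln$strand == "-"
    seqs[minus] <- revcomp_chr(seqs[minus])
    seqs <- apply_sequencing_errors(seqs, config$error_rate_per_base)
    reads <- data.frame(read_id = id, seq = seqs,
                        qual = make_quality_strings(total, rl, config),
                        stringsAsFactors = FALSE)
    list(aln = aln, reads = reads)
  }

  sig <- sample_region_reads(exons, expr, "sig")
  igl <- if (nrow(truth$loci)) {
    sample_region_reads(annotation$intergenic_loci, loc_expr, "igl")
  } else list(aln = NULL, reads = NULL)

  # intronic (pre-mRNA) reads at a low per-base rate relative to exons
  intr <- list(aln = NULL, reads = NULL)
  if (config$intronic_rate_factor > 0) {
    introns <- rbind(annotation_introns(annotation, "known"),
                     annotation_introns(annotation, "predicted"))
    introns <- introns[introns$end - introns$start >= rl, , drop = FALSE]
    if (nrow(introns) > 0) {
      gene_mean <- tapply(expr, exons$gene_id, mean)
      intron_expr <- as.numeric(gene_mean[introns$gene_id]) *
        config$intronic_rate_factor
      intron_expr[is.na(intron_expr)] <- 0
      intr <- sample_region_reads(introns, intron_expr, "int")
    }
  }

  # background: uniform over the whole genome
  n_bg <- rpois(1L, config$sequencing_depth * config$background_rate)
  bg <- list(aln = NULL, reads = NULL)
  if (n_bg > 0) {
    ch <- names(genome)[sample.int(length(genome), n_bg, replace = TRUE,
                                   prob = chrom_len)]
    start <- floor(runif(n_bg) * (chrom_len[ch] - rl))
    strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    id <- sprintf("s%d_bg_%06d", sample, seq_len(n_bg))
    aln <- data.frame(chrom = ch, start = as.integer(start),
                      end = as.integer(start + rl), read_id = id,
                      multiplicity = 1L, strand = strand,
                      stringsAsFactors = FALSE)
    seqs <- substring(chrom_str[aln$chrom], aln$start + 1L, aln$end)
    minus <- aln$strand == "-"
    seqs[minus] <- revcomp_chr(seqs[minus])
    seqs <- apply_sequencing_errors(seqs, config$error_rate_per_base)
    bg <- list(aln = aln,
               reads = data.frame(read_id = id, seq = seqs,
                                  qual = make_quality_strings(n_bg, rl, config),
                                  stringsAsFactors = FALSE))
  }

  aln <- do.call(rbind, c(list(sig$aln, igl$aln, intr$aln, bg$aln)))
  if (is.null(aln)) {
    aln <- data.frame(chrom = character(), start = integer(),
                      end = integer(), read_id = character(),
                      multiplicity = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(aln) <- NULL

  # duplicate-segment reads: report the partner locus, multiplicity 2
  dup <- truth$duplications
  if (nrow(dup) > 0 && nrow(aln) > 0) {
    extra <- list()
    for (b in seq_len(nrow(dup))) {
      d <- dup[b, ]
      in_src <- aln$chrom == d$src_chrom & aln$start >= d$src_start &
        aln$end <= d$src_start + d$length
      in_dst <- aln$chrom == d$dst_chrom & aln$start >= d$dst_start &
        aln$end <= d$dst_start + d$length
      aln$multiplicity[in_src | in_dst] <- 2L
      if (any(in_src)) {
        p <- aln[in_src, ]; p$chrom <- d$dst_chrom
        p$start <- p$start - d$src_start + d$dst_start
        p$end <- p$start + rl
        extra[[length(extra) + 1L]] <- p
      }
      if (any(in_dst)) {
        p <- aln[in_dst, ]; p$chrom <- d$src_chrom
        p$start <- p$start - d$dst_start + d$src_start
        p$end <- p$start + rl
        extra[[length(extra) + 1L]] <- p
      }
    }
    if (length(extra)) aln <- rbind(aln, do.call(rbind, extra))
    rownames(aln) <- NULL
  }

  # junction-spanning reads (FASTQ only; never in the genomic alignments)
  jdb <- rbind(
    build_known_junctions(annotation, genome),
    build_novel_junction_records(annotation, genome, truth$novel_junctions)
  )
  jr <- list(reads = NULL, truth = NULL)
  if (nrow(jdb) > 0) {
    gene_expr1 <- tapply(expr, exons$gene_id, mean)
    jexpr <- ifelse(jdb$status == "known",
                    as.numeric(gene_expr1[jdb$gene_id]),
                    config$novel_junction_expression)
    o_min <- pmax(1L, rl - jdb$acceptor_contrib)
    o_max <- pmin(rl - 1L, jdb$donor_contrib)
    m <- pmax(0L, o_max - o_min + 1L)
    n_j <- draw_counts(jexpr * m * scale * config$junction_rate_factor)
    n_j[m == 0] <- 0L
    idx <- rep.int(seq_len(nrow(jdb)), n_j)
    if (length(idx) > 0) {
      o <- o_min[idx] + floor(runif(length(idx)) * m[idx])
      pos <- jdb$donor_contrib[idx] - o + 1L
      seqs <- substring(jdb$seq[idx], pos, pos + rl - 1L)
      strand <- rep("+", length(idx))
      flip <- runif(length(idx)) < config$antisense_fraction
      seqs[flip] <- revcomp_chr(seqs[flip])
      strand[flip] <- "-"
      seqs <- apply_sequencing_errors(seqs, config$error_rate_per_base)
      id <- sprintf("s%d_jx_%06d", sample, seq_along(idx))
      jr$reads <- data.frame(read_id = id, seq = seqs,
                             qual = make_quality_strings(length(idx), rl,
                                                         config),
                             stringsAsFactors = FALSE)
      jr$truth <- data.frame(
        read_id = id, junction_id = jdb$junction_id[idx],
        gene_id = jdb$gene_id[idx], donor_exon = jdb$donor_exon[idx],
        acceptor_exon = jdb$acceptor_exon[idx], status = jdb$status[idx],
        donor_overlap = o, acceptor_overlap = rl - o,
        strand = strand, stringsAsFactors = FALSE)
    }
  }

  reads <- do.call(rbind, c(list(sig$reads, igl$reads, intr$reads,
                                 bg$reads, jr$reads)))
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), seq = character(),
                        qual = character(), stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL
  nr <- function(x) if (is.null(x)) 0L else nrow(x)
  summary <- c(
    signal = nr(sig$reads) + nr(igl$reads) + nr(intr$reads),
    background = nr(bg$reads),
    junction = nr(jr$reads))
  summary <- c(summary, total = sum(summary))
  list(alignments = aln, reads = reads, junction_reads = jr$truth,
       summary = summary)
}

#' Simulate triplicate array signals and detection p-values
#'
#' Per probeset and replicate, the log2 signal is
#' `intercept + slope*log2(expr+1) + N(0, sd)`. Detection (DABG-style)
#' p-values are Uniform(0,1) for unexpressed probesets and
#' Beta(`dabg_shape`, 1) — concentrated near zero — for expressed ones.
#'
#' @param annotation an [exon_annotation].
#' @param truth a `sim_truth`.
#' @param config a [sim_config()].
#' @return data.frame with `probeset_id`, `exon_id`, and
#'   `signal_s<sample>_r<rep>` / `dabg_s<sample>_r<rep>` columns.
#' @export
simulate_array <- function(annotation, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 200L)
  ps <- annotation$probesets
  n <- nrow(ps)
  expr <- matrix(0, n, 2)
  ei <- match(ps$target_exon, truth$exons$exon_id)
  has_e <- !is.na(ei)
  expr[has_e, 1] <- truth$exons$expr_s1[ei[has_e]]
  expr[has_e, 2] <- truth$exons$expr_s2[ei[has_e]]
  if (nrow(truth$loci)) {
    li <- match(ps$target_locus, truth$loci$locus_id)
    has_l <- !is.na(li)
    expr[has_l, 1] <- truth$loci$expr_s1[li[has_l]]
    expr[has_l, 2] <- truth$loci$expr_s2[li[has_l]]
  }
  out <- data.frame(probeset_id = ps$probeset_id,
                    exon_id = ifelse(is.na(ps$target_exon), "NA",
                                     ps$target_exon),
                    stringsAsFactors = FALSE)
  for (s in 1:2) for (r in seq_len(config$n_array_replicates)) {
    out[[sprintf("signal_s%d_r%d", s, r)]] <-
      config$array_intercept + config$array_slope * log2(expr[, s] + 1) +
      rnorm(n, 0, config$array_noise_sd)
  }
  for (s in 1:2) for (r in seq_len(config$n_array_replicates)) {
    p <- runif(n)
    on <- expr[, s] > 0
    p[on] <- rbeta(sum(on), config$dabg_shape, 1)
    out[[sprintf("dabg_s%d_r%d", s, r)]] <- p
  }
  out
}

#' Simulate a complete two-sample dataset
#'
#' Chains [generate_genome()], [generate_annotation()],
#' [simulate_reads()] (both samples) and [simulate_array()]; optionally
#' writes every artifact in its standard on-disk format.
#'
#' @param config a [sim_config()].
#' @param outdir if non-NULL, directory receiving `genome.fa`,
#'   `annotation.gff3`, `probesets.bed`, `alignments_s<k>.bed`,
#'   `reads_s<k>.fastq`, `array.tsv` and `truth.tsv`.
#' @return list with `genome`, `duplications`, `annotation`, `truth`,
#'   `sample1`, `sample2` (each a [simulate_reads()] result) and `array`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  g <- generate_genome(config)
  ann <- generate_annotation(g, config)
  genome <- ann$genome        # loci carry planted reading frames
  s1 <- simulate_reads(genome, ann$annotation, ann$truth, config, 1L)
  s2 <- simulate_reads(genome, ann$annotation, ann$truth, config, 2L)
  array <- simulate_array(ann$annotation, ann$truth, config)
  ds <- list(genome = genome, duplications = g$duplications,
             annotation = ann$annotation, truth = ann$truth,
             sample1 = s1, sample2 = s2, array = array, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(ds$genome, file.path(outdir, "genome.fa"))
    write_annotation_gff3(ds$annotation, file.path(outdir, "annotation.gff3"))
    write_probesets_bed(ds$annotation, file.path(outdir, "probesets.bed"))
    for (k in 1:2) {
      s <- ds[[paste0("sample", k)]]
      write_alignments_bed(s$alignments,
                           file.path(outdir, sprintf("alignments_s%d.bed", k)))
      write_reads_fastq(s$reads,
                        file.path(outdir, sprintf("reads_s%d.fastq", k)))
    }
    write_tsv(ds$array, file.path(outdir, "array.tsv"))
    write_tsv(ds$truth$exons, file.path(outdir, "truth.tsv"))
  }
  ds
}
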