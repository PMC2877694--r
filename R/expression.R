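## Read-to-annotation assignment, per-exon counting, mappability-corrected
## normalized expression, and the silent-chromosome background analysis.

#' Assign aligned reads to annotation and count per exon
#'
#' In `"unique"` mode only reads with multiplicity 1 are used; in
#' `"all"` mode every reported alignment of every read increments every
#' feature it overlaps (a read targeting two loci adds one count at
#' each). A read counts for an exon when it overlaps it by at least one
#' base on the same strand as the exon's transcript (disable with
#' `strand_check = FALSE`); a read overlapping two exons increments both.
#' Each read is also tallied once at its highest-precedence genomic
#' location category — known exon > known intron > other annotation
#' (predicted exons/genes, probe selection regions) > unannotated — the
#' tally describes where reads land, so it ignores strand.
#'
#' @param alignments data.frame of BED6 alignments (`chrom`, `start`,
#'   `end`, `read_id`, `multiplicity`, `strand`).
#' @param annotation an [exon_annotation].
#' @param mode `"unique"` (multiplicity-1 reads only) or `"all"`.
#' @param strand_check require read strand to match feature strand.
#' @param retained_ids optional character vector of read ids that passed
#'   quality filtering; other reads are dropped first.
#' @return list with `exon_counts` (data.frame `exon_id`, `count`),
#'   `tally` (named integer vector: known_exon, known_intron,
#'   other_annotation, unannotated), `n_reads` (reads considered),
#'   `n_excluded_multi` (reads dropped in unique mode) and
#'   `n_unique_reads` (distinct multiplicity-1 reads, the T of the
#'   normalized expression measure).
#' @export
assign_reads <- function(alignments, annotation,
                         mode = c("unique", "all"),
                         strand_check = TRUE,
                         retained_ids = NULL) {
  mode <- match.arg(mode)
  if (!is.null(retained_ids)) {
    alignments <- alignments[alignments$read_id %in% retained_ids, ,
                             drop = FALSE]
  }
  known_chroms <- unique(c(annotation$genes$chrom, annotation$exons$chrom,
                           annotation$probesets$chrom))
  bad <- !alignments$chrom %in% known_chroms
  if (any(bad)) {
    i <- which(bad)[1]
    stop("read on unknown chromosome: ", alignments$read_id[i], " at ",
         alignments$chrom[i], ":", alignments$start[i])
  }

  all_ids <- unique(alignments$read_id)
  multi_ids <- unique(alignments$read_id[alignments$multiplicity > 1L])
  if (mode == "unique") {
    alignments <- alignments[!alignments$read_id %in% multi_ids, ,
                             drop = FALSE]
    n_excluded <- length(multi_ids)
  } else n_excluded <- 0L

  exons <- annotation$exons
  known_ex <- exons[exons$status == "known", , drop = FALSE]
  ignore_strand <- !strand_check

  empty_counts <- data.frame(exon_id = exons$exon_id,
                             count = 0L, stringsAsFactors = FALSE)
  if (nrow(alignments) == 0) {
    return(list(exon_counts = empty_counts,
                tally = c(known_exon = 0L, known_intron = 0L,
                          other_annotation = 0L, unannotated = 0L),
                n_reads = 0L, n_excluded_multi = n_excluded,
                n_unique_reads = length(setdiff(all_ids, multi_ids))))
  }

  gr_reads <- intervals_to_granges(
    alignments[, c("chrom", "start", "end", "strand")])
  gr_exons <- intervals_to_granges(
    exons[, c("chrom", "start", "end", "strand")])

  hits <- GenomicRanges::findOverlaps(gr_reads, gr_exons,
                                      minoverlap = 1L,
                                      ignore.strand = ignore_strand)
  counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(exons))
  exon_counts <- data.frame(exon_id = exons$exon_id,
                            count = as.integer(counts),
                            stringsAsFactors = FALSE)

  # category per alignment record, then max precedence per read; the
  # tally is location-based, so it ignores strand regardless of the
  # strand rule used for exon counting
  overlaps_any <- function(features) {
    if (is.null(features) || nrow(features) == 0) {
      return(rep(FALSE, nrow(alignments)))
    }
    gr <- intervals_to_granges(
      features[, c("chrom", "start", "end", "strand")])
    GenomicRanges::countOverlaps(gr_reads, gr, minoverlap = 1L,
                                 ignore.strand = TRUE) > 0
  }
  in_known_exon <- overlaps_any(
    exons[exons$status == "known", , drop = FALSE])
  known_genes <- annotation$genes[annotation$genes$status == "known", ,
                                  drop = FALSE]
  in_known_gene <- overlaps_any(known_genes)
  other <- rbind(
    exons[exons$status != "known", c("chrom", "start", "end", "strand")],
    annotation$genes[annotation$genes$status != "known",
                     c("chrom", "start", "end", "strand")],
    annotation$probesets[, c("chrom", "start", "end", "strand")]
  )
  in_other <- overlaps_any(other)

  rec_cat <- ifelse(in_known_exon, 4L,
                    ifelse(in_known_gene, 3L, ifelse(in_other, 2L, 1L)))
  read_cat <- tapply(rec_cat, alignments$read_id, max)
  tally <- c(known_exon = sum(read_cat == 4L),
             known_intron = sum(read_cat == 3L),
             other_annotation = sum(read_cat == 2L),
             unannotated = sum(read_cat == 1L))

  list(exon_counts = exon_counts, tally = tally,
       n_reads = length(unique(alignments$read_id)),
       n_excluded_multi = n_excluded,
       n_unique_reads = length(setdiff(all_ids, multi_ids)))
}

#' Mappability-corrected normalized expression
#'
#' `E = C * S / ((L - U) * T)`: reads on the region, scaled by its
#' uniquely mappable (effective) length and the sample's total count of
#' uniquely mappable reads. With `U = 0` and `C = 1e9` this is RPKM.
#'
#' @param S reads mapping to the region (count).
#' @param L region length in bases.
#' @param U non-unique start positions within the region.
#' @param T_total total uniquely mappable reads in the sample.
#' @param C scaling constant (default 1e9).
#' @return normalized expression E (vectorized).
#' @export
#' @examples
#' normalized_expression(10, 1100, 100, 1e7)  # 1.0
normalized_expression <- function(S, L, U, T_total, C = 1e9) {
  if (any(T_total <= 0)) stop("T_total must be > 0")
  eff <- L - U
  if (any(eff <= 0)) {
    stop("undefined normalized expression: effective length (L - U) <= 0")
  }
  C * S / (eff * T_total)
}

#' Per-exon expression table for two samples
#'
#' Combines per-exon counts, mappability and library sizes into one
#' table. Exons with effective length <= 0 are retained with `E` set to
#' `NA` and `eligible = FALSE`; downstream comparisons exclude them.
#'
#' @param annotation an [exon_annotation].
#' @param profile a `mappability_profile` (or NULL for U = 0).
#' @param counts_s1,counts_s2 data.frames from [assign_reads()]
#'   (`exon_counts` element).
#' @param T1,T2 total uniquely mappable reads per sample.
#' @param C scaling constant of the expression measure.
#' @return data.frame `exon_id`, `gene_id`, `chrom`, `status`, `L`, `U`,
#'   `effective_length`, `eligible`, `S_s1`, `S_s2`, `E_s1`, `E_s2`.
#' @export
exon_expression_table <- function(annotation, profile, counts_s1, counts_s2,
                                  T1, T2, C = 1e9) {
  exons <- annotation$exons
  L <- exons$end - exons$start
  U <- if (is.null(profile)) rep(0L, nrow(exons)) else
    vapply(seq_len(nrow(exons)), function(i)
      count_nonunique(profile, exons$chrom[i], exons$start[i], exons$end[i]),
      integer(1))
  eff <- L - U
  s1 <- counts_s1$count[match(exons$exon_id, counts_s1$exon_id)]
  s2 <- counts_s2$count[match(exons$exon_id, counts_s2$exon_id)]
  ok <- eff > 0
  E1 <- rep(NA_real_, nrow(exons)); E2 <- rep(NA_real_, nrow(exons))
  E1[ok] <- normalized_expression(s1[ok], L[ok], U[ok], T1, C)
  E2[ok] <- normalized_expression(s2[ok], L[ok], U[ok], T2, C)
  data.frame(exon_id = exons$exon_id, gene_id = exons$gene_id,
             chrom = exons$chrom, status = exons$status,
             L = L, U = U, effective_length = eff, eligible = ok,
             S_s1 = s1, S_s2 = s2, E_s1 = E1, E_s2 = E2,
             stringsAsFactors = FALSE)
}

#' Background estimate from a silent chromosome
#'
#' On a chromosome that should produce no RNA (the Y analog in female
#' samples), any uniquely mapped read is a technical artifact. Exons are
#' eligible when their effective length (length minus non-unique start
#' positions) exceeds `min_effective_length`, excluding loci where unique
#' mapping is impaired; the background measure is the proportion of
#' eligible exons hit by at least one read.
#'
#' @param exon_table a table from [exon_expression_table()].
#' @param chromosome silent chromosome name.
#' @param min_effective_length eligibility cutoff in bases (default 100,
#'   strict: eligibility requires effective length > cutoff).
#' @param sample which sample's counts to use (1 or 2).
#' @return list with `proportion`, `n_eligible`, `n_detected`,
#'   `n_total` (exons on the chromosome before the eligibility filter).
#' @export
silent_chromosome_background <- function(exon_table, chromosome,
                                         min_effective_length = 100,
                                         sample = 1L) {
  tab <- exon_table[exon_table$chrom == chromosome, , drop = FALSE]
  if (nrow(tab) == 0) stop("no exons annotated on chromosome ", chromosome)
  eligible <- tab$effective_length > min_effective_length
  if (!any(eligible)) {
    stop("no eligible exons on ", chromosome,
         " (all effective lengths <= ", min_effective_length, ")")
  }
  s <- tab[eligible, paste0("S_s", sample)]
  list(proportion = mean(s >= 1L),
       n_eligible = sum(eligible),
       n_detected = sum(s >= 1L),
       n_total = nrow(tab))
}
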