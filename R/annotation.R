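#' Annotated genome container
#'
#' Bundles the hierarchical gene/transcript/exon model, probeset selection
#' regions and (optionally) planted intergenic transcribed loci into a
#' single object. All coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `status` (`"known"` or `"predicted"`).
#' @param exons data.frame with columns `exon_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end`, `strand`, `status`,
#'   `exon_rank` (1-based order within the transcript, 5' to 3').
#' @param probesets data.frame with columns `probeset_id`, `chrom`,
#'   `start`, `end`, `strand`, `target_exon` (exon_id or `NA`),
#'   `target_locus` (intergenic locus id or `NA`).
#' @param intergenic_loci optional data.frame of planted intergenic
#'   transcribed intervals (`locus_id`, `chrom`, `start`, `end`, `strand`).
#'
#' @return An object of class `exon_annotation`.
#' @export
exon_annotation <- function(genes, exons, probesets,
                            intergenic_loci = NULL) {
  stopifnot(
    all(c("gene_id", "chrom", "start", "end", "strand", "status") %in%
          names(genes)),
    all(c("exon_id", "gene_id", "transcript_id", "chrom", "start", "end",
          "strand", "status", "exon_rank") %in% names(exons)),
    all(c("probeset_id", "chrom", "start", "end") %in% names(probesets))
  )
  if (any(exons$end <= exons$start)) {
    stop("exon intervals must be non-empty ([start, end), end > start)")
  }
  if (anyDuplicated(exons$exon_id)) stop("duplicated exon_id")
  structure(
    list(genes = genes, exons = exons, probesets = probesets,
         intergenic_loci = intergenic_loci),
    class = "exon_annotation"
  )
}

#' @export
print.exon_annotation <- function(x, ...) {
  cat("exon_annotation:",
      nrow(x$genes), "genes,",
      nrow(x$exons), "exons,",
      nrow(x$probesets), "probesets\n")
  invisible(x)
}

#' Known-intron intervals of an annotation
#'
#' Introns are the within-gene intervals not covered by any exon of that
#' gene. Computed per gene by set difference.
#'
#' @param annotation an [exon_annotation] object.
#' @param status gene status to restrict to (`"known"` or `"predicted"`).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
annotation_introns <- function(annotation, status = "known") {
  genes <- annotation$genes[annotation$genes$status == status, , drop = FALSE]
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, ,
                           drop = FALSE]
    gene_rng <- IRanges::IRanges(g$start + 1L, g$end)
    exon_rng <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    intr <- IRanges::setdiff(gene_rng, exon_rng)
    if (length(intr) == 0) next
    out[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom,
      start = IRanges::start(intr) - 1L, end = IRanges::end(intr),
      strand = g$strand, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

## -- GRanges bridge ---------------------------------------------------------

#' Convert an interval data.frame to GRanges
#'
#' Internal coordinates are 0-based half-open; GRanges is 1-based
#' inclusive, so starts shift by +1.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @param use_strand include strand information (default TRUE when a
#'   strand column is present).
#' @return a `GRanges` object; remaining columns become metadata.
#' @export
intervals_to_granges <- function(df, use_strand = "strand" %in% names(df)) {
  strand <- if (use_strand) df$strand else "*"
  extra <- df[, setdiff(names(df), c("chrom", "start", "end", "strand")),
              drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (ncol(extra) > 0) S4Vectors::mcols(gr) <- extra
  gr
}

## -- GFF3 / BED I/O ---------------------------------------------------------

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA and exon records with `ID`/`Parent` links and a
#' `status` attribute; GFF3 coordinates are 1-based inclusive.
#'
#' @param annotation an [exon_annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons
  tx <- unique(exons[, c("transcript_id", "gene_id")])
  tx_rng <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    ex <- exons[exons$transcript_id == tx$transcript_id[i], ]
    data.frame(chrom = ex$chrom[1], start = min(ex$start), end = max(ex$end),
               strand = ex$strand[1], stringsAsFactors = FALSE)
  }))

  gr_gene <- intervals_to_granges(genes[, c("chrom", "start", "end", "strand")])
  S4Vectors::mcols(gr_gene) <- S4Vectors::DataFrame(
    type = "gene", ID = genes$gene_id, status = genes$status)
  gr_tx <- intervals_to_granges(tx_rng)
  S4Vectors::mcols(gr_tx) <- S4Vectors::DataFrame(
    type = "mRNA", ID = tx$transcript_id, Parent = tx$gene_id)
  gr_ex <- intervals_to_granges(exons[, c("chrom", "start", "end", "strand")])
  S4Vectors::mcols(gr_ex) <- S4Vectors::DataFrame(
    type = "exon", ID = exons$exon_id, Parent = exons$transcript_id,
    status = exons$status, exon_rank = exons$exon_rank)

  gr <- suppressWarnings(c(gr_gene, gr_tx, gr_ex))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation from GFF3
#'
#' Inverse of [write_annotation_gff3()]; restores the 0-based half-open
#' internal convention.
#'
#' @param path GFF3 file written by this package.
#' @return an [exon_annotation] (without probesets, which travel as BED).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  is_gene <- df$type == "gene"
  is_tx <- df$type == "mRNA"
  is_ex <- df$type == "exon"
  genes <- data.frame(
    gene_id = df$ID[is_gene], chrom = as.character(df$seqnames[is_gene]),
    start = df$start[is_gene] - 1L, end = df$end[is_gene],
    strand = as.character(df$strand[is_gene]),
    status = df$status[is_gene], stringsAsFactors = FALSE)
  tx2gene <- setNames(parent[is_tx], df$ID[is_tx])
  exons <- data.frame(
    exon_id = df$ID[is_ex], gene_id = unname(tx2gene[parent[is_ex]]),
    transcript_id = parent[is_ex],
    chrom = as.character(df$seqnames[is_ex]),
    start = df$start[is_ex] - 1L, end = df$end[is_ex],
    strand = as.character(df$strand[is_ex]),
    status = df$status[is_ex],
    exon_rank = as.integer(df$exon_rank[is_ex]), stringsAsFactors = FALSE)
  exons <- exons[order(exons$transcript_id, exons$exon_rank), ]
  rownames(exons) <- NULL
  exon_annotation(genes, exons,
                  probesets = data.frame(probeset_id = character(),
                                         chrom = character(),
                                         start = integer(), end = integer(),
                                         stringsAsFactors = FALSE))
}

#' Write probeset selection regions as BED
#'
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param annotation an [exon_annotation].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_probesets_bed <- function(annotation, path) {
  ps <- annotation$probesets
  gr <- intervals_to_granges(ps[, c("chrom", "start", "end", "strand")])
  S4Vectors::mcols(gr)$name <- ps$probeset_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a probeset BED file
#'
#' @param path BED file of probe selection regions.
#' @return data.frame `probeset_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_probesets_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    probeset_id = S4Vectors::mcols(gr)$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
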