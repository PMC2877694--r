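## Exon-exon junction databases and read mapping. A junction sequence is
## the last (up to) 49 bases of the donor exon followed by the first (up
## to) 49 bases of the acceptor exon, both in transcript orientation, so
## that a 50-base read can only match if it spans the splice boundary;
## no junction sequence exceeds 98 nucleotides. Known junctions join
## adjacent exons of a transcript; putative junctions join every other
## ordered exon pair within a gene.

exon_sequence <- function(genome_str, exon) {
  s <- substr(genome_str[[exon$chrom]], exon$start + 1L, exon$end)
  if (exon$strand == "-") revcomp_chr(s) else s
}

junction_record <- function(genome_str, donor, acceptor, gene_id, status,
                            max_contrib = 49L) {
  dseq <- exon_sequence(genome_str, donor)
  aseq <- exon_sequence(genome_str, acceptor)
  dc <- min(max_contrib, nchar(dseq))
  ac <- min(max_contrib, nchar(aseq))
  data.frame(
    junction_id = paste(gene_id, donor$exon_id, acceptor$exon_id,
                        sep = "|"),
    gene_id = gene_id, donor_exon = donor$exon_id,
    acceptor_exon = acceptor$exon_id,
    seq = paste0(substr(dseq, nchar(dseq) - dc + 1L, nchar(dseq)),
                 substr(aseq, 1L, ac)),
    donor_contrib = dc, acceptor_contrib = ac, status = status,
    stringsAsFactors = FALSE)
}

empty_junction_db <- function() {
  data.frame(junction_id = character(), gene_id = character(),
             donor_exon = character(), acceptor_exon = character(),
             seq = character(), donor_contrib = integer(),
             acceptor_contrib = integer(), status = character(),
             stringsAsFactors = FALSE)
}

#' Build the known exon-exon junction database
#'
#' One record per distinct adjacent exon pair across all transcripts
#' (duplicates collapsed); single-exon transcripts contribute nothing.
#' Exon contributions are truncated to `max_contrib` bases, so no
#' sequence exceeds `2 * max_contrib` (98 by default).
#'
#' @param annotation an [exon_annotation]; exon order within a
#'   transcript is given by `exon_rank`.
#' @param genome a named `DNAStringSet` or character vector.
#' @param max_contrib maximum bases contributed by each exon
#'   (default 49, one less than the 50-base read length).
#' @return data.frame junction database (`junction_id`, `gene_id`,
#'   `donor_exon`, `acceptor_exon`, `seq`, `donor_contrib`,
#'   `acceptor_contrib`, `status`).
#' @export
build_known_junctions <- function(annotation, genome, max_contrib = 49L) {
  genome_str <- if (methods::is(genome, "DNAStringSet"))
    as.character(genome) else genome
  exons <- annotation$exons
  recs <- list()
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    if (nrow(ex) < 2) next
    for (i in seq_len(nrow(ex) - 1L)) {
      recs[[length(recs) + 1L]] <- junction_record(
        genome_str, ex[i, ], ex[i + 1L, ], ex$gene_id[1], "known",
        max_contrib)
    }
  }
  if (!length(recs)) return(empty_junction_db())
  db <- do.call(rbind, recs)
  db <- db[!duplicated(db$junction_id), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Build the putative (permuted) junction database
#'
#' All ordered exon pairs (i, j), i != j, within each gene, minus the
#' pairs already present in the known database. With
#' `genomic_order_only = TRUE`, only pairs where the donor precedes the
#' acceptor in transcript order are generated (exon-skipping events
#' only, no scrambled order).
#'
#' @inheritParams build_known_junctions
#' @param known_db the database from [build_known_junctions()] built
#'   from the same annotation.
#' @param genomic_order_only restrict to transcript-order pairs.
#' @return data.frame junction database with status `"putative"`.
#' @export
build_putative_junctions <- function(annotation, genome, known_db,
                                     genomic_order_only = FALSE,
                                     max_contrib = 49L) {
  genome_str <- if (methods::is(genome, "DNAStringSet"))
    as.character(genome) else genome
  exons <- annotation$exons
  recs <- list()
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2) next
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (genomic_order_only && i > j) next
      jid <- paste(gid, ex$exon_id[i], ex$exon_id[j], sep = "|")
      if (jid %in% known_db$junction_id) next
      recs[[length(recs) + 1L]] <- junction_record(
        genome_str, ex[i, ], ex[j, ], gid, "putative", max_contrib)
    }
  }
  if (!length(recs)) return(empty_junction_db())
  db <- do.call(rbind, recs)
  rownames(db) <- NULL
  db
}

## junction records for planted novel exon pairs (simulation truth)
build_novel_junction_records <- function(annotation, genome, pairs,
                                         max_contrib = 49L) {
  if (is.null(pairs) || nrow(pairs) == 0) return(empty_junction_db())
  genome_str <- if (methods::is(genome, "DNAStringSet"))
    as.character(genome) else genome
  exons <- annotation$exons
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    donor <- exons[exons$exon_id == pairs$donor_exon[i], ]
    acceptor <- exons[exons$exon_id == pairs$acceptor_exon[i], ]
    junction_record(genome_str, donor, acceptor, pairs$gene_id[i],
                    "novel", max_contrib)
  })
  db <- do.call(rbind, recs)
  rownames(db) <- NULL
  db
}

#' Write a junction database as FASTA
#'
#' Headers follow `gene|donor_exon|acceptor_exon|status`.
#'
#' @param db a junction database data.frame.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_junctions_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- paste(db$gene_id, db$donor_exon, db$acceptor_exon, db$status,
                    sep = "|")
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Map reads to a junction database
#'
#' Exact-match alignment of each full read against the junction
#' sequences. A read is counted only if it matches exactly one junction
#' record (reads hitting several junctions, or also hitting the genome
#' when one is supplied, are discarded) and covers the splice boundary
#' by at least one base on each side. Sense matches (read equals a
#' junction substring) and antisense matches (reverse complement
#' matches) are tallied separately.
#'
#' @param reads data.frame with `read_id` and `seq` (the reads not
#'   mapped to the genome; for the putative search, also not mapped to
#'   known junctions).
#' @param db a junction database data.frame.
#' @param genome optional named `DNAStringSet`; reads with an exact
#'   genomic match (either strand) are discarded.
#' @return data.frame of junction hits: `junction_id`, `gene_id`,
#'   `donor_exon`, `acceptor_exon`, `status`, `count` (sense reads),
#'   `antisense_count`, `start_sites` (distinct sense match positions),
#'   `max_overlap` (bases on the lesser side of the boundary, maximized
#'   over sense reads; NA when only antisense reads hit). An attribute
#'   `summary` records input/discard tallies.
#' @export
map_junction_reads <- function(reads, db, genome = NULL) {
  empty <- data.frame(junction_id = character(), gene_id = character(),
                      donor_exon = character(), acceptor_exon = character(),
                      status = character(), count = integer(),
                      antisense_count = integer(), start_sites = integer(),
                      max_overlap = integer(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0 || nrow(db) == 0) {
    attr(empty, "summary") <- c(n_reads = nrow(reads), n_counted = 0L,
                                n_discarded_multi = 0L,
                                n_discarded_genome = 0L,
                                n_boundary_fail = 0L)
    return(empty)
  }

  n_genome_hit <- 0L
  if (!is.null(genome)) {
    genome_hit <- vapply(reads$seq, function(s) {
      any(vapply(as.character(genome), function(ch)
        grepl(s, ch, fixed = TRUE) ||
          grepl(revcomp_chr(s), ch, fixed = TRUE), logical(1)))
    }, logical(1), USE.NAMES = FALSE)
    n_genome_hit <- sum(genome_hit)
    reads <- reads[!genome_hit, , drop = FALSE]
  }
  if (nrow(reads) == 0) {
    attr(empty, "summary") <- c(n_reads = 0L, n_counted = 0L,
                                n_discarded_multi = 0L,
                                n_discarded_genome = n_genome_hit,
                                n_boundary_fail = 0L)
    return(empty)
  }

  jseq <- Biostrings::DNAStringSet(db$seq)
  match_pairs <- function(seqs) {
    # (read index, junction index) pairs for exact full-read substring hits
    widths <- nchar(seqs)
    pairs <- list()
    for (w in unique(widths)) {
      idx <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
      hit_lists <- Biostrings::vwhichPDict(pd, jseq)
      for (j in seq_along(hit_lists)) {
        h <- hit_lists[[j]]
        if (length(h)) {
          pairs[[length(pairs) + 1L]] <-
            data.frame(read = idx[h], junction = j)
        }
      }
    }
    if (!length(pairs)) {
      return(data.frame(read = integer(), junction = integer()))
    }
    do.call(rbind, pairs)
  }

  sense <- match_pairs(reads$seq)
  anti <- match_pairs(revcomp_chr(reads$seq))
  sense$orientation <- rep("sense", nrow(sense))
  anti$orientation <- rep("antisense", nrow(anti))
  hits <- rbind(sense, anti)
  if (nrow(hits) == 0) {
    attr(empty, "summary") <- c(n_reads = nrow(reads), n_counted = 0L,
                                n_discarded_multi = 0L,
                                n_discarded_genome = n_genome_hit,
                                n_boundary_fail = 0L)
    return(empty)
  }

  # discard reads matching more than one junction record
  n_jx_per_read <- tapply(hits$junction, hits$read,
                          function(j) length(unique(j)))
  multi_reads <- as.integer(names(n_jx_per_read)[n_jx_per_read > 1])
  hits <- hits[!hits$read %in% multi_reads, , drop = FALSE]

  # match position and boundary coverage
  pos <- vapply(seq_len(nrow(hits)), function(i) {
    s <- reads$seq[hits$read[i]]
    if (hits$orientation[i] == "antisense") s <- revcomp_chr(s)
    as.integer(regexpr(s, db$seq[hits$junction[i]], fixed = TRUE))
  }, integer(1))
  w <- nchar(reads$seq[hits$read])
  dc <- db$donor_contrib[hits$junction]
  donor_side <- dc - pos + 1L
  acceptor_side <- pos + w - 1L - dc
  spans <- donor_side >= 1L & acceptor_side >= 1L
  n_boundary_fail <- sum(!spans)
  hits <- hits[spans, , drop = FALSE]
  pos <- pos[spans]
  overlap <- pmin(donor_side, acceptor_side)[spans]

  if (nrow(hits) == 0) {
    attr(empty, "summary") <- c(n_reads = nrow(reads), n_counted = 0L,
                                n_discarded_multi = length(multi_reads),
                                n_discarded_genome = n_genome_hit,
                                n_boundary_fail = n_boundary_fail)
    return(empty)
  }

  out <- lapply(sort(unique(hits$junction)), function(j) {
    sel <- hits$junction == j
    sns <- sel & hits$orientation == "sense"
    data.frame(
      junction_id = db$junction_id[j], gene_id = db$gene_id[j],
      donor_exon = db$donor_exon[j], acceptor_exon = db$acceptor_exon[j],
      status = db$status[j],
      count = sum(sns), antisense_count = sum(sel) - sum(sns),
      start_sites = length(unique(pos[sns])),
      max_overlap = if (any(sns)) max(overlap[sns]) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "summary") <- c(n_reads = nrow(reads),
                            n_counted = nrow(hits),
                            n_discarded_multi = length(multi_reads),
                            n_discarded_genome = n_genome_hit,
                            n_boundary_fail = n_boundary_fail)
  res
}

#' High-confidence junction filter
#'
#' Keeps junctions supported by at least `min_reads` sense reads with at
#' least `min_start_sites` distinct start sites and a boundary overlap
#' of at least `min_overlap` bases.
#'
#' @param hits a hit table from [map_junction_reads()].
#' @param min_reads minimum sense read count (default 5).
#' @param min_start_sites minimum distinct start sites (default 2).
#' @param min_overlap minimum bases on the lesser side of the boundary
#'   (default 12).
#' @return the filtered hit table.
#' @export
high_confidence_filter <- function(hits, min_reads = 5L,
                                   min_start_sites = 2L,
                                   min_overlap = 12L) {
  keep <- hits$count >= min_reads &
    hits$start_sites >= min_start_sites &
    !is.na(hits$max_overlap) & hits$max_overlap >= min_overlap
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold junction evidence back into exon counts
#'
#' Each sense junction read increments the counts of both flanking exons
#' by one; normalized expression is recomputed downstream.
#'
#' @param exon_counts data.frame `exon_id`, `count`.
#' @param hits a hit table from [map_junction_reads()] (typically the
#'   known-junction hits).
#' @return the updated `exon_counts` data.frame.
#' @export
augment_exon_counts <- function(exon_counts, hits) {
  if (nrow(hits) == 0) return(exon_counts)
  ref <- c(hits$donor_exon, hits$acceptor_exon)
  missing <- setdiff(ref, exon_counts$exon_id)
  if (length(missing)) {
    stop("junction references unknown exon(s): ",
         paste(missing, collapse = ", "))
  }
  add <- tapply(rep(hits$count, 2L), ref, sum)
  i <- match(names(add), exon_counts$exon_id)
  exon_counts$count[i] <- exon_counts$count[i] + as.integer(add)
  exon_counts
}
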