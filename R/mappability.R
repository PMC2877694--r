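## Genome mappability: exact-match k-mer uniqueness profiling. A start
## position is non-unique when its k-mer occurs at two or more distinct
## start positions anywhere in the genome (same strand; reverse-complement
## matching is optional). The per-interval count of non-unique starts, U,
## feeds the effective length L - U used by the normalized expression
## measure and the silent-chromosome eligibility filter.

#' Build a k-mer mappability profile
#'
#' For every start position of every chromosome, marks whether the k-mer
#' beginning there occurs elsewhere in the genome (exact match). Marking
#' is symmetric: every occurrence of a repeated k-mer is marked. The
#' production path hashes all k-mers at once (contract-equivalent to the
#' literal all-against-all search).
#'
#' @param genome a named `DNAStringSet` or named character vector.
#' @param k word length in bases (default 50).
#' @param reverse_complement also treat a position as non-unique when its
#'   k-mer equals the reverse complement of another position's k-mer
#'   (default FALSE: same-strand matching only).
#' @return a `mappability_profile`: a list of logical vectors, one per
#'   chromosome, of length equal to the chromosome (positions past
#'   length - k + 1 are always FALSE), with attribute `k`.
#' @export
build_mappability <- function(genome, k = 50L) {
  build_mappability_profile(genome, k)
}

#' @rdname build_mappability
#' @export
build_mappability_profile <- function(genome, k = 50L,
                                      reverse_complement = FALSE) {
  seqs <- if (methods::is(genome, "DNAStringSet")) as.character(genome)
          else genome
  if (is.null(names(seqs))) stop("genome must be named by chromosome")
  lens <- nchar(seqs)
  short <- lens < k
  if (any(short)) {
    warning("chromosome(s) shorter than k yield empty profiles: ",
            paste(names(seqs)[short], collapse = ", "))
  }
  kmers <- lapply(seq_along(seqs), function(i) {
    n <- lens[i]
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(seqs[i], starts, starts + k - 1L)
  })
  all_kmers <- unlist(kmers, use.names = FALSE)
  marked <- duplicated(all_kmers) | duplicated(all_kmers, fromLast = TRUE)
  if (reverse_complement) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(all_kmers)))
    marked <- marked | rc %in% all_kmers
  }
  profile <- vector("list", length(seqs))
  names(profile) <- names(seqs)
  off <- 0L
  for (i in seq_along(seqs)) {
    v <- rep(FALSE, lens[i])
    nk <- length(kmers[[i]])
    if (nk > 0) v[seq_len(nk)] <- marked[off + seq_len(nk)]
    profile[[i]] <- v
    off <- off + nk
  }
  structure(profile, k = as.integer(k), class = "mappability_profile")
}

#' @export
print.mappability_profile <- function(x, ...) {
  cat("mappability_profile: k =", attr(x, "k"), "\n")
  for (ch in names(x)) {
    cat(" ", ch, ": ", sum(x[[ch]]), "/", length(x[[ch]]),
        " non-unique start positions\n", sep = "")
  }
  invisible(x)
}

#' Count non-unique start positions in an interval
#'
#' U = number of marked k-mer start positions whose coordinate lies in
#' `[start, end)` (0-based half-open), including starts whose k-mer
#' extends past the interval end.
#'
#' @param profile a `mappability_profile`.
#' @param chrom chromosome name.
#' @param start,end interval bounds, 0-based half-open.
#' @return integer count U, `0 <= U <= end - start`.
#' @export
count_nonunique <- function(profile, chrom, start, end) {
  if (!chrom %in% names(profile)) stop("unknown chromosome: ", chrom)
  v <- profile[[chrom]]
  if (start < 0 || end > length(v) || end < start) {
    stop("interval out of chromosome bounds")
  }
  if (end == start) return(0L)
  sum(v[(start + 1L):end])
}

#' Effective (uniquely mappable) interval length
#'
#' Interval length minus the number of non-unique start positions it
#' contains. May be <= 0 for heavily duplicated intervals; callers must
#' treat such intervals as ineligible for normalized expression.
#'
#' @inheritParams count_nonunique
#' @return integer L - U (possibly <= 0).
#' @export
effective_length <- function(profile, chrom, start, end) {
  (end - start) - count_nonunique(profile, chrom, start, end)
}

#' Non-unique runs as a BED-writable data.frame
#'
#' Collapses marked start positions into maximal runs.
#'
#' @param profile a `mappability_profile`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open runs of
#'   non-unique start positions).
#' @export
mappability_runs <- function(profile) {
  out <- lapply(names(profile), function(ch) {
    v <- profile[[ch]]
    if (!any(v)) return(NULL)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
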