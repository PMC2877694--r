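## Expected-error read filtering. A base with Phred quality value QV has
## error probability p = 10^(-QV/10); the expected number of erroneous
## calls in a read is the sum of its per-base error probabilities. Reads
## whose expected error exceeds the threshold (default 6) are discarded
## before any counting.

#' Expected number of base-call errors in a read
#'
#' `sum(10^(-QV/10))` over the read's per-position quality values.
#' Monotone non-increasing in every QV: raising all QVs by 10 divides the
#' result by exactly 10.
#'
#' @param qualities integer vector of per-position Phred quality values
#'   (all >= 0), or a '!'-offset quality string.
#' @return non-negative expected-error value.
#' @export
#' @examples
#' expected_error(rep(10, 50))  # 50 bases at p = 0.1 -> 5
expected_error <- function(qualities) {
  if (is.character(qualities)) {
    stopifnot(length(qualities) == 1L)
    qualities <- string_to_qv(qualities)
  }
  if (length(qualities) == 0) stop("zero-length read: no quality values")
  if (any(qualities < 0)) stop("quality values must be >= 0")
  sum(10^(-qualities / 10))
}

#' Filter reads by expected error
#'
#' A read is retained iff its expected error is <= `threshold` (the
#' discard rule is strictly "greater than", so ties at the threshold are
#' kept). Filtering is idempotent.
#'
#' @param reads a FASTQ path or a data.frame with `read_id` and `qual`
#'   (quality strings) as produced by [read_reads_fastq()].
#' @param threshold positive expected-error cutoff (default 6).
#' @return list with `retained_ids` (character vector) and `summary`
#'   (data.frame: total, removed, fraction_removed).
#' @export
filter_reads <- function(reads, threshold = 6) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.character(reads)) reads <- read_reads_fastq(reads)
  stopifnot(all(c("read_id", "qual") %in% names(reads)))
  if (nrow(reads) == 0) {
    return(list(retained_ids = character(0),
                summary = data.frame(total = 0L, removed = 0L,
                                     fraction_removed = 0)))
  }
  ee <- vapply(reads$qual, function(q) expected_error(q), numeric(1),
               USE.NAMES = FALSE)
  keep <- ee <= threshold
  list(
    retained_ids = reads$read_id[keep],
    summary = data.frame(total = nrow(reads),
                         removed = sum(!keep),
                         fraction_removed = mean(!keep))
  )
}
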