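## Standard-format readers/writers. Sequence formats go through Biostrings,
## interval formats through rtracklayer; only the one-dialect TSV layer is
## local (tab-separated, '#'-prefixed header, '.' decimal point).

#' Write a genome as FASTA
#'
#' @param genome a named `DNAStringSet` (one entry per chromosome).
#' @param path output file; sequence lines wrap at 60 columns.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are upper-cased on read; names are truncated at the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `seq`, `qual` (integer-list
#'   column or '!'-offset quality strings).
#' @param path output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  qual <- if (is.character(reads$qual)) reads$qual else
    vapply(reads$qual, qv_to_string, character(1))
  q <- Biostrings::PhredQuality(qual)
  x <- Biostrings::QualityScaledDNAStringSet(seqs, q)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame `read_id`, `seq`, `qual` (quality strings).
#' @export
read_reads_fastq <- function(path) {
  out <- tryCatch({
    # structural validation first: the Biostrings reader silently pads
    # records whose quality line is shorter than the sequence line
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) {
      stop("line count is not a multiple of 4")
    }
    if (length(lines) > 0) {
      heads <- lines[seq(1L, length(lines), by = 4L)]
      seqs <- lines[seq(2L, length(lines), by = 4L)]
      quals <- lines[seq(4L, length(lines), by = 4L)]
      bad <- which(!startsWith(heads, "@") |
                     nchar(seqs) != nchar(quals))[1]
      if (!is.na(bad)) {
        stop("record '", sub("^@", "", heads[bad]),
             "' (line ", 4L * (bad - 1L) + 1L,
             "): bad header or sequence/quality length mismatch")
      }
    }
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(
        path, quality.scoring = "phred"),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    data.frame(
      read_id = sub("\\s.*$", "", names(x)),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x)),
      stringsAsFactors = FALSE
    )
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  out
}

#' Phred quality conversions
#'
#' `qv_to_string()` encodes integer quality values on the '!'-offset
#' (Phred+33) scale; `string_to_qv()` decodes.
#'
#' @param qv integer vector of quality values.
#' @return a single quality string.
#' @export
qv_to_string <- function(qv) {
  intToUtf8(as.integer(qv) + 33L)
}

#' @rdname qv_to_string
#' @param s a quality string.
#' @export
string_to_qv <- function(s) {
  utf8ToInt(s) - 33L
}

#' Write alignments as BED6
#'
#' Columns: chrom, start, end, read_id (name), multiplicity (score),
#' strand. BED is 0-based half-open, identical to the internal convention.
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `read_id`,
#'   `multiplicity`, `strand`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(alignments, path) {
  gr <- intervals_to_granges(
    alignments[, c("chrom", "start", "end", "strand")])
  S4Vectors::mcols(gr)$name <- alignments$read_id
  S4Vectors::mcols(gr)$score <- alignments$multiplicity
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 alignment file
#'
#' @param path BED file written by [write_alignments_bed()].
#' @return data.frame `chrom`, `start`, `end`, `read_id`, `multiplicity`,
#'   `strand`.
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    read_id = S4Vectors::mcols(gr)$name,
    multiplicity = as.integer(S4Vectors::mcols(gr)$score),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write / read the package's TSV dialect
#'
#' Tab-separated, UTF-8, '#'-prefixed header line, '.' decimal point,
#' floats at 6 significant digits.
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot open file '", path, "'")
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing '#' header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  } else names(df) <- cols
  df
}
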