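## Poisson-based differential expression for single-replicate count
## data (Audic-Claverie), threshold-grid alignment of DE calls across
## platforms, and exon-length bias diagnostics. The AC model gives the
## probability of observing y reads on an exon in sample 2 given x reads
## in sample 1 and library sizes N1, N2:
##   p(y | x) = (N2/N1)^y * (x+y)! / (x! * y! * (1 + N2/N1)^(x+y+1))
## computed in log space via lgamma.

#' Audic-Claverie point probability
#'
#' For fixed `x`, `p(y|x)` is a proper distribution over y (sums to 1).
#'
#' @param x reads on the exon in sample 1 (vectorized).
#' @param y reads on the exon in sample 2.
#' @param N1,N2 total unique reads in samples 1 and 2.
#' @return point probability in (0, 1].
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 1/2
ac_probability <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), N1 > 0, N2 > 0)
  lr <- log(N2) - log(N1)
  lp <- y * lr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(N2 / N1)
  exp(lp)
}

## cumulative lower tail P(Y <= y | x), by direct summation
ac_lower_tail <- function(x, y, N1, N2) {
  sum(ac_probability(x, 0:y, N1, N2))
}

#' Audic-Claverie p-value
#'
#' One-sided: the tail sum of `p(y'|x)` over outcomes as or more
#' extreme than the observed `y` in the observed direction (upper tail
#' when `y/N2 >= x/N1`). Two-sided (default): twice the smaller tail,
#' capped at 1 — the conservative doubling convention.
#'
#' @inheritParams ac_probability
#' @param sided `"two"` (default) or `"one"`.
#' @return p-value in (0, 1] (vectorized over `x`, `y`).
#' @export
ac_pvalue <- function(x, y, N1, N2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) {
    lower <- ac_lower_tail(x[i], y[i], N1, N2)
    upper <- 1 - lower + ac_probability(x[i], y[i], N1, N2)
    upper <- min(1, max(upper, ac_probability(x[i], y[i], N1, N2)))
    if (sided == "one") {
      if (y[i] / N2 >= x[i] / N1) upper else lower
    } else {
      min(1, 2 * min(lower, upper))
    }
  }, numeric(1))
}

#' Differential-expression threshold grid
#'
#' Varies a DE threshold independently on each platform and computes the
#' correspondence score of the resulting DE / not-DE calls at every
#' combination. In `"fc"` mode a feature is called DE when its absolute
#' statistic reaches the threshold (`|stat| >= thr`); in `"p"` mode when
#' its p-value is strictly below the threshold. The optimum is the
#' maximal-CS cell, ties broken by the lowest RNA-Seq threshold and then
#' the lowest array threshold.
#'
#' @param seq_stat,array_stat per-exon statistics on a common universe
#'   (log2 fold changes or p-values).
#' @param seq_thresholds,array_thresholds threshold axes.
#' @param seq_mode,array_mode `"fc"` or `"p"` per platform.
#' @return list with `cs` matrix (RNA-Seq thresholds x array
#'   thresholds), `optimum` (`seq_threshold`, `array_threshold`, `cs`)
#'   and the axes.
#' @export
de_threshold_grid <- function(seq_stat, array_stat,
                              seq_thresholds, array_thresholds,
                              seq_mode = c("fc", "p"),
                              array_mode = c("fc", "p")) {
  seq_mode <- match.arg(seq_mode); array_mode <- match.arg(array_mode)
  ok <- !is.na(seq_stat) & !is.na(array_stat)
  if (!any(ok)) stop("empty exon universe for the DE grid")
  s <- seq_stat[ok]; a <- array_stat[ok]
  de_call <- function(stat, thr, mode) {
    if (mode == "fc") abs(stat) >= thr else stat < thr
  }
  cs <- matrix(NA_real_, length(seq_thresholds), length(array_thresholds),
               dimnames = list(as.character(seq_thresholds),
                               as.character(array_thresholds)))
  for (i in seq_along(seq_thresholds)) {
    sd_call <- de_call(s, seq_thresholds[i], seq_mode)
    for (j in seq_along(array_thresholds)) {
      ad_call <- de_call(a, array_thresholds[j], array_mode)
      ct <- contingency_table(sd_call, ad_call)
      cs[i, j] <- correspondence_score(ct$A, ct$B, ct$C, ct$D,
                                       na_on_undefined = TRUE)
    }
  }
  best <- which(cs == max(cs, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(seq_thresholds[best[, 1]],
                     array_thresholds[best[, 2]]), , drop = FALSE]
  list(cs = cs,
       optimum = list(seq_threshold = seq_thresholds[best[1, 1]],
                      array_threshold = array_thresholds[best[1, 2]],
                      cs = cs[best[1, 1], best[1, 2]]),
       seq_thresholds = seq_thresholds,
       array_thresholds = array_thresholds)
}

#' Exon-length bias of differential-expression calls
#'
#' Under uniform read sampling, count-based tests gain power with
#' feature length; this summarizes the DE call rate by exon-length
#' quartile. Quartile boundaries come from the supplied length
#' distribution; the lower/upper headline rates use strict comparisons
#' (length < Q1, length > Q3).
#'
#' @param de_calls logical DE calls.
#' @param lengths exon lengths (bases), same order as `de_calls`.
#' @return list with `overall`, `lower_quartile`, `upper_quartile`
#'   (DE fractions), and `table` (per-quartile n, n_de, fraction).
#' @export
length_bias <- function(de_calls, lengths) {
  stopifnot(length(de_calls) == length(lengths))
  if (length(lengths) < 4) stop("need at least 4 exons for quartiles")
  q <- quantile(lengths, c(0.25, 0.5, 0.75), names = FALSE)
  breaks <- unique(c(-Inf, q, Inf))   # ties collapse degenerate quartiles
  bin <- cut(lengths, breaks = breaks,
             labels = paste0("Q", seq_len(length(breaks) - 1L)))
  tab <- data.frame(
    quartile = levels(bin),
    n = as.integer(table(bin)),
    n_de = as.integer(tapply(de_calls, bin, sum, default = 0L)),
    stringsAsFactors = FALSE)
  tab <- tab[tab$n > 0, , drop = FALSE]    # ties can empty a bin
  rownames(tab) <- NULL
  tab$fraction <- tab$n_de / tab$n
  lower <- lengths < q[1]; upper <- lengths > q[3]
  list(overall = mean(de_calls),
       lower_quartile = if (any(lower)) mean(de_calls[lower]) else NA_real_,
       upper_quartile = if (any(upper)) mean(de_calls[upper]) else NA_real_,
       q_lower = q[1], q_upper = q[3],
       table = tab)
}

#' Two-sample t-test on array replicate signals
#'
#' The array-side differential-expression stand-in for synthetic
#' triplicate data: an ordinary Welch t-test on the log2 signals of
#' sample 1 versus sample 2 replicates, per probeset.
#'
#' @param array array data.frame (`signal_s*_r*` columns).
#' @param replicates replicates per sample.
#' @return data.frame `probeset_id`, `exon_id`, `fc` (mean log2
#'   difference, sample 2 minus sample 1), `t`, `p`.
#' @export
array_de_ttest <- function(array, replicates = 3L) {
  c1 <- sprintf("signal_s1_r%d", seq_len(replicates))
  c2 <- sprintf("signal_s2_r%d", seq_len(replicates))
  m1 <- as.matrix(array[, c1, drop = FALSE])
  m2 <- as.matrix(array[, c2, drop = FALSE])
  res <- t(vapply(seq_len(nrow(array)), function(i) {
    tt <- t.test(m2[i, ], m1[i, ])
    c(t = unname(tt$statistic), p = tt$p.value)
  }, numeric(2)))
  data.frame(probeset_id = array$probeset_id, exon_id = array$exon_id,
             fc = rowMeans(m2) - rowMeans(m1), t = res[, "t"],
             p = res[, "p"], stringsAsFactors = FALSE)
}
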