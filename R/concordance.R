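## Cross-platform Present/Absent concordance. The correspondence score
## CS is a Matthews-correlation-style statistic on the 2x2 agreement
## table between RNA-Seq detection calls and array detection calls:
## +1 = perfect agreement, 0 = no better than random, -1 = perfect
## disagreement. The same score drives detection threshold grids,
## differential-expression threshold grids and read-cluster thresholds.

#' Correspondence score (modified Matthews correlation)
#'
#' `CS = (A*B - C*D) / sqrt((A+C)(A+D)(B+C)(B+D))` where A counts
#' agreements in the Present state, B agreements in the Absent state,
#' and C, D the two kinds of disagreement. Invariant under scaling all
#' four cells, and symmetric under swapping platform labels
#' (`CS(A,B,C,D) = CS(B,A,D,C)`).
#'
#' @param A both-Present count.
#' @param B both-Absent count.
#' @param C RNA-Seq-Present / array-Absent count.
#' @param D RNA-Seq-Absent / array-Present count.
#' @param na_on_undefined if TRUE, return `NaN` when a marginal is zero
#'   instead of raising an error (used inside grids; never silently 0).
#' @return CS in `[-1, 1]`.
#' @export
#' @examples
#' correspondence_score(1000, 1000, 0, 0)  #  1
#' correspondence_score(0, 0, 1000, 1000)  # -1
correspondence_score <- function(A, B, C, D, na_on_undefined = FALSE) {
  stopifnot(A >= 0, B >= 0, C >= 0, D >= 0)
  m <- c(A + C, A + D, B + C, B + D)
  if (any(m == 0)) {
    if (na_on_undefined) return(NaN)
    stop("correspondence score undefined: a marginal of the 2x2 table is 0")
  }
  (A * B - C * D) / sqrt(prod(m))
}

#' Contingency table from paired logical calls
#'
#' @param seq_present,array_present logical vectors (RNA-Seq and array
#'   Present calls on the same exon universe); NA pairs are dropped.
#' @return named list A, B, C, D.
#' @export
contingency_table <- function(seq_present, array_present) {
  ok <- !is.na(seq_present) & !is.na(array_present)
  s <- seq_present[ok]; a <- array_present[ok]
  list(A = sum(s & a), B = sum(!s & !a), C = sum(s & !a), D = sum(!s & a))
}

## majority / single-replicate Present rule on array detection p-values
array_present_calls <- function(array, sample, alpha, replicates,
                                replicate = NULL) {
  cols <- sprintf("dabg_s%d_r%d", sample, seq_len(replicates))
  p <- as.matrix(array[, cols, drop = FALSE])
  if (!is.null(replicate)) {
    p[, replicate] < alpha
  } else {
    rowSums(p < alpha, na.rm = TRUE) >= ceiling((replicates + 1) / 2)
  }
}

#' Present/Absent detection calls on both platforms
#'
#' RNA-Seq: an exon is Present when its read count exceeds `t` (strict),
#' or its normalized expression exceeds `tau` in expression mode. Array:
#' a probeset is Present when its detection p-value is strictly below
#' `alpha` in a majority of replicates (default 2 of 3), or in one
#' chosen replicate. The exon universe is restricted to exons targeted
#' by exactly one probeset; exons with undefined effective length are
#' excluded.
#'
#' @param exon_table table from [exon_expression_table()].
#' @param array array data.frame from [simulate_array()] or
#'   [read_tsv()] (columns `probeset_id`, `exon_id`, `dabg_s*_r*`).
#' @param t read-count threshold (Present iff count > t); ignored if
#'   `tau` given.
#' @param tau normalized-expression threshold (Present iff E > tau).
#' @param alpha detection p-value cutoff (Present iff p < alpha).
#' @param sample sample index (1 or 2).
#' @param replicates number of array replicates present in `array`.
#' @param replicate if non-NULL, use this single replicate instead of
#'   the majority rule.
#' @return data.frame `exon_id`, `seq_present`, `array_present`.
#' @export
call_detection <- function(exon_table, array, t = 0L, tau = NULL,
                           alpha = 0.01, sample = 1L, replicates = 3L,
                           replicate = NULL) {
  arr <- array[array$exon_id != "NA" & !is.na(array$exon_id), , drop = FALSE]
  n_ps <- table(arr$exon_id)
  single <- names(n_ps)[n_ps == 1L]
  arr <- arr[arr$exon_id %in% single, , drop = FALSE]
  tab <- exon_table[exon_table$eligible &
                      exon_table$exon_id %in% arr$exon_id, , drop = FALSE]
  arr <- arr[match(tab$exon_id, arr$exon_id), , drop = FALSE]

  seq_present <- if (!is.null(tau)) {
    tab[[paste0("E_s", sample)]] > tau
  } else {
    tab[[paste0("S_s", sample)]] > t
  }
  dabg_cols <- sprintf("dabg_s%d_r%d", sample, seq_len(replicates))
  miss <- rowSums(is.na(arr[, dabg_cols, drop = FALSE])) > 0
  if (any(miss)) {
    warning(sum(miss), " exon(s) with missing detection p-values excluded")
  }
  ap <- array_present_calls(arr, sample, alpha, replicates, replicate)
  data.frame(exon_id = tab$exon_id,
             seq_present = seq_present & !miss,
             array_present = ap & !miss,
             stringsAsFactors = FALSE)[!miss, , drop = FALSE]
}

#' Detection threshold grid
#'
#' Varies the RNA-Seq read-count threshold and the array detection
#' p-value cutoff independently, computing CS at every combination.
#' Undefined cells (a zero marginal) are `NaN`. The optimum is the cell
#' with maximal CS, ties broken by smallest `t` then smallest `alpha`.
#'
#' @inheritParams call_detection
#' @param t_values integer read-count thresholds (rows).
#' @param alpha_values detection p-value cutoffs (columns; default the
#'   standard ladder 0.1, 0.05, 0.01, 0.001).
#' @param tau_values optional normalized-expression thresholds replacing
#'   `t_values` (expression mode).
#' @return list with `cs` (matrix t x alpha), `optimum` (list `t`/`tau`,
#'   `alpha`, `cs`) and the axes.
#' @export
detection_grid <- function(exon_table, array,
                           t_values = 0:5,
                           alpha_values = c(0.1, 0.05, 0.01, 0.001),
                           tau_values = NULL, sample = 1L,
                           replicates = 3L, replicate = NULL) {
  stopifnot(length(alpha_values) >= 1)
  axis <- if (is.null(tau_values)) t_values else tau_values
  stopifnot(length(axis) >= 1)
  cs <- matrix(NA_real_, length(axis), length(alpha_values),
               dimnames = list(as.character(axis),
                               as.character(alpha_values)))
  for (j in seq_along(alpha_values)) {
    for (i in seq_along(axis)) {
      calls <- if (is.null(tau_values)) {
        call_detection(exon_table, array, t = axis[i],
                       alpha = alpha_values[j], sample = sample,
                       replicates = replicates, replicate = replicate)
      } else {
        call_detection(exon_table, array, tau = axis[i],
                       alpha = alpha_values[j], sample = sample,
                       replicates = replicates, replicate = replicate)
      }
      ct <- contingency_table(calls$seq_present, calls$array_present)
      cs[i, j] <- correspondence_score(ct$A, ct$B, ct$C, ct$D,
                                       na_on_undefined = TRUE)
    }
  }
  best <- which(cs == max(cs, na.rm = TRUE), arr.ind = TRUE)
  # tie-break: smallest threshold, then smallest alpha; alpha axis is
  # ordered as given (descending ladder), so order by value
  best <- best[order(axis[best[, 1]], alpha_values[best[, 2]]), ,
               drop = FALSE]
  opt <- list(threshold = axis[best[1, 1]],
              alpha = alpha_values[best[1, 2]],
              cs = cs[best[1, 1], best[1, 2]])
  list(cs = cs, optimum = opt, thresholds = axis,
       alpha_values = alpha_values,
       mode = if (is.null(tau_values)) "count" else "expression")
}

#' Log2 fold change with pseudocount
#'
#' `log2(E2 + pseudocount) - log2(E1 + pseudocount)`; the pseudocount
#' (default 0.0001) avoids logs of zero for undetected exons, so exons
#' absent in both samples have fold change exactly 0. Antisymmetric
#' under sample swap.
#'
#' @param E1,E2 non-negative normalized expression values (vectorized).
#' @param pseudocount small constant added to both (default 1e-4).
#' @return log2 fold change.
#' @export
fold_change <- function(E1, E2, pseudocount = 1e-4) {
  if (any(E1 < 0, na.rm = TRUE) || any(E2 < 0, na.rm = TRUE)) {
    stop("normalized expression must be non-negative")
  }
  log2(E2 + pseudocount) - log2(E1 + pseudocount)
}

#' Cross-platform transition categories
#'
#' Collapses the four Present/Absent states (RNA-Seq sample 1/2, array
#' sample 1/2) of each exon into the standard classes: Present
#' everywhere (`PP_PP`); Absent in at least one sample on both
#' platforms (`absent_both`); Absent in at least one RNA-Seq sample
#' only (`absent_seq_only`); Absent in at least one array sample only
#' (`absent_array_only`). The classes partition the universe.
#'
#' @param seq_p1,seq_p2,arr_p1,arr_p2 logical Present calls per platform
#'   and sample.
#' @return factor of classes.
#' @export
transition_categories <- function(seq_p1, seq_p2, arr_p1, arr_p2) {
  seq_absent <- !seq_p1 | !seq_p2
  arr_absent <- !arr_p1 | !arr_p2
  cls <- ifelse(!seq_absent & !arr_absent, "PP_PP",
         ifelse(seq_absent & arr_absent, "absent_both",
         ifelse(seq_absent, "absent_seq_only", "absent_array_only")))
  factor(cls, levels = c("PP_PP", "absent_both", "absent_seq_only",
                         "absent_array_only"))
}

#' Fold-change correspondence between platforms
#'
#' The headline statistic is the Pearson correlation of RNA-Seq and
#' array fold changes over exons Present in both samples on both
#' platforms (the only class with reliable signal-to-noise). For exons
#' flagged as changing Absent-to-Present on at least one platform, the
#' direction-agreement fraction is also reported (a zero fold change
#' agrees only with zero).
#'
#' @param seq_fc,array_fc log2 fold changes on the common exon universe.
#' @param seq_p1,seq_p2,arr_p1,arr_p2 logical Present calls (sample 1
#'   and 2 on each platform).
#' @return list with `r_pp` (correlation in the all-Present class),
#'   `r_by_category` (per-class correlations, NA when a class has fewer
#'   than 3 exons), `direction_agreement` and `n_absent_to_present`.
#' @export
fc_correspondence <- function(seq_fc, array_fc,
                              seq_p1, seq_p2, arr_p1, arr_p2) {
  cls <- transition_categories(seq_p1, seq_p2, arr_p1, arr_p2)
  cor_or_na <- function(x, y) {
    if (length(x) < 3) return(NA_real_)
    cor(x, y)
  }
  r_by_cat <- vapply(levels(cls), function(lv) {
    sel <- cls == lv
    cor_or_na(seq_fc[sel], array_fc[sel])
  }, numeric(1))

  a_to_p <- (!seq_p1 & seq_p2) | (!arr_p1 & arr_p2)
  agree <- sign(seq_fc[a_to_p]) == sign(array_fc[a_to_p])
  list(r_pp = unname(r_by_cat["PP_PP"]),
       r_by_category = r_by_cat,
       direction_agreement = if (any(a_to_p)) mean(agree) else NA_real_,
       n_absent_to_present = sum(a_to_p))
}
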