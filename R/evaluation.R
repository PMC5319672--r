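#' Score a call set against a truth set
#'
#' Counts true positives (calls present in the truth set), false positives
#' (calls absent from it) and false negatives (truth variants never called),
#' and derives sensitivity `TP/(TP+FN)` and positive predictive value
#' `TP/(TP+FP)`. True negatives are undefined for call sets, so specificity
#' is not reported. Matching is exact on `(chrom, pos, ref, alt)`; pass both
#' sets through [normalize_calls()] first when they may differ in indel
#' representation.
#'
#' A ratio with denominator zero is `NA` internally and displayed as `"/"`
#' by [format_eval()]. Duplicate calls are collapsed before counting, with a
#' warning.
#'
#' @param calls Data frame of called variants (`chrom`, `pos`, `ref`, `alt`).
#' @param truth Data frame of known true variants, same columns.
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `ppv` (full
#'   precision; round only for display).
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", pos = 1:4, ref = "A", alt = "G")
#' truth <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "G")
#' score_calls(calls, truth)
#' @export
score_calls <- function(calls, truth) {
  ck <- .call_key(calls)
  tk <- .call_key(truth)
  if (anyDuplicated(ck)) {
    rlang::warn(sprintf("%d duplicate call(s) collapsed before scoring",
                        sum(duplicated(ck))))
    ck <- unique(ck)
  }
  tk <- unique(tk)
  tp <- sum(ck %in% tk)
  fp <- length(ck) - tp
  fn <- length(tk) - tp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    # PPV is also undefined when the truth set is empty: with no true
    # variants to find, precision against the panel is not calculable
    ppv = if (tp + fp > 0 && tp + fn > 0) tp / (tp + fp) else NA_real_
  )
}

#' PPV improvement factor between two evaluation summaries
#'
#' Ratio of PPV with the trained filter to PPV without it, at full precision.
#' Undefined (`NA`) when the baseline PPV is zero or undefined.
#'
#' @param summary_without,summary_with One-row tibbles from [score_calls()].
#' @return Scalar ratio.
#' @export
improvement_factor <- function(summary_without, summary_with) {
  p0 <- summary_without$ppv[1]
  p1 <- summary_with$ppv[1]
  if (is.na(p0) || is.na(p1) || p0 == 0) return(NA_real_)
  p1 / p0
}

#' Intersect two call sets
#'
#' Calls match on normalized `(chrom, pos, ref, alt)`. Used for
#' re-sequencing overlap analysis: variants called in both runs of the same
#' sample, separating reproducible (systematic) calls from random errors.
#'
#' @param set_a,set_b Data frames of calls.
#' @return Tibble of the rows of `set_a` also present in `set_b`.
#' @export
overlap_calls <- function(set_a, set_b) {
  dplyr::filter(tibble::as_tibble(set_a), .call_key(set_a) %in% .call_key(set_b))
}

#' Ratio of false positive counts between two runs
#'
#' Intra-platform variation statistic: how many times as many false
#' positives one sequencing run produced compared to another of the same
#' samples.
#'
#' @param count_set2,count_set1 False positive counts; `count_set1` must be
#'   positive.
#' @return `count_set2 / count_set1` at full precision.
#' @export
fp_ratio <- function(count_set2, count_set1) {
  stopifnot(count_set1 > 0)
  count_set2 / count_set1
}

#' Display-format an evaluation summary
#'
#' Ratios rounded half-up to 2 decimals; undefined ratios shown as `"/"`.
#'
#' @param summary Tibble from [score_calls()].
#' @return Tibble with character `sensitivity` and `ppv` columns.
#' @export
format_eval <- function(summary) {
  fmt <- function(x) ifelse(is.na(x), "/", sprintf("%.2f", round_half_up(x, 2)))
  dplyr::mutate(summary,
    sensitivity = fmt(.data$sensitivity),
    ppv = fmt(.data$ppv)
  )
}

# round half away from zero at `digits` decimals (report convention; R's
# round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
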