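#' Normalize variant representation
#'
#' Puts every call into a canonical `(chrom, pos, ref, alt)` representation so
#' that call sets and truth sets can be compared exactly: redundant shared
#' bases are trimmed (common suffix first, then common prefix, adjusting
#' `pos`), and, when a reference sequence is supplied, indels are left-aligned
#' by shifting them as far 5' as the reference allows.
#'
#' Truth matching is exact-match after this normalization; without it, the
#' same indel written at two anchor positions would count once as a false
#' positive and once as a false negative.
#'
#' @param calls Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param reference Optional named [Biostrings::DNAStringSet] (names =
#'   chromosome) used to left-align indels; trimming alone needs no reference.
#' @return The input tibble with normalized `pos`, `ref`, `alt` and `type`
#'   recomputed.
#' @export
normalize_calls <- function(calls, reference = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(calls)))
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) return(calls)
  norm <- purrr::pmap(
    list(calls$chrom, calls$pos, calls$ref, calls$alt),
    function(chrom, pos, ref, alt) .normalize_one(chrom, pos, ref, alt, reference)
  )
  calls$pos <- purrr::map_dbl(norm, "pos")
  calls$ref <- purrr::map_chr(norm, "ref")
  calls$alt <- purrr::map_chr(norm, "alt")
  if ("type" %in% names(calls)) calls$type <- variant_type_of(calls$ref, calls$alt)
  calls
}

.normalize_one <- function(chrom, pos, ref, alt, reference) {
  # trim common suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1, nchar(ref) - 1L)
    alt <- substring(alt, 1, nchar(alt) - 1L)
  }
  # trim common prefix, keeping one anchor base for indels
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, 1, 1) == substring(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2)
    pos <- pos + 1
  }
  # left-align pure insertions/deletions against the reference
  if (!is.null(reference) && chrom %in% names(reference) &&
      nchar(ref) != nchar(alt)) {
    chromseq <- reference[[chrom]]
    repeat {
      enc <- indel_encoding(ref, alt)
      if (is.na(enc) || pos <= 1) break
      varseq <- substring(enc, 2)          # inserted or deleted bases
      last <- substring(varseq, nchar(varseq))
      prev <- as.character(Biostrings::subseq(chromseq, pos, pos))
      # shiftable iff the indel's last base equals the current anchor base
      if (last != prev) break
      shifted <- paste0(prev, substring(varseq, 1, nchar(varseq) - 1L))
      pos <- pos - 1
      anchor <- as.character(Biostrings::subseq(chromseq, pos, pos))
      if (startsWith(enc, "+")) {
        ref <- anchor; alt <- paste0(anchor, shifted)
      } else {
        ref <- paste0(anchor, shifted); alt <- anchor
      }
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

.call_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
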