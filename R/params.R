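#' Variant-characterizing parameter registry
#'
#' The package scores every call on a fixed panel of 23 parameters grouped by
#' what they characterize: quality and depth, coverage, allele frequency,
#' strand bias, variant position in the read, base quality, mapping quality,
#' homopolymer context and indel width. 18 apply to SNVs and 22 to indels:
#' the homopolymer and indel-width parameters (`HP`, `HP_AT`, `HP_CG`,
#' `VARW`, `DevGT`) are indel-only, while the calculated mean alt base
#' quality `BQ` is SNV-only.
#'
#' Parameters suffixed `_vcf` are copied from GATK annotations in the VCF
#' (`QUAL`, `DP`, `QD`, `AD`, `FS`, `SOR`, `ReadPosRankSum`, `BaseQRankSum`,
#' `MQ`, `MQRankSum`); the rest are calculated from the read pileup and the
#' reference sequence.
#'
#' @param variant_type `"SNV"`, `"INDEL"`, or `"all"` (default) for the full
#'   panel in its canonical order.
#' @return Character vector of parameter names.
#' @examples
#' glm_params("SNV")
#' setdiff(glm_params("all"), glm_params("INDEL"))
#' @export
glm_params <- function(variant_type = c("all", "SNV", "INDEL")) {
  variant_type <- match.arg(variant_type)
  switch(variant_type,
    all   = .param_registry$name,
    SNV   = .param_registry$name[.param_registry$snv],
    INDEL = .param_registry$name[.param_registry$indel]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical order: quality/depth, coverage, allele frequency, strand bias,
# variant position, base quality, mapping quality, homopolymer, indel width
.param_registry <- tibble::tibble(
  name = c(
    "Q", "DP", "QD",
    "Cov_total", "Cov_ref", "Cov_vcf",
    "AF_total", "AF_ref", "AF_vcf",
    "SB", "SB_vcf", "SOR",
    "VP", "VP_vcf",
    "BQ", "BQ_vcf",
    "MQ", "MQRank",
    "HP", "HP_AT", "HP_CG",
    "VARW", "DevGT"
  ),
  snv = c(rep(TRUE, 18), rep(FALSE, 5)),
  indel = c(rep(TRUE, 14), FALSE, rep(TRUE, 8))
)

# rank-sum-type statistics and Phred-scaled bias scores whose GATK null value
# is 0; safe to impute when GATK omits them (e.g. homozygous-alt sites)
.zero_null_params <- c("VP_vcf", "BQ_vcf", "MQRank", "SB_vcf", "SOR")

#' Default VCF annotation key aliases
#'
#' Maps each parameter sourced from the VCF to the INFO/FORMAT keys it may be
#' stored under. GATK versions differ in spelling; supply a modified copy of
#' this list to [read_vcf()] to accommodate local conventions.
#'
#' @return Named list: parameter name -> character vector of candidate keys.
#' @export
vcf_key_aliases <- function() {
  list(
    DP     = "DP",
    QD     = "QD",
    SB_vcf = c("FS"),
    SOR    = c("SOR"),
    VP_vcf = c("ReadPosRankSum"),
    BQ_vcf = c("BaseQRankSum"),
    MQ     = c("MQ"),
    MQRank = c("MQRankSum")
  )
}

#' Classify a ref/alt allele pair
#'
#' A call is an SNV iff both alleles are single bases; anything else
#' (length-changing or multi-base substitution) is treated as an indel.
#'
#' @param ref,alt Uppercase allele strings over \{A,C,G,T\}.
#' @return `"SNV"` or `"INDEL"`, vectorized.
#' @export
variant_type_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

.assert_alleles <- function(ref, alt) {
  ok <- nchar(ref) > 0 & nchar(alt) > 0 &
    !grepl("[^ACGT]", ref) & !grepl("[^ACGT]", alt)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    rlang::abort(sprintf(
      "invalid allele pair at entry %d: ref='%s', alt='%s' (alphabet {A,C,G,T})",
      bad, ref[bad], alt[bad]
    ))
  }
  invisible(TRUE)
}

# Signed indel encoding relative to the VCF anchor base: "+SEQ" for an
# insertion, "-SEQ" for a deletion. Used to compare read-level indel
# observations with the called allele (VARW / DevGT).
indel_encoding <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    if (nchar(a) > nchar(r) && startsWith(a, r)) {
      out[i] <- paste0("+", substring(a, nchar(r) + 1L))
    } else if (nchar(r) > nchar(a) && startsWith(r, a)) {
      out[i] <- paste0("-", substring(r, nchar(a) + 1L))
    } else {
      out[i] <- NA_character_  # complex substitution: no simple encoding
    }
  }
  out
}
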