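#' Parameters copied from VCF annotations
#'
#' Maps a call's GATK annotations onto the parameter panel: `Q` (QUAL),
#' `DP`, `QD`, `SB_vcf` (FS), `SOR`, `VP_vcf` (ReadPosRankSum), `BQ_vcf`
#' (BaseQRankSum), `MQ`, `MQRank` (MQRankSum), and the AD-derived
#' `Cov_vcf = #ref + #alt` and `AF_vcf = #alt / (#ref + #alt)`. Absent
#' annotations propagate as `NA`, never as zero (imputation is a modeling
#' policy, not an extraction one).
#'
#' @param calls Calls tibble from [read_vcf()] (columns `Q`, `DP`, `QD`,
#'   `SB_vcf`, `SOR`, `VP_vcf`, `BQ_vcf`, `MQ`, `MQRank`, `AD_ref`,
#'   `AD_alt`).
#' @return Tibble of per-call VCF-sourced parameters.
#' @export
vcf_features <- function(calls) {
  calls <- tibble::as_tibble(calls)
  grab <- function(col) if (col %in% names(calls)) calls[[col]] else rep(NA_real_, nrow(calls))
  ad_ref <- grab("AD_ref"); ad_alt <- grab("AD_alt")
  cov_vcf <- ad_ref + ad_alt
  tibble::tibble(
    Q = grab("Q"), DP = grab("DP"), QD = grab("QD"),
    Cov_vcf = cov_vcf,
    AF_vcf = ifelse(!is.na(cov_vcf) & cov_vcf > 0, ad_alt / cov_vcf, NA_real_),
    SB_vcf = grab("SB_vcf"), SOR = grab("SOR"),
    VP_vcf = grab("VP_vcf"), BQ_vcf = grab("BQ_vcf"),
    MQ = grab("MQ"), MQRank = grab("MQRank")
  )
}

#' Parameters calculated from the read pileup
#'
#' From the per-read observations at one site:
#' \describe{
#'   \item{`Cov_total`}{all reads at the site, including OTHER-allele and
#'     ambiguous observations;}
#'   \item{`Cov_ref`}{reads supporting exactly the ref or the called alt;}
#'   \item{`AF_total`, `AF_ref`}{alt-supporting fraction over each
#'     denominator;}
#'   \item{`SB`}{strand bias as the absolute difference of forward-strand
#'     fractions between ALT and REF reads, in `[0, 1]`; `NA` when either
#'     class is empty;}
#'   \item{`VP`}{median over ALT reads of the distance to the nearer read
#'     end divided by read length, in `[0, 0.5]` — small values flag
#'     end-of-read artifacts;}
#'   \item{`BQ`}{mean ALT base quality (SNVs only).}
#' }
#'
#' @param column Pileup observations for one site (tibble with
#'   `allele_class`, `strand`, `base_quality`, `read_offset`,
#'   `read_length`).
#' @param variant_type `"SNV"` or `"INDEL"` (controls whether `BQ` is
#'   emitted).
#' @return One-row tibble; all-`NA` when the column is empty.
#' @export
pileup_features <- function(column, variant_type = "SNV") {
  empty <- tibble::tibble(
    Cov_total = NA_real_, Cov_ref = NA_real_, AF_total = NA_real_,
    AF_ref = NA_real_, SB = NA_real_, VP = NA_real_, BQ = NA_real_
  )
  if (is.null(column) || nrow(column) == 0) {
    if (variant_type == "INDEL") empty$BQ <- NA_real_
    return(empty)
  }
  is_alt <- column$allele_class == "ALT"
  is_ref <- column$allele_class == "REF"
  cov_total <- nrow(column)
  cov_ref <- sum(is_alt | is_ref)
  n_alt <- sum(is_alt)
  fwd_frac <- function(idx) {
    if (!any(idx)) return(NA_real_)
    mean(column$strand[idx] == "FWD")
  }
  sb <- {
    fa <- fwd_frac(is_alt); fr <- fwd_frac(is_ref)
    if (is.na(fa) || is.na(fr)) NA_real_ else abs(fa - fr)
  }
  vp <- if (n_alt > 0) {
    off <- column$read_offset[is_alt]
    len <- column$read_length[is_alt]
    stats::median(pmin(off, len - 1 - off) / len)
  } else NA_real_
  bq <- if (variant_type == "SNV" && n_alt > 0) {
    mean(column$base_quality[is_alt])
  } else NA_real_
  tibble::tibble(
    Cov_total = cov_total,
    Cov_ref = cov_ref,
    AF_total = n_alt / cov_total,
    AF_ref = if (cov_ref > 0) n_alt / cov_ref else NA_real_,
    SB = sb, VP = vp, BQ = bq
  )
}

#' Homopolymer context of an indel
#'
#' Length of the maximal reference run of the indel's first inserted/deleted
#' base that contains, or is immediately adjacent to, the position following
#' the VCF anchor base. Long homopolymers are the principal source of false
#' positive indel calls on pyrosequencing and semiconductor platforms, where
#' flow-space undercalls/overcalls shorten or lengthen the run.
#'
#' `HP_AT` equals `HP` when the run base is A or T (else 0); `HP_CG` when it
#' is C or G. Exactly one of the two is nonzero whenever `HP > 0`. When the
#' reference carries no matching base near the site (an insertion of a novel
#' base), the inserted base itself forms a run of length 1.
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param chrom,pos,ref,alt Left-aligned indel call (VCF anchor convention).
#' @param indicator If `TRUE`, report presence (0/1) instead of run length.
#' @return One-row tibble `HP`, `HP_AT`, `HP_CG`.
#' @export
homopolymer_features <- function(reference, chrom, pos, ref, alt,
                                 indicator = FALSE) {
  if (variant_type_of(ref, alt) != "INDEL") {
    rlang::abort("homopolymer context is an indel-only feature")
  }
  if (!chrom %in% names(reference)) {
    rlang::abort(paste0("contig absent from reference: ", chrom))
  }
  chromseq <- reference[[chrom]]
  enc <- indel_encoding(ref, alt)
  if (is.na(enc)) rlang::abort("complex substitution: no single inserted/deleted sequence")
  b <- substring(enc, 2, 2)  # first inserted/deleted base
  s <- pos + 1               # first reference position after the anchor
  L <- length(chromseq)
  if (pos < 1 || pos > L) rlang::abort("position outside reference")
  refchars <- strsplit(as.character(chromseq), "")[[1]]
  hp <- 0L
  for (w in max(1, s - 1):min(L, s + 1)) {
    if (refchars[w] == b) {
      lo <- w; hi <- w
      while (lo > 1 && refchars[lo - 1] == b) lo <- lo - 1
      while (hi < L && refchars[hi + 1] == b) hi <- hi + 1
      hp <- max(hp, hi - lo + 1L)
    }
  }
  if (hp == 0L) hp <- 1L  # the inserted/deleted base itself
  if (indicator) hp <- 1L
  tibble::tibble(
    HP = as.numeric(hp),
    HP_AT = if (b %in% c("A", "T")) as.numeric(hp) else 0,
    HP_CG = if (b %in% c("C", "G")) as.numeric(hp) else 0
  )
}

#' Indel-width statistics from the pileup
#'
#' Over the reads carrying an indel at the site: `VARW` is the number of
#' distinct observed indel alleles minus one (0 when support is
#' homogeneous), and `DevGT` the fraction of indel-bearing reads whose indel
#' differs from the called allele. Heterogeneous indel support is the
#' signature of homopolymer length-calling noise rather than a real variant.
#'
#' @param column Pileup observations (uses `observed_allele`: signed indel
#'   strings such as `"+A"` / `"-TG"` mark indel-bearing reads).
#' @param call_ref,call_alt The called alleles.
#' @return One-row tibble `VARW`, `DevGT`; no indel-bearing reads gives
#'   `VARW = 0`, `DevGT = NA`.
#' @export
indel_width_features <- function(column, call_ref, call_alt) {
  if (variant_type_of(call_ref, call_alt) != "INDEL") {
    rlang::abort("indel width is an indel-only feature")
  }
  obs <- if (is.null(column) || nrow(column) == 0) character(0) else column$observed_allele
  ind <- obs[grepl("^[+-]", obs)]
  if (length(ind) == 0) {
    return(tibble::tibble(VARW = 0, DevGT = NA_real_))
  }
  called <- indel_encoding(call_ref, call_alt)
  tibble::tibble(
    VARW = max(0L, length(unique(ind)) - 1L),
    DevGT = mean(ind != called)
  )
}

#' Build the per-call feature table
#'
#' Assembles one row per call with identity columns (`chrom`, `pos`, `ref`,
#' `alt`, `type`, `label`) followed by all 23 parameters in canonical order:
#' VCF-sourced values from the call annotations, calculated values from the
#' pileup, homopolymer and indel-width statistics for indels. Parameters not
#' applicable to a call's variant type are `NA`. Calls lacking pileup
#' evidence get their calculated features `NA` (counted in a warning).
#'
#' @param calls Calls tibble from [read_vcf()] (or compatible).
#' @param pileups Pileup tibble from [read_pileup_table()] /
#'   [pileup_from_bam()], or `NULL` to skip calculated features.
#' @param reference Named [Biostrings::DNAStringSet], or `NULL` to skip
#'   homopolymer features.
#' @return Feature table tibble.
#' @examples
#' \dontrun{
#' calls <- read_vcf("calls.vcf")
#' pile <- read_pileup_table("pileup.tsv")
#' features <- build_feature_table(calls, pile, reference)
#' }
#' @export
build_feature_table <- function(calls, pileups = NULL, reference = NULL) {
  calls <- tibble::as_tibble(calls)
  n <- nrow(calls)
  vtab <- vcf_features(calls)
  no_pileup <- 0L
  rows <- purrr::map(seq_len(n), function(i) {
    type <- calls$type[i]
    col <- NULL
    if (!is.null(pileups) && nrow(pileups) > 0) {
      col <- dplyr::filter(pileups,
        .data$chrom == calls$chrom[i], .data$pos == calls$pos[i])
      if (nrow(col) == 0) { col <- NULL; no_pileup <<- no_pileup + 1L }
    }
    ptab <- pileup_features(col, type)
    if (type == "INDEL") {
      hp <- if (!is.null(reference)) {
        homopolymer_features(reference, calls$chrom[i], calls$pos[i],
                             calls$ref[i], calls$alt[i])
      } else {
        tibble::tibble(HP = NA_real_, HP_AT = NA_real_, HP_CG = NA_real_)
      }
      iw <- indel_width_features(col, calls$ref[i], calls$alt[i])
      ptab$BQ <- NA_real_
    } else {
      hp <- tibble::tibble(HP = NA_real_, HP_AT = NA_real_, HP_CG = NA_real_)
      iw <- tibble::tibble(VARW = NA_real_, DevGT = NA_real_)
    }
    dplyr::bind_cols(ptab, hp, iw)
  })
  if (!is.null(pileups) && no_pileup > 0) {
    rlang::warn(sprintf("build_feature_table: %d call(s) without pileup evidence", no_pileup))
  }
  calc <- dplyr::bind_rows(rows)
  out <- tibble::tibble(
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    type = calls$type,
    label = if ("label" %in% names(calls)) calls$label else "UNLABELED"
  )
  out <- dplyr::bind_cols(out, vtab[, c("Q", "DP", "QD")], calc["Cov_total"],
    calc["Cov_ref"], vtab["Cov_vcf"], calc["AF_total"], calc["AF_ref"],
    vtab["AF_vcf"], calc["SB"], vtab[, c("SB_vcf", "SOR")], calc["VP"],
    vtab["VP_vcf"], calc["BQ"], vtab[, c("BQ_vcf", "MQ", "MQRank")],
    calc[, c("HP", "HP_AT", "HP_CG", "VARW", "DevGT")])
  out
}

#' Split a mixed feature table by variant type
#'
#' SNVs and indels are modeled separately throughout; this partitions a
#' mixed table into the two training inputs.
#'
#' @param tbl Feature table.
#' @return Named list `SNV`, `INDEL` of tibbles (possibly zero-row).
#' @export
split_by_type <- function(tbl) {
  list(
    SNV = dplyr::filter(tbl, .data$type == "SNV"),
    INDEL = dplyr::filter(tbl, .data$type == "INDEL")
  )
}

#' Write / read a feature table TSV
#'
#' Columns: identity (`chrom`, `pos`, `ref`, `alt`, `type`, `label`) then
#' the 23 parameters in canonical order; missing values written as `NA`.
#'
#' @param tbl Feature table.
#' @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), ref = readr::col_character(),
    alt = readr::col_character(), type = readr::col_character(),
    label = readr::col_character(), .default = readr::col_double()
  ))
}
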