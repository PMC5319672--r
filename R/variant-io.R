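#' Read a GATK-style VCF into a calls tibble
#'
#' Parses a VCF 4.x file with [vcfR::read.vcfR()] and returns one row per
#' (record, alt allele): multi-allelic records are decomposed, and records
#' with symbolic alts (`<DEL>`, breakends) are skipped with a warning count.
#' Annotations used by the parameter panel are pulled from QUAL, INFO and
#' the first sample's FORMAT fields; absent annotations are `NA`, never 0.
#' The SnpEff effect term is taken from the first `ANN`/`EFF` entry matching
#' the focal alt allele.
#'
#' @param path VCF file (plain or gzipped).
#' @param region Optional `"chrom:start-end"` restriction applied after
#'   parsing.
#' @param key_aliases Annotation key aliases, see [vcf_key_aliases()].
#' @return Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `type`,
#'   `effect`, `label`, `qual_str`, `info`, the numeric annotations `Q`,
#'   `DP`, `QD`, `SB_vcf`, `SOR`, `VP_vcf`, `BQ_vcf`, `MQ`, `MQRank`, and
#'   `AD_ref`, `AD_alt`.
#' @export
read_vcf <- function(path, region = NULL, key_aliases = vcf_key_aliases()) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read VCF: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) return(.empty_calls())

  info_str <- unname(fix[, "INFO"])
  ann_params <- c("DP", "QD", "SB_vcf", "SOR", "VP_vcf", "BQ_vcf", "MQ", "MQRank")
  ann_vals <- purrr::map(stats::setNames(ann_params, ann_params), function(param) {
    keys <- key_aliases[[param]]
    vals <- rep(NA_real_, n_rec)
    for (k in keys) {
      v <- suppressWarnings(as.numeric(.info_field(info_str, k)))
      vals[is.na(vals)] <- v[is.na(vals)]
    }
    vals
  })
  info_num <- function(param) ann_vals[[param]]
  ad_str <- tryCatch({
    gt <- vcfR::extract.gt(vcf, element = "AD")
    if (is.null(gt)) rep(NA_character_, n_rec) else unname(gt[, 1])
  }, error = function(e) rep(NA_character_, n_rec))

  ann_str <- .info_field(info_str, "ANN")
  eff_str <- .info_field(info_str, "EFF")

  rows <- list()
  skipped <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    ref <- unname(fix[i, "REF"])
    ad_parts <- if (!is.na(ad_str[i])) {
      suppressWarnings(as.numeric(strsplit(ad_str[i], ",", fixed = TRUE)[[1]]))
    } else NULL
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (grepl("[^ACGT]", alt)) { skipped <- skipped + 1L; next }  # symbolic alt / breakend / spanning-deletion
      id_i <- unname(fix[i, "ID"])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = unname(fix[i, "CHROM"]),
        pos = as.numeric(fix[i, "POS"]),
        id = ifelse(is.na(id_i) || id_i == ".", "", id_i),
        ref = ref, alt = alt,
        type = unname(variant_type_of(ref, alt)),
        effect = .match_effect(ann_str[i], eff_str[i], alt),
        label = "UNLABELED",
        qual_str = unname(fix[i, "QUAL"]),
        info = info_str[i],
        Q = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        DP = info_num("DP")[i], QD = info_num("QD")[i],
        SB_vcf = info_num("SB_vcf")[i], SOR = info_num("SOR")[i],
        VP_vcf = info_num("VP_vcf")[i], BQ_vcf = info_num("BQ_vcf")[i],
        MQ = info_num("MQ")[i], MQRank = info_num("MQRank")[i],
        AD_ref = if (!is.null(ad_parts) && length(ad_parts) > j) ad_parts[1] else NA_real_,
        AD_alt = if (!is.null(ad_parts) && length(ad_parts) > j) ad_parts[j + 1] else NA_real_
      )
    }
  }
  if (skipped > 0) {
    rlang::warn(sprintf("read_vcf: skipped %d record(s) with symbolic alt alleles", skipped))
  }
  out <- if (length(rows) == 0) .empty_calls() else dplyr::bind_rows(rows)
  if (!is.null(region) && nrow(out) > 0) {
    m <- stringr::str_match(region, "^([^:]+)(?::(\\d+)-(\\d+))?$")
    out <- dplyr::filter(out, .data$chrom == m[2])
    if (!is.na(m[3])) {
      out <- dplyr::filter(out, .data$pos >= as.numeric(m[3]), .data$pos <= as.numeric(m[4]))
    }
  }
  out
}

.empty_calls <- function() {
  tibble::tibble(
    chrom = character(), pos = numeric(), id = character(), ref = character(),
    alt = character(), type = character(), effect = character(),
    label = character(), qual_str = character(), info = character(),
    Q = numeric(), DP = numeric(), QD = numeric(), SB_vcf = numeric(),
    SOR = numeric(), VP_vcf = numeric(), BQ_vcf = numeric(), MQ = numeric(),
    MQRank = numeric(), AD_ref = numeric(), AD_alt = numeric()
  )
}

# scalar INFO key lookup over a character vector of INFO strings
.info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))
  m[, 2]
}

# first ANN entry whose allele field matches alt; EFF fallback
.match_effect <- function(ann, eff, alt) {
  if (!is.na(ann)) {
    for (entry in strsplit(ann, ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) >= 2 && f[1] == alt) return(strsplit(f[2], "&", fixed = TRUE)[[1]][1])
    }
    return("")
  }
  if (!is.na(eff)) {
    first <- strsplit(eff, ",", fixed = TRUE)[[1]][1]
    return(sub("\\(.*$", "", first))
  }
  ""
}

#' Attach truth labels to a call set
#'
#' Labels every call `"TP"` if present in the truth set (exact match on
#' normalized `chrom,pos,ref,alt`) and `"FP"` otherwise.
#'
#' @param calls Calls tibble.
#' @param truth Data frame of known true variants.
#' @return `calls` with its `label` column set.
#' @export
label_calls <- function(calls, truth) {
  calls$label <- ifelse(.call_key(calls) %in% .call_key(truth), "TP", "FP")
  calls
}

#' Read / write a truth-label TSV
#'
#' Columns `chrom`, `pos`, `ref`, `alt` and optionally `label`.
#'
#' @param path TSV path.
#' @param truth Data frame to write.
#' @return Tibble (read) or `path` invisibly (write).
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    ref = readr::col_character(), alt = readr::col_character(),
    .default = readr::col_character()
  ))
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' Read a pileup observation table
#'
#' The pileup table is the package's textual exchange format for read-level
#' evidence: one row per (site, read) with columns `chrom`, `pos`,
#' `read_id`, `allele_class` (`REF`/`ALT`/`OTHER`), `observed_allele` (a
#' base, or a signed indel string such as `"+A"`/`"-TG"`), `strand`
#' (`FWD`/`REV`), `base_quality` (Phred), `read_offset` (0-based site
#' offset from the read 5' end) and `read_length`.
#'
#' @param path TSV with the header above.
#' @return Tibble of observations; group by `(chrom, pos)` for per-site
#'   columns.
#' @export
read_pileup_table <- function(path) {
  needed <- c("chrom", "pos", "read_id", "allele_class", "observed_allele",
              "strand", "base_quality", "read_offset", "read_length")
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    read_id = readr::col_character(), allele_class = readr::col_character(),
    observed_allele = readr::col_character(), strand = readr::col_character(),
    base_quality = readr::col_double(), read_offset = readr::col_double(),
    read_length = readr::col_double()
  ))
  miss <- setdiff(needed, names(tbl))
  if (length(miss) > 0) {
    rlang::abort(paste0("pileup table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!(tbl$read_offset >= 0 & tbl$read_offset < tbl$read_length |
                   is.na(tbl$read_offset)))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "pileup table line %d: read_offset %g outside [0, read_length)",
      bad[1] + 1L, tbl$read_offset[bad[1]]))
  }
  bad_cls <- which(!tbl$allele_class %in% c("REF", "ALT", "OTHER"))
  if (length(bad_cls) > 0) {
    rlang::abort(sprintf("pileup table line %d: bad allele_class '%s'",
                         bad_cls[1] + 1L, tbl$allele_class[bad_cls[1]]))
  }
  tbl
}

#' @rdname read_pileup_table
#' @param tbl Pileup tibble.
#' @param path Output path.
#' @export
write_pileup_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Write a filtered VCF
#'
#' Emits the calls with the model decision folded into the FILTER column
#' (`PASS` for kept calls, `GLM_FAIL` for filtered ones) and the model
#' probability as an INFO key `GLMP`. Original CHROM/POS/ID/REF/ALT/QUAL
#' and INFO content are preserved.
#'
#' @param calls Calls tibble (from [read_vcf()], `info`/`qual_str` columns
#'   used when present).
#' @param classifications Tibble aligned with `calls` holding `p_hat` and
#'   `decision` (from [apply_model()]).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_filtered_vcf <- function(calls, classifications, path) {
  stopifnot(nrow(calls) == nrow(classifications))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=GLM_FAIL,Description=\"Predicted probability of being a true positive at or below the trained retention threshold\">",
    "##INFO=<ID=GLMP,Number=1,Type=Float,Description=\"Predicted probability of being a true positive under the trained logistic filter\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  n <- nrow(calls)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  qual <- if ("qual_str" %in% names(calls)) calls$qual_str else rep(".", n)
  info0 <- if ("info" %in% names(calls)) calls$info else rep(".", n)
  info0[is.na(info0) | info0 == ""] <- "."
  glmp <- sprintf("GLMP=%.6g", classifications$p_hat)
  info <- ifelse(info0 == ".", glmp, paste0(info0, ";", glmp))
  filt <- ifelse(classifications$decision == "KEEP", "PASS", "GLM_FAIL")
  id <- if ("id" %in% names(calls)) ifelse(calls$id == "", ".", calls$id) else "."
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                  calls$chrom, as.integer(calls$pos), id, calls$ref, calls$alt,
                  ifelse(is.na(qual), ".", qual), filt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a reference FASTA as a named DNA string set
#'
#' @param path FASTA file.
#' @return Named [Biostrings::DNAStringSet] (names truncated at the first
#'   whitespace, matching SAM/VCF contig naming).
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
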