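#' Build a mutually consistent miniature fixture
#'
#' From a declarative fixture specification — a reference sequence per
#' contig plus, per variant, the alleles, optional annotation values and a
#' per-read observation layout — writes four consistent files: a FASTA, a
#' pileup observation table, a VCF and a truth-label TSV. Feature extraction
#' on the emitted files reproduces the specification's intended values
#' exactly, which makes the fixture an oracle for the extraction code.
#'
#' @param spec List with elements:
#'   \describe{
#'     \item{`reference`}{named character vector, contig -> sequence;}
#'     \item{`variants`}{list of variant specs: `chrom`, `pos`, `ref`,
#'       `alt`, optional `id`, `label` (`"TP"`/`"FP"`), `effect`,
#'       `annotations` (named numeric, VCF INFO spellings such as
#'       `DP`, `QD`, `FS`, `SOR`, `ReadPosRankSum`, `BaseQRankSum`, `MQ`,
#'       `MQRankSum`), `qual`, `ad` (length-2 ref/alt depths), and `reads`
#'       — a data frame of observations with columns `n` (replication),
#'       `allele_class`, `observed_allele`, `strand`, `base_quality`,
#'       `read_offset`, `read_length`.}
#'   }
#' @param dir Output directory (created if needed).
#' @return List of paths: `fasta`, `pileup`, `vcf`, `truth`.
#' @export
build_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(is.character(spec$reference), !is.null(names(spec$reference)))
  for (v in spec$variants) {
    if (!v$chrom %in% names(spec$reference)) {
      rlang::abort(paste0("fixture variant on unknown contig: ", v$chrom))
    }
    L <- nchar(spec$reference[[v$chrom]])
    if (v$pos < 1 || v$pos + nchar(v$ref) - 1 > L) {
      rlang::abort(sprintf("fixture variant outside reference: %s:%d", v$chrom, v$pos))
    }
    refseq <- substring(spec$reference[[v$chrom]], v$pos, v$pos + nchar(v$ref) - 1)
    if (refseq != v$ref) {
      rlang::abort(sprintf("fixture ref allele mismatch at %s:%d ('%s' vs reference '%s')",
                           v$chrom, v$pos, v$ref, refseq))
    }
  }

  fasta <- file.path(dir, "reference.fa")
  writeLines(unlist(purrr::imap(as.list(spec$reference),
                                ~ c(paste0(">", .y), .x))), fasta)

  pileup_rows <- purrr::map(spec$variants, function(v) {
    if (is.null(v$reads)) return(NULL)
    reads <- tibble::as_tibble(v$reads)
    if (!"n" %in% names(reads)) reads$n <- 1L
    reads <- reads[rep(seq_len(nrow(reads)), reads$n), , drop = FALSE]
    tibble::tibble(
      chrom = v$chrom, pos = v$pos,
      read_id = sprintf("%s_%d_r%03d", v$chrom, v$pos, seq_len(nrow(reads))),
      allele_class = reads$allele_class,
      observed_allele = reads$observed_allele,
      strand = reads$strand,
      base_quality = reads$base_quality,
      read_offset = reads$read_offset,
      read_length = reads$read_length
    )
  })
  pileup <- file.path(dir, "pileup.tsv")
  write_pileup_table(dplyr::bind_rows(pileup_rows), pileup)

  vcf <- file.path(dir, "calls.vcf")
  .write_fixture_vcf(spec$variants, vcf)

  truth <- file.path(dir, "truth.tsv")
  tp <- purrr::keep(spec$variants, ~ identical(.x$label, "TP"))
  write_truth(tibble::tibble(
    chrom = purrr::map_chr(tp, "chrom"),
    pos = purrr::map_dbl(tp, "pos"),
    ref = purrr::map_chr(tp, "ref"),
    alt = purrr::map_chr(tp, "alt")
  ), truth)

  list(fasta = fasta, pileup = pileup, vcf = vcf, truth = truth)
}

.write_fixture_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio strand bias\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Rank sum of alt read position\">",
    "##INFO=<ID=BaseQRankSum,Number=1,Type=Float,Description=\"Rank sum of alt base quality\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Rank sum of alt mapping quality\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  body <- purrr::map_chr(variants, function(v) {
    info_parts <- character()
    if (!is.null(v$annotations)) {
      info_parts <- sprintf("%s=%s", names(v$annotations),
                            purrr::map_chr(v$annotations, ~ format(.x, scientific = FALSE)))
    }
    if (!is.null(v$effect) && nzchar(v$effect)) {
      info_parts <- c(info_parts, sprintf("ANN=%s|%s|MODIFIER|GENE", v$alt, v$effect))
    }
    info <- if (length(info_parts) == 0) "." else paste(info_parts, collapse = ";")
    fmt <- "GT:AD"
    ad <- if (!is.null(v$ad)) paste(v$ad, collapse = ",") else "."
    sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\t%s\t%s\t%s",
            v$chrom, as.integer(v$pos), v$id %||% ".", v$ref, v$alt,
            if (is.null(v$qual)) "." else format(v$qual), info, fmt,
            paste0("0/1:", ad))
  })
  writeLines(c(header, body), path)
}
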