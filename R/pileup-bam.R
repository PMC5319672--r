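#' Build pileup observations from a BAM file
#'
#' For each call, extracts the reads overlapping the VCF position from a
#' coordinate-sorted, indexed BAM and classifies each read's support:
#' `ALT` for exact support of the called alt allele, `REF` for exact
#' reference support across the affected bases, `OTHER` otherwise (a
#' mismatching base, a different indel allele, or a deletion spanning an
#' SNV site). Duplicate-marked, secondary, supplementary and unmapped
#' alignments are excluded.
#'
#' For an SNV the observed allele is the read base at the site; for an
#' indel call the read's CIGAR is inspected for an insertion/deletion
#' anchored immediately after the VCF position, and the observation is
#' recorded in signed-indel notation (`"+A"`, `"-TG"`). The read offset is
#' the 0-based query position of the site (the anchor base for indels).
#'
#' @param bam_path Indexed BAM file.
#' @param fasta_path Reference FASTA (indexed or small enough to load).
#' @param calls Calls tibble (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @return Pileup tibble in the [read_pileup_table()] layout.
#' @export
pileup_from_bam <- function(bam_path, fasta_path, calls) {
  if (!file.exists(bam_path)) rlang::abort(paste0("cannot read BAM: ", bam_path))
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    rlang::abort(paste0("BAM index missing for: ", bam_path))
  }
  reference <- read_reference(fasta_path)
  bad_contig <- setdiff(unique(calls$chrom), names(reference))
  if (length(bad_contig) > 0) {
    rlang::abort(paste0("contig absent from FASTA: ", paste(bad_contig, collapse = ", ")))
  }
  out <- list()
  for (i in seq_len(nrow(calls))) {
    out[[i]] <- .pileup_one_site(bam_path, reference,
                                 calls$chrom[i], calls$pos[i],
                                 calls$ref[i], calls$alt[i])
  }
  dplyr::bind_rows(out)
}

.pileup_one_site <- function(bam_path, reference, chrom, pos, ref, alt) {
  span <- max(nchar(ref), 1)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos + span - 1))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isDuplicate = FALSE, isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(which = which, flag = flag,
                                   what = c("qname", "flag", "seq", "qual"))
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param)
  n <- length(aln)
  empty <- tibble::tibble(
    chrom = character(), pos = numeric(), read_id = character(),
    allele_class = character(), observed_allele = character(),
    strand = character(), base_quality = numeric(), read_offset = numeric(),
    read_length = numeric()
  )
  if (n == 0) return(empty)
  mc <- S4Vectors::mcols(aln)
  is_snv <- variant_type_of(ref, alt) == "SNV"
  called_enc <- if (!is_snv) indel_encoding(ref, alt) else NA_character_
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    obs <- .classify_read(
      cigar = GenomicAlignments::cigar(aln)[k],
      read_start = GenomicAlignments::start(aln)[k],
      seq = as.character(mc$seq[k]),
      qual = as.character(mc$qual[k]),
      pos = pos, ref = ref, alt = alt, is_snv = is_snv,
      called_enc = called_enc, reference = reference, chrom = chrom
    )
    if (is.null(obs)) next
    rows[[k]] <- tibble::tibble(
      chrom = chrom, pos = pos, read_id = mc$qname[k],
      allele_class = obs$class, observed_allele = obs$allele,
      strand = ifelse(bitwAnd(mc$flag[k], 16L) > 0, "REV", "FWD"),
      base_quality = obs$bq, read_offset = obs$offset,
      read_length = nchar(as.character(mc$seq[k]))
    )
  }
  kept <- purrr::compact(rows)
  if (length(kept) == 0) empty else dplyr::bind_rows(kept)
}

# Walk the CIGAR to find the query offset of reference position `pos` and
# any indel op anchored immediately after it; classify the read's support.
.classify_read <- function(cigar, read_start, seq, qual, pos, ref, alt,
                           is_snv, called_enc, reference, chrom) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  rpos <- read_start   # next reference position to consume
  qpos <- 1L           # next query position to consume
  anchor_q <- NA_integer_  # query offset of `pos`
  indel_after <- NULL      # signed indel op anchored right after `pos`
  deleted_at <- NULL       # deletion covering `pos` itself (SNV -> OTHER)
  for (i in seq_along(ops)) {
    op <- ops[i]; ln <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (pos >= rpos && pos < rpos + ln) anchor_q <- qpos + (pos - rpos)
      rpos <- rpos + ln; qpos <- qpos + ln
    } else if (op == "I") {
      if (rpos == pos + 1L) {
        indel_after <- paste0("+", substring(seq, qpos, qpos + ln - 1L))
      }
      qpos <- qpos + ln
    } else if (op == "D" || op == "N") {
      if (rpos == pos + 1L) {
        del <- as.character(Biostrings::subseq(reference[[chrom]], rpos, rpos + ln - 1L))
        indel_after <- paste0("-", del)
      }
      if (pos >= rpos && pos < rpos + ln) deleted_at <- TRUE
      rpos <- rpos + ln
    } else if (op == "S") {
      qpos <- qpos + ln
    } else if (op %in% c("H", "P")) {
      # consume nothing
    }
  }
  if (is.na(anchor_q)) {
    if (is_snv && isTRUE(deleted_at)) {
      return(list(class = "OTHER", allele = "*", bq = NA_real_, offset = 0))
    }
    return(NULL)  # site not covered by aligned bases
  }
  bq <- utf8ToInt(substring(qual, anchor_q, anchor_q)) - 33
  offset0 <- anchor_q - 1L
  if (is_snv) {
    base <- substring(seq, anchor_q, anchor_q)
    cls <- if (base == alt) "ALT" else if (base == ref) "REF" else "OTHER"
    return(list(class = cls, allele = base, bq = bq, offset = offset0))
  }
  # indel call
  if (!is.null(indel_after)) {
    cls <- if (!is.na(called_enc) && indel_after == called_enc) "ALT" else "OTHER"
    return(list(class = cls, allele = indel_after, bq = bq, offset = offset0))
  }
  # no indel at the anchor: exact reference support requires the read to
  # match the reference across the call's ref span
  span_end <- pos + nchar(ref) - 1L
  refseq <- as.character(Biostrings::subseq(reference[[chrom]], pos, span_end))
  readseq <- substring(seq, anchor_q, anchor_q + nchar(ref) - 1L)
  cls <- if (identical(readseq, refseq)) "REF" else "OTHER"
  list(class = cls, allele = substring(seq, anchor_q, anchor_q), bq = bq,
       offset = offset0)
}
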