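vcf_lines <- function(body) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=BaseQRankSum,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    body)
}

test_that("read_vcf maps fields, decomposes multi-allelics, skips symbolic alts", {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    paste("chr1", 100, "rs123", "A", "G", 354, ".",
          "DP=900;QD=12.5;FS=1.2;SOR=0.7;ReadPosRankSum=0.4;MQ=59.1;ANN=G|missense_variant|MOD|X",
          "GT:AD", "0/1:60,40", sep = "\t"),
    paste("chr1", 200, ".", "C", "A,T", 88, ".", "DP=120",
          "GT:AD", "1/2:10,60,50", sep = "\t"),
    paste("chr1", 300, ".", "G", "<DEL>", 50, ".", "DP=80",
          "GT:AD", "0/1:40,40", sep = "\t"),
    paste("chr1", 400, ".", "T", "C", 77, ".", "QD=3.1",  # no BaseQRankSum
          "GT:AD", "0/1:30,30", sep = "\t")
  )), path)
  expect_warning(calls <- read_vcf(path), "symbolic")
  expect_identical(nrow(calls), 4L)  # 1 + 2 + 0 + 1

  snv <- calls[1, ]
  expect_identical(snv$id, "rs123")
  expect_equal(snv$Q, 354); expect_equal(snv$DP, 900)
  expect_equal(snv$SB_vcf, 1.2)      # FS under its panel name
  expect_equal(snv$VP_vcf, 0.4)
  expect_identical(snv$effect, "missense_variant")
  expect_identical(snv$type, "SNV")
  expect_identical(snv$label, "UNLABELED")

  # decomposition: same position, per-alt AD slices, allele count conserved
  multi <- calls[calls$pos == 200, ]
  expect_identical(nrow(multi), 2L)
  expect_identical(multi$alt, c("A", "T"))
  expect_equal(multi$AD_alt, c(60, 50))
  expect_equal(multi$AD_ref, c(10, 10))

  # absent annotation is missing, not zero
  expect_true(is.na(calls$BQ_vcf[calls$pos == 400]))
  expect_error(read_vcf(tempfile()), "cannot read")
})

test_that("read_vcf region restriction filters by coordinates", {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    paste("chr1", 100, ".", "A", "G", 10, ".", "DP=50", "GT:AD", "0/1:5,5", sep = "\t"),
    paste("chr2", 100, ".", "A", "G", 10, ".", "DP=50", "GT:AD", "0/1:5,5", sep = "\t"),
    paste("chr1", 900, ".", "A", "G", 10, ".", "DP=50", "GT:AD", "0/1:5,5", sep = "\t")
  )), path)
  expect_identical(nrow(read_vcf(path, region = "chr1")), 2L)
  expect_identical(nrow(read_vcf(path, region = "chr1:50-500")), 1L)
})

test_that("model files round-trip exactly, including intercept-only models", {
  m <- amplicon_models()$snv_iontorrent
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$threshold, m$threshold)
  expect_identical(back$variant_type, m$variant_type)

  m0 <- glmvc_model("SNV", "p", intercept = 1.234567890123,
                    coefficients = NULL, threshold = 0.5)
  write_model(m0, path)
  back0 <- read_model(path)
  expect_identical(back0$intercept, m0$intercept)
  expect_identical(length(back0$coefficients), 0L)

  # unknown parameter name in file is rejected with the valid names listed
  bad <- path
  writeLines(sub("VP_vcf", "FOO", readLines(path)), bad)
  json <- jsonlite::read_json(path)
  json$coefficients <- list(FOO = 1)
  jsonlite::write_json(json, bad, auto_unbox = TRUE)
  expect_error(read_model(bad), "FOO")
})

test_that("filtered VCF carries PASS/GLM_FAIL and the model probability", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200), id = c("rs1", ""),
    ref = "A", alt = "G", qual_str = c("354", "10"),
    info = c("DP=900", "DP=30")
  )
  cls <- tibble::tibble(p_hat = c(0.8, 0.01), decision = c("KEEP", "FILTER"))
  path <- tempfile(fileext = ".vcf")
  write_filtered_vcf(calls, cls, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_match(body[1], "PASS"); expect_match(body[1], "GLMP=0.8")
  expect_match(body[2], "GLM_FAIL"); expect_match(body[2], "GLMP=0.01")
  # untouched identity fields survive re-parsing byte-identically
  back <- read_vcf(path)
  expect_identical(back$chrom, calls$chrom)
  expect_identical(back$pos, calls$pos)
  expect_identical(back$ref, calls$ref)
  expect_identical(back$alt, calls$alt)
  # empty call set: header-only file
  write_filtered_vcf(calls[0, ], cls[0, ], path)
  expect_true(all(startsWith(readLines(path), "#")))
})

test_that("pileup table reader enforces schema and invariants", {
  path <- tempfile(fileext = ".tsv")
  good <- tibble::tibble(
    chrom = "c", pos = 100, read_id = sprintf("r%d", 1:4),
    allele_class = c("REF", "REF", "ALT", "ALT"),
    observed_allele = c("A", "A", "G", "G"), strand = "FWD",
    base_quality = 30, read_offset = c(10, 20, 30, 40), read_length = 100
  )
  write_pileup_table(good, path)
  back <- read_pileup_table(path)
  expect_identical(nrow(back), 4L)
  # empty file with header
  write_pileup_table(good[0, ], path)
  expect_identical(nrow(read_pileup_table(path)), 0L)
  # invariant violation names the line
  bad <- good; bad$read_offset[2] <- 100
  write_pileup_table(bad, path)
  expect_error(read_pileup_table(path), "line 3")
})

test_that("pileup_from_bam classifies SNV support from a constructed alignment", {
  contig <- paste(rep("ACGT", 25), collapse = "")   # 100 bp
  ref_at_50 <- substring(contig, 50, 50)            # "T"
  fasta <- tempfile(fileext = ".fa")
  writeLines(c(">ctg", contig), fasta)
  alt_seq <- paste0(substring(contig, 41, 49), "A", substring(contig, 51, 60))
  ref_seq <- substring(contig, 41, 60)
  sam <- c(
    sam_header(c(ctg = contig)),
    # 10 ref reads (6 FWD), 10 alt reads (2 FWD)
    sapply(1:6,  function(i) sam_line(paste0("ref_f", i), 0,  "ctg", 41, "20M", ref_seq)),
    sapply(1:4,  function(i) sam_line(paste0("ref_r", i), 16, "ctg", 41, "20M", ref_seq)),
    sapply(1:2,  function(i) sam_line(paste0("alt_f", i), 0,  "ctg", 41, "20M", alt_seq)),
    sapply(1:8,  function(i) sam_line(paste0("alt_r", i), 16, "ctg", 41, "20M", alt_seq)),
    # deletion spanning the site: OTHER for an SNV call
    sam_line("del_span", 0, "ctg", 41, "5M10D15M", substring(contig, 41, 60)),
    # duplicate-marked alt read: excluded
    sam_line("dup", 1024, "ctg", 41, "20M", alt_seq)
  )
  bam <- sam_to_bam(sam)
  calls <- tibble::tibble(chrom = "ctg", pos = 50, ref = ref_at_50, alt = "A",
                          type = "SNV")
  pile <- pileup_from_bam(bam, fasta, calls)
  expect_identical(sum(pile$allele_class == "REF"), 10L)
  expect_identical(sum(pile$allele_class == "ALT"), 10L)
  expect_identical(sum(pile$allele_class == "OTHER"), 1L)
  expect_false("dup" %in% pile$read_id)
  expect_identical(sum(pile$strand == "FWD" & pile$allele_class == "ALT"), 2L)
  # offsets: site at ref 50, read start 41 -> query offset 9 (0-based)
  expect_true(all(pile$read_offset[pile$allele_class != "OTHER"] == 9))
  expect_true(all(pile$read_length[pile$allele_class != "OTHER"] == 20))
  # feature agreement with the layout
  f <- pileup_features(pile, "SNV")
  expect_equal(f$Cov_total, 21)
  expect_equal(f$Cov_ref, 20)
  expect_equal(f$SB, abs(0.2 - 0.6))
  # site with no coverage
  none <- pileup_from_bam(bam, fasta,
    tibble::tibble(chrom = "ctg", pos = 99, ref = substring(contig, 99, 99),
                   alt = "A", type = "SNV"))
  expect_identical(nrow(none), 0L)
  # missing contig
  expect_error(pileup_from_bam(bam, fasta,
    tibble::tibble(chrom = "nope", pos = 1, ref = "A", alt = "G", type = "SNV")),
    "contig")
})

test_that("pileup_from_bam distinguishes matching, deviating and absent indels", {
  contig <- "ACGAACGGTTTTAGCACGTACGTACGTACG"  # TTTT run at 10-13
  fasta <- tempfile(fileext = ".fa")
  writeLines(c(">ctg", contig), fasta)
  # call: deletion of one T anchored at pos 9 (ref "GT" -> "G")
  ref_read <- substring(contig, 1, 20)
  del1 <- paste0(substring(contig, 1, 9), substring(contig, 11, 21))   # -T
  del2 <- paste0(substring(contig, 1, 9), substring(contig, 12, 22))   # -TT
  sam <- c(
    sam_header(c(ctg = contig)),
    sapply(1:3, function(i) sam_line(paste0("ref", i), 0, "ctg", 1, "20M", ref_read)),
    sapply(1:2, function(i) sam_line(paste0("d1_", i), 0, "ctg", 1, "9M1D11M", del1)),
    sam_line("d2", 0, "ctg", 1, "9M2D11M", del2)
  )
  bam <- sam_to_bam(sam)
  calls <- tibble::tibble(chrom = "ctg", pos = 9, ref = "GT", alt = "G",
                          type = "INDEL")
  pile <- pileup_from_bam(bam, fasta, calls)
  expect_identical(sum(pile$allele_class == "ALT"), 2L)
  expect_identical(sum(pile$allele_class == "REF"), 3L)
  expect_identical(sum(pile$allele_class == "OTHER"), 1L)
  expect_setequal(pile$observed_allele[pile$allele_class == "ALT"], "-T")
  expect_identical(pile$observed_allele[pile$allele_class == "OTHER"], "-TT")
  w <- indel_width_features(pile, "GT", "G")
  expect_equal(w$VARW, 1)
  expect_equal(w$DevGT, 1 / 3)
})

test_that("normalization left-aligns and trims redundant allele padding", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGCATTTTTACGT"))
  # same deletion written three ways
  a <- tibble::tibble(chrom = "chr1", pos = 7, ref = "TT", alt = "T")
  b <- tibble::tibble(chrom = "chr1", pos = 4, ref = "AT", alt = "A")
  c3 <- tibble::tibble(chrom = "chr1", pos = 6, ref = "TTT", alt = "TT")
  na <- normalize_calls(a, ref); nb <- normalize_calls(b, ref)
  nc <- normalize_calls(c3, ref)
  expect_identical(na[c("pos", "ref", "alt")], nb[c("pos", "ref", "alt")])
  expect_identical(na[c("pos", "ref", "alt")], nc[c("pos", "ref", "alt")])
  # SNV with padded representation
  s <- normalize_calls(tibble::tibble(chrom = "chr1", pos = 3, ref = "CAT",
                                      alt = "CGT"))
  expect_identical(s$pos, 4); expect_identical(s$ref, "A"); expect_identical(s$alt, "G")
  # truth matching uses the normalized identity
  calls <- normalize_calls(a, ref)
  truth <- normalize_calls(b, ref)
  expect_identical(score_calls(calls, truth)$tp, 1L)
})

test_that("labeling against a truth set marks TP and FP", {
  calls <- tibble::tibble(chrom = "c", pos = 1:3, ref = "A", alt = "G")
  truth <- tibble::tibble(chrom = "c", pos = 2, ref = "A", alt = "G")
  lab <- label_calls(calls, truth)
  expect_identical(lab$label, c("FP", "TP", "FP"))
})
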