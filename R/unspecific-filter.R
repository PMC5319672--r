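#' Unspecific filtration policy
#'
#' The pre-model filter removes call categories that are uninformative for
#' somatic screening regardless of platform: variants with non-coding or
#' silent effects, sites covered by fewer than `min_coverage` reads, and
#' known germline polymorphisms. Polymorphism exclusion is list-driven
#' (dbSNP identifiers and/or explicit sites) so the package stays
#' self-contained; supply whatever exclusion list fits the assay.
#'
#' @param excluded_effects SnpEff/Sequence-Ontology effect terms to drop.
#' @param min_coverage Minimum read depth (default 20).
#' @param polymorphism_ids Character vector of rs identifiers.
#' @param polymorphism_sites Data frame `chrom`, `pos`, `ref`, `alt` of
#'   known polymorphic sites, or `NULL`.
#' @param effect_aliases Named list mapping alias terms to canonical ones
#'   (annotator versions differ: "silent" and "synonymous_variant" name the
#'   same concept).
#' @return Object of class `glmvc_policy`.
#' @export
filter_policy <- function(excluded_effects = c("intron_variant",
                                               "synonymous_variant",
                                               "3_prime_UTR_variant",
                                               "5_prime_UTR_variant"),
                          min_coverage = 20,
                          polymorphism_ids = character(),
                          polymorphism_sites = NULL,
                          effect_aliases = list(
                            SILENT = "synonymous_variant",
                            silent = "synonymous_variant",
                            INTRON = "intron_variant",
                            UTR_3_PRIME = "3_prime_UTR_variant",
                            UTR_5_PRIME = "5_prime_UTR_variant"
                          )) {
  stopifnot(min_coverage >= 0)
  structure(
    list(
      excluded_effects = excluded_effects,
      min_coverage = min_coverage,
      polymorphism_ids = polymorphism_ids,
      polymorphism_sites = polymorphism_sites,
      effect_aliases = effect_aliases
    ),
    class = "glmvc_policy"
  )
}

#' Read a filtration policy from a YAML/JSON-style file
#'
#' Structured-text policy with keys `excluded_effects`, `min_coverage`,
#' `polymorphism_list` (path to a TSV with columns `id` and/or
#' `chrom,pos,ref,alt`).
#'
#' @param path JSON policy file.
#' @return A `glmvc_policy`.
#' @export
read_policy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- character(); sites <- NULL
  if (!is.null(obj$polymorphism_list)) {
    ppath <- obj$polymorphism_list
    if (!file.exists(ppath)) {
      ppath <- file.path(dirname(path), obj$polymorphism_list)
    }
    ptab <- readr::read_tsv(ppath, col_types = readr::cols())
    if ("id" %in% names(ptab)) ids <- stats::na.omit(ptab$id)
    if (all(c("chrom", "pos", "ref", "alt") %in% names(ptab))) {
      sites <- ptab[, c("chrom", "pos", "ref", "alt")]
    }
  }
  filter_policy(
    excluded_effects = obj$excluded_effects %||% c("intron_variant",
      "synonymous_variant", "3_prime_UTR_variant", "5_prime_UTR_variant"),
    min_coverage = obj$min_coverage %||% 20,
    polymorphism_ids = ids,
    polymorphism_sites = sites
  )
}

#' Apply unspecific filtration to annotated calls
#'
#' Removes calls whose (alias-canonicalized) effect is excluded, whose depth
#' is below the policy minimum, or which match the polymorphism exclusion
#' lists by identifier or site. Depth uses INFO `DP`, falling back to the
#' AD-derived `Cov_vcf` when `DP` is absent; a call with neither is treated
#' as failing the coverage rule. Each removed call is tagged with its first
#' matching reason, in the order effect, coverage, polymorphism-id,
#' polymorphism-site; the retained and removed sets partition the input.
#'
#' @param calls Calls tibble (columns `effect`, `DP`, and/or `AD_ref` +
#'   `AD_alt`, `id`).
#' @param policy A [filter_policy()].
#' @return List: `retained` (tibble), `removed` (tibble with a `reason`
#'   column).
#' @examples
#' calls <- tibble::tibble(
#'   chrom = "chr1", pos = 1:3, ref = "A", alt = "G", type = "SNV",
#'   id = c("", "rs1", ""), effect = c("intron_variant", "", ""),
#'   DP = c(100, 100, 10))
#' unspecific_filter(calls, filter_policy(polymorphism_ids = "rs1"))
#' @export
unspecific_filter <- function(calls, policy = filter_policy()) {
  calls <- tibble::as_tibble(calls)
  eff <- if ("effect" %in% names(calls)) calls$effect else rep("", nrow(calls))
  eff <- ifelse(eff %in% names(policy$effect_aliases),
                unlist(policy$effect_aliases)[eff], eff)
  dp <- if ("DP" %in% names(calls)) calls$DP else rep(NA_real_, nrow(calls))
  cov_vcf <- if (all(c("AD_ref", "AD_alt") %in% names(calls))) {
    calls$AD_ref + calls$AD_alt
  } else rep(NA_real_, nrow(calls))
  depth <- ifelse(is.na(dp), cov_vcf, dp)
  id <- if ("id" %in% names(calls)) calls$id else rep("", nrow(calls))
  site_key <- .call_key(calls)
  poly_keys <- if (!is.null(policy$polymorphism_sites)) {
    .call_key(policy$polymorphism_sites)
  } else character()

  reason <- rep(NA_character_, nrow(calls))
  hit <- function(cond, tag) {
    pick <- is.na(reason) & cond
    reason[pick] <<- tag
  }
  hit(!is.na(eff) & eff %in% policy$excluded_effects, "effect")
  hit(is.na(depth) | depth < policy$min_coverage, "coverage")
  hit(!is.na(id) & id %in% policy$polymorphism_ids, "polymorphism_id")
  hit(site_key %in% poly_keys, "polymorphism_site")

  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(retained = calls[is.na(reason), , drop = FALSE], removed = removed)
}

#' Fixed-threshold QD/VARW comparator filter
#'
#' The straightforward indel filter used as a comparator baseline: retain a
#' call iff `QD >= 2.5` and `VARW == 0`. Fixed one-size-fits-all thresholds
#' of this kind transfer poorly across assays — on some training sets the
#' rule removes a majority of true positives — which is the motivation for
#' the calibrated GLM approach.
#'
#' @param features Indel feature table with `QD` and `VARW` columns.
#' @return `features` with logical `retained` and `flagged` (missing QD or
#'   VARW: retained but flagged) columns.
#' @export
qd_varw_filter <- function(features) {
  features <- tibble::as_tibble(features)
  qd <- features$QD; varw <- features$VARW
  flagged <- is.na(qd) | is.na(varw)
  retained <- ifelse(flagged, TRUE, qd >= 2.5 & varw == 0)
  features$retained <- retained
  features$flagged <- flagged
  features
}
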