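#' Reference filtration models from an MDS amplicon-panel benchmark
#'
#' Six ready-to-apply logistic filters — one per platform (Roche 454,
#' Ion Torrent PGM, Illumina NextSeq) and variant type — with the linear
#' predictors and sensitivity-preserving thresholds obtained on a
#' myelodysplastic-syndrome amplicon sequencing benchmark of 19 recurrently
#' mutated genes. They illustrate how platform error profiles diverge: the
#' 454 and Ion Torrent indel filters lean on homopolymer length with large
#' negative weights, while the Illumina indel filter instead rewards
#' AD-derived coverage and A/T-homopolymer context (positive weight).
#'
#' These models are applicable as-is via [apply_model()] to feature tables
#' from comparable assays, and serve as worked examples of the
#' `glmvc_model` container.
#'
#' @return Named list of [glmvc_model] objects:
#'   `snv_454`, `snv_iontorrent`, `snv_illumina`,
#'   `indel_454`, `indel_iontorrent`, `indel_illumina`.
#' @examples
#' m <- amplicon_models()$snv_iontorrent
#' apply_model(m, tibble::tibble(VP_vcf = c(0, 2)))[, c("p_hat", "decision")]
#' @export
amplicon_models <- function() {
  list(
    snv_454 = glmvc_model(
      "SNV", "454", intercept = -7.08,
      coefficients = c(Q = 0.02, VP_vcf = 6.70),
      aic = 10.75, threshold = 0.28
    ),
    snv_iontorrent = glmvc_model(
      "SNV", "IonTorrent", intercept = -4.58,
      coefficients = c(VP_vcf = 20.62),
      aic = 9.09, threshold = 0.04
    ),
    snv_illumina = glmvc_model(
      "SNV", "Illumina", intercept = 9.09,
      coefficients = c(Q = 0.01, Cov_total = -0.02),
      aic = 12.01, threshold = 0.15
    ),
    indel_454 = glmvc_model(
      "INDEL", "454", intercept = 27.06,
      coefficients = c(HP = -31.02, QD = 0.58, BQ_vcf = 16.69),
      aic = 15.45, threshold = 0.08
    ),
    indel_iontorrent = glmvc_model(
      "INDEL", "IonTorrent", intercept = -64.76,
      coefficients = c(SOR = -4.02, HP = -2.93, MQ = 0.81, Cov_total = 0.01),
      aic = 21.95, threshold = 0.07
    ),
    indel_illumina = glmvc_model(
      "INDEL", "Illumina", intercept = -12.09,
      coefficients = c(Cov_vcf = 0.11, Q = -0.01, HP_AT = 2.51),
      aic = 17.51, threshold = 0.10
    )
  )
}
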