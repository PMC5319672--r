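#' Platform error-structure profiles for synthetic feature tables
#'
#' A profile fixes, for one platform and variant type, the class sizes and
#' the class-conditional generating distribution of every applicable
#' parameter. The built-in profiles emulate the *direction* of the error
#' structure seen on amplicon panels — false positive indels concentrated at
#' long homopolymers on pyrosequencing/semiconductor platforms, elevated
#' strand-bias odds ratios among artifacts, depressed quality-by-depth —
#' with invented numeric settings; the class counts default to the training
#' compositions of the benchmarking study the package is modeled on (e.g.
#' 7 TP vs 644 FP indels for the semiconductor profile).
#'
#' To keep the two classes overlapping (so that fitted logistic models
#' converge rather than quasi-separate), a small contaminant fraction (2%)
#' of each FP class is drawn from the TP distributions.
#'
#' @param name One of `"454-snv"`, `"iontorrent-snv"`, `"illumina-snv"`,
#'   `"454-indel"`, `"iontorrent-indel"`, `"illumina-indel"`.
#' @param n_tp,n_fp Class sizes; defaults per profile.
#' @param seed Integer seed; every draw is deterministic given it.
#' @param contaminant Fraction of FP rows drawn from the TP distributions
#'   (default 0.02).
#' @return Object of class `glmvc_profile`.
#' @export
platform_profile <- function(name, n_tp = NULL, n_fp = NULL, seed = 1L,
                             contaminant = 0.02) {
  spec <- .profile_specs[[name]]
  if (is.null(spec)) {
    rlang::abort(paste0("unknown profile '", name, "'; available: ",
                        paste(names(.profile_specs), collapse = ", ")))
  }
  structure(
    list(
      name = name,
      variant_type = spec$variant_type,
      n_tp = n_tp %||% spec$n_tp,
      n_fp = n_fp %||% spec$n_fp,
      tp = spec$tp, fp = spec$fp,
      contaminant = contaminant,
      seed = as.integer(seed)
    ),
    class = "glmvc_profile"
  )
}

# distribution atoms: list(dist = "norm"/"unif"/"gamma"/"pois"/"beta"/"const",
# ... family parameters ..., shift, min, max)
.draw <- function(n, d) {
  x <- switch(d$dist,
    norm  = stats::rnorm(n, d$mean, d$sd),
    unif  = stats::runif(n, d$min, d$max),
    gamma = stats::rgamma(n, shape = d$shape, rate = d$rate),
    pois  = stats::rpois(n, d$lambda),
    beta  = stats::rbeta(n, d$a, d$b),
    const = rep(d$value, n),
    rlang::abort(paste0("unknown distribution: ", d$dist))
  )
  if (!is.null(d$shift)) x <- x + d$shift
  if (!is.null(d$lo)) x <- pmax(x, d$lo)
  if (!is.null(d$hi)) x <- pmin(x, d$hi)
  x
}

# shared uninformative baselines; informative parameters overridden per class
.base_snv <- list(
  Q = list(dist = "gamma", shape = 4, rate = 0.02, lo = 30),
  DP = list(dist = "gamma", shape = 6, rate = 0.01, lo = 25),
  QD = list(dist = "norm", mean = 12, sd = 4, lo = 0.5),
  Cov_total = list(dist = "gamma", shape = 6, rate = 0.01, lo = 25),
  Cov_ref = list(dist = "gamma", shape = 6, rate = 0.011, lo = 22),
  Cov_vcf = list(dist = "gamma", shape = 6, rate = 0.011, lo = 22),
  AF_total = list(dist = "beta", a = 4, b = 6),
  AF_ref = list(dist = "beta", a = 4, b = 6),
  AF_vcf = list(dist = "beta", a = 4, b = 6),
  SB = list(dist = "beta", a = 1.5, b = 6),
  SB_vcf = list(dist = "gamma", shape = 1.2, rate = 0.4),
  SOR = list(dist = "gamma", shape = 3, rate = 3),
  VP = list(dist = "beta", a = 3, b = 3, hi = 0.5),
  VP_vcf = list(dist = "norm", mean = 0, sd = 1),
  BQ = list(dist = "norm", mean = 30, sd = 3, lo = 10),
  BQ_vcf = list(dist = "norm", mean = 0, sd = 1),
  MQ = list(dist = "norm", mean = 58, sd = 2, hi = 60),
  MQRank = list(dist = "norm", mean = 0, sd = 1)
)
.base_indel <- c(
  .base_snv[setdiff(names(.base_snv), "BQ")],
  list(
    HP = list(dist = "pois", lambda = 0.8, shift = 1),
    VARW = list(dist = "pois", lambda = 0.1),
    DevGT = list(dist = "beta", a = 1, b = 12)
  )
)

.mk_profile <- function(variant_type, n_tp, n_fp, tp_over, fp_over) {
  base <- if (variant_type == "SNV") .base_snv else .base_indel
  tp <- utils::modifyList(base, tp_over)
  fp <- utils::modifyList(base, fp_over)
  if (variant_type == "INDEL") {
    tp$HP_run_at <- tp$HP_run_at %||% 0.6  # P(run base is A/T)
    fp$HP_run_at <- fp$HP_run_at %||% 0.7
  }
  list(variant_type = variant_type, n_tp = n_tp, n_fp = n_fp, tp = tp, fp = fp)
}

.profile_specs <- list(
  # SNV profiles: artifacts show low QUAL and end-of-read alt support
  "454-snv" = .mk_profile("SNV", 36, 300,
    tp_over = list(Q = list(dist = "gamma", shape = 8, rate = 0.02, lo = 150),
                   VP_vcf = list(dist = "norm", mean = 0.5, sd = 0.7)),
    fp_over = list(Q = list(dist = "gamma", shape = 2.2, rate = 0.05, lo = 30),
                   VP_vcf = list(dist = "norm", mean = -3.0, sd = 0.8),
                   BQ = list(dist = "norm", mean = 24, sd = 4, lo = 10))),
  "iontorrent-snv" = .mk_profile("SNV", 15, 300,
    tp_over = list(VP_vcf = list(dist = "norm", mean = 0.3, sd = 0.8)),
    fp_over = list(VP_vcf = list(dist = "norm", mean = -2.8, sd = 0.8),
                   SOR = list(dist = "gamma", shape = 6, rate = 2))),
  "illumina-snv" = .mk_profile("SNV", 27, 300,
    tp_over = list(Q = list(dist = "gamma", shape = 9, rate = 0.018, lo = 150)),
    fp_over = list(Q = list(dist = "gamma", shape = 2, rate = 0.05, lo = 30),
                   SB_vcf = list(dist = "gamma", shape = 6, rate = 0.25))),
  # indel profiles: artifacts cluster at long homopolymers with low QD
  "454-indel" = .mk_profile("INDEL", 20, 158,
    tp_over = list(QD = list(dist = "norm", mean = 16, sd = 3.5, lo = 6),
                   HP = list(dist = "pois", lambda = 0.4, shift = 1)),
    fp_over = list(QD = list(dist = "norm", mean = 2.5, sd = 1.2, lo = 0.2),
                   HP = list(dist = "pois", lambda = 2.2, shift = 4),
                   BQ_vcf = list(dist = "norm", mean = -1.2, sd = 0.8))),
  "iontorrent-indel" = .mk_profile("INDEL", 7, 644,
    tp_over = list(HP = list(dist = "pois", lambda = 0.4, shift = 1),
                   SOR = list(dist = "gamma", shape = 4, rate = 4),
                   QD = list(dist = "norm", mean = 18, sd = 4, lo = 6)),
    fp_over = list(HP = list(dist = "pois", lambda = 2.0, shift = 4),
                   SOR = list(dist = "gamma", shape = 10, rate = 3),
                   QD = list(dist = "norm", mean = 3, sd = 1.5, lo = 0.2),
                   VARW = list(dist = "pois", lambda = 0.9),
                   DevGT = list(dist = "beta", a = 3, b = 4))),
  "illumina-indel" = .mk_profile("INDEL", 12, 31,
    tp_over = list(Cov_vcf = list(dist = "gamma", shape = 10, rate = 0.008, lo = 200)),
    fp_over = list(Cov_vcf = list(dist = "gamma", shape = 3, rate = 0.02, lo = 25),
                   DP = list(dist = "gamma", shape = 3, rate = 0.02, lo = 25),
                   DevGT = list(dist = "beta", a = 3, b = 5)))
)

#' @export
print.glmvc_profile <- function(x, ...) {
  cat(sprintf("<glmvc_profile> %s (%s): %d TP, %d FP, seed %d\n",
              x$name, x$variant_type, x$n_tp, x$n_fp, x$seed))
  invisible(x)
}

#' Generate a labeled feature table from a platform profile
#'
#' Draws `n_tp` TP rows and `n_fp` FP rows with every applicable parameter
#' sampled independently from its class-conditional distribution
#' (Mersenne-Twister, fully determined by the profile seed). Indel rows
#' split `HP` into `HP_AT`/`HP_CG` by a Bernoulli run-base draw, preserving
#' the `HP = HP_AT + HP_CG` decomposition. Parameters not applicable to the
#' profile's variant type are `NA`.
#'
#' @param profile A [platform_profile()].
#' @return Labeled feature table tibble (identity columns synthesized as
#'   `chrS:i`).
#' @examples
#' tbl <- generate_profile_table(platform_profile("454-indel", seed = 2))
#' dplyr::count(tbl, label)
#' @export
generate_profile_table <- function(profile) {
  stopifnot(inherits(profile, "glmvc_profile"))
  vt <- profile$variant_type
  params <- glm_params(vt)
  old <- .Random.seed_exists()
  set.seed(profile$seed)
  on.exit(.restore_seed(old), add = TRUE)

  n_contam <- if (profile$n_fp > 0) round(profile$contaminant * profile$n_fp) else 0
  draw_class <- function(n, dists) {
    if (n == 0) {
      return(NULL)
    }
    cols <- purrr::map(stats::setNames(params, params), function(p) {
      if (p %in% c("HP_AT", "HP_CG")) return(rep(NA_real_, n))  # filled below
      d <- dists[[p]]
      if (is.null(d)) rep(NA_real_, n) else .draw(n, d)
    })
    tbl <- tibble::as_tibble(cols)
    if (vt == "INDEL") {
      at <- stats::runif(n) < dists$HP_run_at
      tbl$HP <- round(pmax(tbl$HP, 1))
      tbl$HP_AT <- ifelse(at, tbl$HP, 0)
      tbl$HP_CG <- ifelse(at, 0, tbl$HP)
      tbl$VARW <- round(pmax(tbl$VARW, 0))
      tbl$DevGT <- pmin(pmax(tbl$DevGT, 0), 1)
    }
    tbl
  }
  tp_tbl <- draw_class(profile$n_tp, profile$tp)
  fp_main <- draw_class(profile$n_fp - n_contam, profile$fp)
  fp_contam <- draw_class(n_contam, profile$tp)
  fp_tbl <- dplyr::bind_rows(fp_main, fp_contam)
  out <- dplyr::bind_rows(
    if (!is.null(tp_tbl)) dplyr::mutate(tp_tbl, label = "TP") else NULL,
    if (!is.null(fp_tbl)) dplyr::mutate(fp_tbl, label = "FP") else NULL
  )
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::as_tibble(purrr::map(stats::setNames(params, params), ~ numeric(0)))
    out$label <- character(0)
  }
  n <- nrow(out)
  for (p in setdiff(glm_params("all"), params)) out[[p]] <- rep(NA_real_, n)
  dplyr::bind_cols(
    tibble::tibble(
      chrom = "chrS", pos = seq_len(n) * 100,
      ref = if (vt == "SNV") rep("A", n) else rep("AT", n),
      alt = if (vt == "SNV") rep("G", n) else rep("A", n),
      type = vt
    ),
    out[, c("label", glm_params("all"))]
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Logistic ground-truth generator for recovery tests
#'
#' Draws covariates from stated distributions and labels each row
#' `TP` with probability `1/(1 + exp(-eta*))`, `eta*` from the stated true
#' intercept and coefficients. Used to verify that the fitting and selection
#' machinery recovers a known generating model.
#'
#' @param n Number of rows.
#' @param intercept True intercept.
#' @param coefficients Named numeric vector of true coefficients.
#' @param covariates Named list of distribution atoms (defaults: standard
#'   normal for each coefficient name); extra names beyond `coefficients`
#'   yield pure-noise covariates.
#' @param seed Integer seed.
#' @return Tibble with the covariate columns, `eta_true`, `p_true`, `label`.
#' @examples
#' gt <- generate_logistic(500, -1, c(x1 = 2), seed = 42)
#' mean(gt$label == "TP")
#' @export
generate_logistic <- function(n, intercept, coefficients,
                              covariates = NULL, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.restore_seed(old), add = TRUE)
  if (is.null(covariates)) {
    covariates <- purrr::map(stats::setNames(names(coefficients), names(coefficients)),
                             ~ list(dist = "norm", mean = 0, sd = 1))
  }
  if (n == 0) {
    out <- tibble::as_tibble(purrr::map(covariates, ~ numeric(0)))
    out$eta_true <- numeric(0); out$p_true <- numeric(0); out$label <- character(0)
    return(out)
  }
  cols <- purrr::map(covariates, ~ .draw(n, .x))
  tbl <- tibble::as_tibble(cols)
  eta <- rep(intercept, n)
  for (p in names(coefficients)) eta <- eta + coefficients[[p]] * tbl[[p]]
  p <- stats::plogis(eta)
  tbl$eta_true <- eta
  tbl$p_true <- p
  tbl$label <- ifelse(stats::runif(n) < p, "TP", "FP")
  tbl
}
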