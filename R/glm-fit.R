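#' Fit a binomial-logit GLM to labeled calls
#'
#' Maximum-likelihood fit of `P(label = TP) = 1/(1 + exp(-eta))` with
#' `eta = intercept + sum_j beta_j x_j`, via [stats::glm()]. Covariates enter
#' on their raw scales (no standardization), so coefficient magnitudes are
#' directly comparable with published linear predictors.
#'
#' A fit is declared non-converged when the iteratively reweighted least
#' squares loop hits `maxit` iterations, or when any coefficient exceeds
#' `coef_limit` in absolute value — a quasi-separation proxy: perfectly
#' separating covariates drive coefficients to infinity and would otherwise
#' appear to fit arbitrarily well.
#'
#' @param rows Data frame with a `label` column (`"TP"`/`"FP"`) and the
#'   covariate columns; rows must be complete in `covariates`.
#' @param covariates Character vector of covariate column names (may be
#'   empty: intercept-only fit).
#' @param maxit IRLS iteration cap (default 25).
#' @param coef_limit Absolute coefficient bound beyond which the fit is
#'   flagged non-converged (default 15).
#' @return List: `intercept`, `coefficients` (named, in `covariates` order),
#'   `aic` = `2(k+1) - 2 logLik`, `loglik`, `converged`, `n`.
#' @export
fit_logistic <- function(rows, covariates = character(), maxit = 25L,
                         coef_limit = 15) {
  stopifnot("label" %in% names(rows))
  y <- as.integer(rows$label == "TP")
  if (length(unique(rows$label)) < 1 || nrow(rows) == 0) {
    rlang::abort("fit_logistic: no rows to fit")
  }
  if (length(covariates) > 0) {
    missing_cov <- setdiff(covariates, names(rows))
    if (length(missing_cov) > 0) {
      rlang::abort(paste0("fit_logistic: missing covariate column(s): ",
                          paste(missing_cov, collapse = ", ")))
    }
    dat <- rows[, covariates, drop = FALSE]
    if (anyNA(dat)) rlang::abort("fit_logistic: NA in covariates; impute or drop first")
    form <- stats::as.formula(paste(
      ".glmvc_y ~", paste(sprintf("`%s`", covariates), collapse = " + ")))
    dat$.glmvc_y <- y
  } else {
    form <- .glmvc_y ~ 1
    dat <- data.frame(.glmvc_y = y)
  }
  fit <- suppressWarnings(stats::glm(
    form, family = stats::binomial(), data = dat,
    control = stats::glm.control(maxit = maxit)
  ))
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$converged) && all(is.finite(cf)) && all(abs(cf) <= coef_limit)
  beta <- cf[-1]
  names(beta) <- covariates
  list(
    intercept = unname(cf[1]),
    coefficients = beta,
    aic = stats::AIC(fit),
    loglik = as.numeric(stats::logLik(fit)),
    converged = conv,
    n = nrow(rows)
  )
}

#' Impute missing covariates by their null values
#'
#' GATK omits rank-sum annotations (`VP_vcf`, `BQ_vcf`, `MQRank`) at sites
#' without both ref and alt reads (e.g. homozygous-alt calls), and may omit
#' the Phred-scaled bias scores `SB_vcf` (FS) and `SOR`. Their null value —
#' no evidence of bias — is 0, so 0 is imputed. Every other parameter has no
#' defensible default: rows missing one are dropped from training
#' ([training_rows()]) and flagged at application time ([apply_model()]).
#'
#' @param tbl Feature table.
#' @return `tbl` with zero-null columns imputed and a logical `imputed`
#'   column recording which rows were touched.
#' @export
impute_features <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  present <- intersect(.zero_null_params, names(tbl))
  touched <- rep(FALSE, nrow(tbl))
  for (p in present) {
    miss <- is.na(tbl[[p]])
    touched <- touched | miss
    tbl[[p]][miss] <- 0
  }
  tbl$imputed <- if ("imputed" %in% names(tbl)) tbl$imputed | touched else touched
  tbl
}

#' Rows usable for model training
#'
#' Applies the imputation policy, then drops rows still incomplete in the
#' candidate covariates (dropping is confined to training; at application
#' time such calls are kept and flagged, to protect sensitivity).
#'
#' @param tbl Labeled feature table.
#' @param covariates Candidate covariate names.
#' @return Filtered, imputed tibble.
#' @export
training_rows <- function(tbl, covariates) {
  tbl <- impute_features(tbl)
  covariates <- intersect(covariates, names(tbl))
  if (length(covariates) == 0) return(tbl)
  keep <- stats::complete.cases(tbl[, covariates, drop = FALSE])
  if (any(!keep)) {
    rlang::inform(sprintf("training_rows: dropped %d incomplete row(s)", sum(!keep)))
  }
  tbl[keep, , drop = FALSE]
}
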