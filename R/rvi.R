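#' Screen parameter pairs for collinearity
#'
#' Jointly including strongly correlated covariates biases AIC-based model
#' comparison, so models containing such a pair are excluded from the model
#' space. A pair is forbidden when the absolute Pearson correlation over
#' pairwise-complete rows reaches `threshold`. The pair (`Q`, `QD`) —
#' variant quality and quality-by-depth, near-deterministically related — is
#' always forbidden when both parameters are candidates.
#'
#' @param tbl Feature table.
#' @param threshold Absolute correlation cutoff (default 0.7).
#' @param params Parameters to screen; default: all registry parameters
#'   present in `tbl`.
#' @return Tibble with columns `a`, `b` (one row per forbidden pair) and
#'   attribute `r` left in a `cor` column for inspection.
#' @export
correlation_screen <- function(tbl, threshold = 0.7, params = NULL) {
  if (is.null(params)) params <- intersect(glm_params("all"), names(tbl))
  params <- intersect(params, names(tbl))
  out <- tibble::tibble(a = character(), b = character(), cor = numeric())
  if (length(params) >= 2) {
    constant <- params[purrr::map_lgl(params, function(p) {
      v <- tbl[[p]][!is.na(tbl[[p]])]
      length(v) >= 3 && stats::sd(v) == 0
    })]
    if (length(constant) > 0) {
      rlang::warn(paste0("correlation_screen: constant column(s), correlation undefined: ",
                         paste(constant, collapse = ", ")))
    }
    combs <- utils::combn(sort(params), 2)
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]; b <- combs[2, k]
      if (a %in% constant || b %in% constant) next
      x <- tbl[[a]]; y <- tbl[[b]]
      ok <- stats::complete.cases(x, y)
      r <- if (sum(ok) >= 3) stats::cor(x[ok], y[ok]) else NA_real_
      if (!is.na(r) && abs(r) >= threshold) {
        out <- dplyr::bind_rows(out, tibble::tibble(a = a, b = b, cor = r))
      }
    }
  }
  if (all(c("Q", "QD") %in% params) && !any(out$a == "Q" & out$b == "QD")) {
    out <- dplyr::bind_rows(out, tibble::tibble(a = "Q", b = "QD", cor = NA_real_))
  }
  out
}

#' Enumerate the admissible logistic model space
#'
#' Fits a binomial-logit GLM for every nonempty subset of the candidate
#' parameters of size at most `max_size` that contains no forbidden pair,
#' and records each fit's AIC. Non-converging fits (including
#' quasi-separated ones) are excluded from the space and counted. Full
#' enumeration over all subset sizes is used when the admissible count does
#' not exceed `full_limit`; beyond that, `max_size` caps the subset size.
#'
#' @param tbl Labeled feature table.
#' @param candidates Candidate parameter names.
#' @param forbidden_pairs Output of [correlation_screen()] or `NULL`.
#' @param max_size Maximum subset size when capping is needed (default 4).
#' @param full_limit Admissible-subset count up to which all sizes are
#'   enumerated (default 50000).
#' @param maxit,coef_limit Convergence controls, see [fit_logistic()].
#' @return Object of class `glmvc_modelspace`: list with `fits` (tibble:
#'   `id`, `params` list-column, `size`, `aic`), `candidates`,
#'   `excluded_correlated`, `excluded_nonconverged`, `n_rows`.
#' @export
enumerate_models <- function(tbl, candidates, forbidden_pairs = NULL,
                             max_size = 4L, full_limit = 50000L,
                             maxit = 25L, coef_limit = 15) {
  stopifnot(max_size >= 1)
  candidates <- sort(intersect(candidates, names(tbl)))
  rows <- training_rows(tbl, candidates)
  subsets_all <- .admissible_subsets(candidates, forbidden_pairs, length(candidates))
  if (length(subsets_all) > full_limit) {
    subsets <- .admissible_subsets(candidates, forbidden_pairs, max_size)
  } else {
    subsets <- subsets_all
  }
  n_corr_excluded <- (2^length(candidates) - 1) - length(subsets_all)
  fits <- purrr::map(subsets, function(s) {
    fit_logistic(rows, s, maxit = maxit, coef_limit = coef_limit)
  })
  conv <- purrr::map_lgl(fits, "converged")
  if (!any(conv)) rlang::abort("empty model space: no admissible model converged")
  fits_tbl <- tibble::tibble(
    id = seq_along(subsets)[conv],
    params = subsets[conv],
    size = lengths(subsets)[conv],
    aic = purrr::map_dbl(fits, "aic")[conv]
  )
  structure(
    list(
      fits = fits_tbl,
      candidates = candidates,
      excluded_correlated = as.integer(n_corr_excluded),
      excluded_nonconverged = sum(!conv),
      n_rows = nrow(rows)
    ),
    class = "glmvc_modelspace"
  )
}

# all nonempty subsets of `params` of size <= max_size avoiding forbidden pairs
.admissible_subsets <- function(params, forbidden_pairs, max_size) {
  forb <- if (is.null(forbidden_pairs) || nrow(as.data.frame(forbidden_pairs)) == 0) {
    NULL
  } else {
    as.data.frame(forbidden_pairs)[, 1:2]
  }
  ok_pair <- function(s) {
    if (is.null(forb) || length(s) < 2) return(TRUE)
    !any(forb[[1]] %in% s & forb[[2]] %in% s)
  }
  out <- list()
  for (k in seq_len(min(max_size, length(params)))) {
    cmb <- utils::combn(params, k, simplify = FALSE)
    out <- c(out, cmb[purrr::map_lgl(cmb, ok_pair)])
  }
  out
}

#' @export
print.glmvc_modelspace <- function(x, ...) {
  cat(sprintf(
    "<glmvc_modelspace> %d converged model(s) over %d candidate(s); excluded: %d correlated, %d non-converged\n",
    nrow(x$fits), length(x$candidates), x$excluded_correlated, x$excluded_nonconverged))
  invisible(x)
}

#' Akaike weights of an enumerated model space
#'
#' `w_m = exp(-delta_m/2) / sum_k exp(-delta_k/2)` with
#' `delta_m = AIC_m - min AIC`; the weights sum to one and quantify each
#' model's relative support.
#'
#' @param space A `glmvc_modelspace`.
#' @return Numeric vector of weights aligned with `space$fits`.
#' @export
akaike_weights <- function(space) {
  aic <- space$fits$aic
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Raw relative variable importance
#'
#' For each parameter, the sum of Akaike weights over the admissible models
#' containing it; lies in `[0, 1]`, with 0 for parameters present in no
#' admissible converged model.
#'
#' @param weights Weights from [akaike_weights()].
#' @param space The matching `glmvc_modelspace`.
#' @return Named numeric vector over `space$candidates`.
#' @export
raw_rvi <- function(weights, space) {
  purrr::map_dbl(
    stats::setNames(space$candidates, space$candidates),
    function(p) sum(weights[purrr::map_lgl(space$fits$params, ~ p %in% .x)])
  )
}

#' Normalize relative variable importance for unequal model membership
#'
#' Excluding correlated and non-converging models leaves parameters present
#' in unequal numbers of admissible models, which distorts the raw RVI. Two
#' corrections are available:
#' \describe{
#'   \item{`"mean_inverse"` (default)}{`RVI(p) = raw(p) * (mean model count
#'     over parameters) / #models(p)`: up-weights parameters admitted to few
#'     models. Values above 1 are possible for parameters that concentrate
#'     weight despite scarce membership.}
#'   \item{`"as_printed"`}{`RVI(p) = raw(p) * #models(p) / sum_i #models(i)`:
#'     a pure down-scaling (never exceeds the raw value).}
#' }
#' Parameters with `#models(p) = 0` get RVI 0 in both modes.
#'
#' @param raw Named raw RVI vector.
#' @param n_models Named count of admissible models containing each
#'   parameter.
#' @param mode `"mean_inverse"` or `"as_printed"`.
#' @return Named numeric vector.
#' @export
normalize_rvi <- function(raw, n_models, mode = c("mean_inverse", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(all(names(raw) %in% names(n_models)))
  if (any(n_models < 0)) rlang::abort("negative model count")
  # totals are taken over the full parameter set of the model space, even
  # when only a subset of raw values is being normalized
  total <- sum(n_models)
  n <- length(n_models)
  n_models <- n_models[names(raw)]
  out <- switch(mode,
    as_printed = ifelse(n_models == 0, 0, raw * n_models / total),
    mean_inverse = ifelse(n_models == 0, 0, raw * (total / n) / n_models)
  )
  stats::setNames(as.numeric(out), names(raw))
}

#' Relative variable importance of every parameter
#'
#' End-to-end importance analysis: screens correlated pairs, enumerates the
#' admissible logistic model space, computes Akaike weights, and reports per
#' parameter the raw RVI (sum of weights of models containing it), the
#' number of admissible models containing it, and the normalized RVI.
#'
#' @param tbl Labeled feature table (`label` in `"TP"`/`"FP"`).
#' @param candidates Parameters to assess; default: all applicable, non-all-NA
#'   columns of `tbl`.
#' @param mode Normalization mode, see [normalize_rvi()].
#' @param corr_threshold Correlation cutoff for [correlation_screen()].
#' @param max_size,full_limit,maxit,coef_limit Passed to
#'   [enumerate_models()].
#' @return Object of class `glmvc_rvi`: tibble with columns `parameter`,
#'   `n_models`, `raw_rvi`, `normalized_rvi`, `mode`, plus attributes
#'   `excluded_correlated`, `excluded_nonconverged`, `n_models_total`.
#' @examples
#' tbl <- generate_profile_table(platform_profile("454-snv", seed = 3))
#' rvi(tbl, candidates = c("Q", "VP_vcf", "MQ", "SB"), max_size = 2)
#' @export
rvi <- function(tbl, candidates = NULL, mode = c("mean_inverse", "as_printed"),
                corr_threshold = 0.7, max_size = 4L, full_limit = 50000L,
                maxit = 25L, coef_limit = 15) {
  mode <- match.arg(mode)
  if (is.null(candidates)) {
    ty <- unique(tbl$type)
    candidates <- if (length(ty) == 1) glm_params(ty) else glm_params("all")
    candidates <- intersect(candidates, names(tbl))
    candidates <- candidates[purrr::map_lgl(candidates, function(p) !all(is.na(tbl[[p]])))]
  }
  rows <- training_rows(tbl, candidates)
  forb <- correlation_screen(rows, threshold = corr_threshold, params = candidates)
  space <- enumerate_models(rows, candidates, forb, max_size = max_size,
                            full_limit = full_limit, maxit = maxit,
                            coef_limit = coef_limit)
  w <- akaike_weights(space)
  raw <- raw_rvi(w, space)
  n_models <- purrr::map_int(
    stats::setNames(space$candidates, space$candidates),
    function(p) sum(purrr::map_lgl(space$fits$params, ~ p %in% .x))
  )
  normalized <- normalize_rvi(raw, n_models, mode)
  res <- tibble::tibble(
    parameter = space$candidates,
    n_models = as.integer(unname(n_models)),
    raw_rvi = as.numeric(unname(raw)),
    normalized_rvi = as.numeric(unname(normalized)),
    mode = mode
  )
  structure(res,
    class = c("glmvc_rvi", class(res)),
    excluded_correlated = space$excluded_correlated,
    excluded_nonconverged = space$excluded_nonconverged,
    n_models_total = nrow(space$fits)
  )
}

#' Write an RVI report TSV
#'
#' @param x A `glmvc_rvi` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rvi_report <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
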