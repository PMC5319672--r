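#' Forward covariate selection by AIC
#'
#' Starts from the intercept-only model and greedily adds, at each step, the
#' candidate covariate whose addition yields the lowest AIC among additions
#' that (a) converge and (b) introduce no forbidden (correlated) pair with
#' already-included covariates. Selection stops when no admissible addition
#' strictly lowers AIC. Ties are broken lexicographically by parameter name,
#' making the procedure deterministic.
#'
#' @param rows Labeled, imputation-complete feature rows (see
#'   [training_rows()]).
#' @param candidates Candidate covariate names.
#' @param forbidden_pairs Two-column matrix/data frame of forbidden pairs
#'   (from [correlation_screen()]), or `NULL`.
#' @param variant_type,platform Tags recorded on the returned model.
#' @param maxit,coef_limit Passed to [fit_logistic()].
#' @return A `glmvc_model` without a threshold; `$trace` holds the per-step
#'   AIC trace.
#' @export
forward_select <- function(rows, candidates, forbidden_pairs = NULL,
                           variant_type = "SNV", platform = "unspecified",
                           maxit = 25L, coef_limit = 15) {
  candidates <- sort(intersect(candidates, names(rows)))
  base <- fit_logistic(rows, character(), maxit = maxit, coef_limit = coef_limit)
  selected <- character()
  best <- base
  trace <- tibble::tibble(step = 0L, added = NA_character_, aic = base$aic)
  repeat {
    pool <- setdiff(candidates, selected)
    pool <- pool[!purrr::map_lgl(pool, .forbidden_with, selected, forbidden_pairs)]
    if (length(pool) == 0) break
    fits <- purrr::map(pool, function(p) {
      fit_logistic(rows, c(selected, p), maxit = maxit, coef_limit = coef_limit)
    })
    ok <- purrr::map_lgl(fits, "converged")
    if (!any(ok)) break
    aics <- ifelse(ok, purrr::map_dbl(fits, "aic"), Inf)
    # lexicographic tie-break: pool is sorted, which.min takes the first
    i <- which.min(aics)
    if (aics[i] >= best$aic) break
    selected <- c(selected, pool[i])
    best <- fits[[i]]
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = nrow(trace), added = pool[i], aic = best$aic))
  }
  glmvc_model(
    variant_type = variant_type, platform = platform,
    intercept = best$intercept,
    coefficients = best$coefficients[selected],
    aic = best$aic, converged = best$converged,
    trace = trace,
    check_params = all(selected %in% glm_params(variant_type))
  )
}

.forbidden_with <- function(p, selected, forbidden_pairs) {
  if (is.null(forbidden_pairs) || length(selected) == 0) return(FALSE)
  fp <- as.data.frame(forbidden_pairs)
  any((fp[[1]] == p & fp[[2]] %in% selected) |
      (fp[[2]] == p & fp[[1]] %in% selected))
}

#' Sensitivity-preserving retention threshold
#'
#' Chooses the probability threshold `t` subject to three conditions:
#' (1) no true positive of the training set is mistaken for a false positive
#' (sensitivity is maintained), (2) as many false positives as possible are
#' excluded, (3) `t` is as low as possible while satisfying (1) and (2).
#'
#' With the strict decision rule KEEP iff `p > t`, the literal optimum is:
#' let `m` be the smallest predicted probability among TP rows and `E` the
#' set of FP probabilities below `m`; then `t = max(E)` (or 0 when `E` is
#' empty). Every TP is kept, every FP that can be excluded without touching
#' a TP is excluded, and no smaller `t` excludes as many.
#'
#' @param model A `glmvc_model`.
#' @param rows Labeled feature rows (post-imputation).
#' @return Threshold in `[0, 1]`.
#' @export
estimate_threshold <- function(model, rows) {
  p <- predict_prob(model, rows)
  tp <- p[rows$label == "TP"]
  fp <- p[rows$label == "FP"]
  if (length(tp) == 0) rlang::abort("cannot preserve sensitivity: no TP rows")
  m <- min(tp)
  excludable <- fp[fp < m]
  if (length(excludable) == 0) 0 else max(excludable)
}

#' Apply a trained model to a feature table
#'
#' Computes each call's probability of being a true positive and the
#' KEEP/FILTER decision under the strict rule KEEP iff `p > threshold`.
#' Zero-null covariates are imputed as in training; a call missing any other
#' model covariate cannot be scored honestly and is KEPT with its `imputed`
#' flag set (fail-safe toward sensitivity), with a warning.
#'
#' @param model A `glmvc_model` with a threshold.
#' @param features Feature table.
#' @return `features` with columns `p_hat`, `decision` (`"KEEP"`/`"FILTER"`)
#'   and `imputed` appended.
#' @export
apply_model <- function(model, features) {
  if (is.na(model$threshold)) rlang::abort("model has no threshold; train or set one")
  features <- impute_features(features)
  needed <- names(model$coefficients)
  miss_col <- setdiff(needed, names(features))
  if (length(miss_col) > 0) {
    rlang::abort(paste0("feature table lacks model covariate(s): ",
                        paste(miss_col, collapse = ", ")))
  }
  if (length(needed) > 0) {
    incomplete <- !stats::complete.cases(features[, needed, drop = FALSE])
  } else {
    incomplete <- rep(FALSE, nrow(features))
  }
  scored <- features
  if (any(incomplete)) {
    rlang::warn(sprintf(
      "%d call(s) missing non-imputable covariates: kept and flagged",
      sum(incomplete)))
    for (p in needed) scored[[p]][is.na(scored[[p]])] <- 0  # placeholder for p_hat only
  }
  p_hat <- predict_prob(model, scored)
  decision <- ifelse(p_hat > model$threshold, "KEEP", "FILTER")
  decision[incomplete] <- "KEEP"
  features$p_hat <- p_hat
  features$decision <- decision
  features$imputed <- features$imputed | incomplete
  features
}

#' Train the full specific-filtration model
#'
#' Composition of the training path: screen correlated parameter pairs,
#' forward-select covariates by AIC, then estimate the sensitivity-preserving
#' threshold — yielding a complete, applicable filter for one platform and
#' variant type.
#'
#' @param tbl Labeled feature table (`label` in `"TP"`/`"FP"`).
#' @param variant_type `"SNV"` or `"INDEL"`; defaults to the table's `type`
#'   column when unambiguous.
#' @param platform Platform tag recorded on the model.
#' @param candidates Candidate covariates; default: all parameters applicable
#'   to `variant_type` present in the table.
#' @param corr_threshold Absolute Pearson correlation above which a pair is
#'   forbidden (default 0.7).
#' @param maxit,coef_limit Convergence controls, see [fit_logistic()].
#' @return A `glmvc_model` with threshold set.
#' @examples
#' tbl <- generate_profile_table(platform_profile("iontorrent-indel", seed = 7))
#' m <- train_pipeline(tbl, platform = "IonTorrent")
#' glance(m)
#' @export
train_pipeline <- function(tbl, variant_type = NULL, platform = "unspecified",
                           candidates = NULL, corr_threshold = 0.7,
                           maxit = 25L, coef_limit = 15) {
  if (is.null(variant_type)) {
    ty <- unique(tbl$type)
    if (length(ty) != 1) rlang::abort("mixed variant types: pass variant_type or split the table")
    variant_type <- ty
  }
  if (is.null(candidates)) {
    candidates <- intersect(glm_params(variant_type), names(tbl))
    candidates <- candidates[purrr::map_lgl(candidates, function(p) !all(is.na(tbl[[p]])))]
  }
  if (!any(tbl$label == "TP")) rlang::abort("training set has no TP rows")
  if (!any(tbl$label == "FP")) rlang::abort("training set has no FP rows")
  rows <- training_rows(tbl, candidates)
  forb <- correlation_screen(rows, threshold = corr_threshold, params = candidates)
  model <- forward_select(rows, candidates, forb,
                          variant_type = variant_type, platform = platform,
                          maxit = maxit, coef_limit = coef_limit)
  model$threshold <- estimate_threshold(model, rows)
  model
}

#' Two-threshold triage of scored calls
#'
#' Optional reporting mode: calls below `t_low` are filtered, calls above
#' `t_high` are kept, and the band in between is routed to manual review or
#' confirmatory sequencing. Defaults: `t_low` is the model's trained
#' threshold, `t_high` the smallest training TP probability.
#'
#' @param model A trained `glmvc_model`.
#' @param features Feature table.
#' @param t_low,t_high Band bounds; `t_low <= t_high`.
#' @return Feature table with `p_hat` and `triage`
#'   (`"FILTER"`/`"REVIEW"`/`"KEEP"`).
#' @export
triage_calls <- function(model, features, t_low = model$threshold, t_high = NULL) {
  scored <- apply_model(model, features)
  if (is.null(t_high)) t_high <- max(t_low, min(scored$p_hat[scored$decision == "KEEP"]))
  stopifnot(t_low <= t_high)
  scored$triage <- dplyr::case_when(
    scored$p_hat <= t_low ~ "FILTER",
    scored$p_hat > t_high ~ "KEEP",
    TRUE ~ "REVIEW"
  )
  scored
}
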