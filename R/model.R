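#' Construct a fitted filtration model
#'
#' Container for a platform- and variant-type-specific logistic filter: the
#' linear predictor's intercept and named coefficients, the fit's AIC, and
#' the retention threshold on the predicted probability scale. Calls with
#' predicted probability strictly above the threshold are kept.
#'
#' @param variant_type `"SNV"` or `"INDEL"`.
#' @param platform Free-text platform tag (e.g. `"454"`, `"IonTorrent"`).
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric vector; names must be parameters from
#'   [glm_params()] applicable to `variant_type`.
#' @param aic Akaike information criterion of the fit (`NA` allowed for
#'   hand-constructed models).
#' @param threshold Retention threshold in `[0, 1]`.
#' @param converged Convergence flag.
#' @param trace Optional tibble with the forward-selection AIC trace.
#' @param check_params Validate coefficient names against the parameter
#'   registry (default). Disable for models over simulated covariates.
#' @return Object of class `glmvc_model`.
#' @export
glmvc_model <- function(variant_type, platform, intercept, coefficients,
                        aic = NA_real_, threshold = NA_real_,
                        converged = TRUE, trace = NULL, check_params = TRUE) {
  variant_type <- match.arg(variant_type, c("SNV", "INDEL"))
  coefficients <- unlist(coefficients)
  if (is.null(coefficients)) coefficients <- stats::setNames(numeric(0), character(0))
  bad <- setdiff(names(coefficients), glm_params(variant_type))
  if (check_params && length(bad) > 0) {
    rlang::abort(paste0(
      "unknown parameter name(s): ", paste(bad, collapse = ", "),
      "; valid names for ", variant_type, ": ",
      paste(glm_params(variant_type), collapse = ", ")
    ))
  }
  if (!is.na(threshold) && (threshold < 0 || threshold > 1)) {
    rlang::abort("threshold must lie in [0, 1]")
  }
  structure(
    list(
      variant_type = variant_type,
      platform = platform,
      intercept = as.numeric(intercept),
      coefficients = coefficients,
      aic = as.numeric(aic),
      threshold = as.numeric(threshold),
      converged = isTRUE(converged),
      trace = trace
    ),
    class = "glmvc_model"
  )
}

#' @export
print.glmvc_model <- function(x, ...) {
  cat(sprintf("<glmvc_model> %s / %s\n", x$platform, x$variant_type))
  terms <- c(sprintf("%+.4g", x$intercept),
             sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)))
  cat("  eta =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  AIC %.4g | threshold %.4g | converged %s\n",
              x$aic, x$threshold, x$converged))
  invisible(x)
}

#' Linear predictor and probability of a model on a feature table
#'
#' @param model A `glmvc_model`.
#' @param features Data frame with the model's covariate columns.
#' @return Numeric vector of predicted probabilities `1/(1+exp(-eta))`.
#' @export
predict_prob <- function(model, features) {
  eta <- rep(model$intercept, nrow(features))
  for (p in names(model$coefficients)) {
    if (!p %in% names(features)) {
      rlang::abort(paste0("feature table lacks model covariate: ", p))
    }
    eta <- eta + model$coefficients[[p]] * features[[p]]
  }
  stats::plogis(eta)
}

#' Write a fitted model to a JSON file
#'
#' Plain-text serialization with full numeric precision; the round trip
#' through [read_model()] reproduces the model exactly.
#'
#' @param model A `glmvc_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "glmvc_model"))
  obj <- list(
    variant_type = model$variant_type,
    platform_tag = model$platform,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    aic = model$aic,
    converged = model$converged,
    threshold = model$threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a fitted model from a JSON file
#'
#' @param path File written by [write_model()].
#' @return A `glmvc_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  coefs <- unlist(obj$coefficients)
  if (is.null(coefs)) coefs <- stats::setNames(numeric(0), character(0))
  glmvc_model(
    variant_type = obj$variant_type,
    platform = obj$platform_tag,
    intercept = obj$intercept,
    coefficients = coefs,
    aic = if (is.null(obj$aic)) NA_real_ else obj$aic,
    threshold = if (is.null(obj$threshold)) NA_real_ else obj$threshold,
    converged = isTRUE(obj$converged)
  )
}
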