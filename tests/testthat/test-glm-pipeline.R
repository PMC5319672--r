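test_that("fit_logistic matches an independently coded likelihood maximizer", {
  gt <- generate_logistic(400, -0.5, c(a = 1.2, b = -0.8), seed = 9)
  fit <- fit_logistic(gt, c("a", "b"))
  oracle <- oracle_logistic(as.data.frame(gt), c("a", "b"))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle$beta,
               tolerance = 1e-4)
  expect_equal(fit$aic, oracle$aic, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik, tolerance = 1e-10)
})

test_that("fit_logistic recovers generating coefficients at n = 5000", {
  gt <- generate_logistic(5000, -1, c(x = 2), seed = 101)
  fit <- fit_logistic(gt, "x")
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - (-1)), 0.15)
  expect_lt(abs(fit$coefficients[["x"]] - 2), 0.15)
})

test_that("degenerate and separated inputs are flagged non-converged", {
  # single-class labels: fitted probability driven to 1
  one_class <- tibble::tibble(label = rep("TP", 40), x = rnorm(40))
  f1 <- fit_logistic(one_class, character())
  expect_false(f1$converged)
  # perfect separation on a binary covariate equal to the label
  sep <- tibble::tibble(label = rep(c("TP", "FP"), each = 30),
                        x = rep(c(1, 0), each = 30))
  f2 <- fit_logistic(sep, "x")
  expect_false(f2$converged)
})

test_that("forward selection recovers a planted 2-of-6 logistic model", {
  hits <- 0L
  for (seed in 1:20) {
    covs <- purrr::map(setNames(paste0("c", 1:6), paste0("c", 1:6)),
                       ~ list(dist = "norm", mean = 0, sd = 1))
    gt <- generate_logistic(2000, 0, c(c1 = 1.5, c2 = -1), covariates = covs,
                            seed = 1000 + seed)
    m <- forward_select(gt, paste0("c", 1:6))
    if (all(c("c1", "c2") %in% names(m$coefficients))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("forward selection on pure noise mostly returns the intercept-only model", {
  small <- 0L
  for (seed in 1:20) {
    covs <- purrr::map(setNames(paste0("c", 1:6), paste0("c", 1:6)),
                       ~ list(dist = "norm", mean = 0, sd = 1))
    gt <- generate_logistic(2000, 0, c(c1 = 0), covariates = covs,
                            seed = 2000 + seed)
    m <- forward_select(gt, paste0("c", 1:6))
    if (length(m$coefficients) <= 1) small <- small + 1L
  }
  expect_gte(small, 15L)
})

test_that("forward selection AIC trace is strictly decreasing and greedy-optimal", {
  covs <- purrr::map(setNames(paste0("c", 1:5), paste0("c", 1:5)),
                     ~ list(dist = "norm", mean = 0, sd = 1))
  gt <- generate_logistic(1500, 0.3, c(c1 = 1.2, c2 = 0.8, c3 = -0.5),
                          covariates = covs, seed = 77)
  m <- forward_select(gt, paste0("c", 1:5))
  tr <- m$trace
  expect_true(all(diff(tr$aic) < 0))
  # greedy-step optimality: at each step the chosen covariate has minimal
  # AIC among all admissible converged additions (exhaustive re-check)
  selected <- character()
  for (i in seq_len(nrow(tr))[-1]) {
    pool <- setdiff(paste0("c", 1:5), selected)
    aics <- vapply(pool, function(p) {
      f <- fit_logistic(gt, c(selected, p))
      if (f$converged) f$aic else Inf
    }, numeric(1))
    expect_identical(tr$added[i], pool[which.min(aics)])
    selected <- c(selected, tr$added[i])
  }
  # final AIC no worse than intercept-only
  expect_lte(tr$aic[nrow(tr)], tr$aic[1])
})

test_that("forward selection honors forbidden pairs and empty candidate lists", {
  covs <- purrr::map(setNames(c("a", "b"), c("a", "b")),
                     ~ list(dist = "norm", mean = 0, sd = 1))
  gt <- generate_logistic(800, 0, c(a = 1.5, b = 1), covariates = covs, seed = 5)
  forb <- tibble::tibble(a = "a", b = "b")
  m <- forward_select(gt, c("a", "b"), forb)
  expect_lte(length(m$coefficients), 1L)
  m0 <- forward_select(gt, character())
  expect_identical(length(m0$coefficients), 0L)
})

test_that("threshold rule: hand-enumerated example and boundary cases", {
  mk_rows <- function(p, lab) tibble::tibble(x = qlogis(p), label = lab)
  model <- glmvc_model("SNV", "test", intercept = 0, coefficients = c(Q = 1))
  rows <- tibble::tibble(Q = qlogis(c(0.9, 0.8, 0.1, 0.5, 0.85)),
                         label = c("TP", "TP", "FP", "FP", "FP"))
  t <- estimate_threshold(model, rows)
  expect_equal(t, 0.5, tolerance = 1e-12)
  scored <- apply_model(
    glmvc_model("SNV", "t", 0, c(Q = 1), threshold = t), rows)
  expect_true(all(scored$decision[rows$label == "TP"] == "KEEP"))
  expect_identical(sum(scored$decision[rows$label == "FP"] == "FILTER"), 2L)
  # all FP above min TP: threshold 0, nothing filtered
  rows2 <- tibble::tibble(Q = qlogis(c(0.6, 0.7, 0.9)),
                          label = c("TP", "FP", "FP"))
  expect_equal(estimate_threshold(model, rows2), 0)
  # all FP below min TP: threshold = max FP probability, all FP filtered
  rows3 <- tibble::tibble(Q = qlogis(c(0.9, 0.2, 0.3)),
                          label = c("TP", "FP", "FP"))
  expect_equal(estimate_threshold(model, rows3), 0.3, tolerance = 1e-12)
  # no TP rows: error
  rows4 <- tibble::tibble(Q = c(0, 1), label = c("FP", "FP"))
  expect_error(estimate_threshold(model, rows4), "sensitivity")
})

test_that("threshold rule preserves sensitivity and maximizes exclusion on random sets", {
  model <- glmvc_model("SNV", "t", 0, c(Q = 1))
  set.seed(303)
  for (i in 1:100) {
    n_tp <- sample(1:20, 1); n_fp <- sample(1:50, 1)
    rows <- tibble::tibble(
      Q = qlogis(runif(n_tp + n_fp, 0.001, 0.999)),
      label = c(rep("TP", n_tp), rep("FP", n_fp))
    )
    t <- estimate_threshold(model, rows)
    m2 <- glmvc_model("SNV", "t", 0, c(Q = 1), threshold = t)
    scored <- apply_model(m2, rows)
    keep <- scored$decision == "KEEP"
    # condition 1: sensitivity unchanged
    expect_identical(sum(keep & rows$label == "TP"), n_tp)
    # condition 2+3: no threshold satisfying condition 1 filters more FPs
    p <- scored$p_hat
    n_filtered <- sum(!keep & rows$label == "FP")
    best_possible <- sum(p[rows$label == "FP"] < min(p[rows$label == "TP"]))
    expect_identical(n_filtered, best_possible)
  }
})

test_that("apply_model: strict boundary, probability bounds, monotonicity", {
  m <- glmvc_model("SNV", "t", 0, c(Q = 1), threshold = 0.5)
  rows <- tibble::tibble(Q = c(0, -1, 1))  # p = .5, .27, .73
  scored <- apply_model(m, rows)
  expect_identical(scored$decision, c("FILTER", "FILTER", "KEEP"))
  expect_true(all(scored$p_hat > 0 & scored$p_hat < 1))
  expect_true(all(diff(scored$p_hat[order(rows$Q)]) > 0))
})

test_that("apply_model imputes zero-null covariates and flags non-imputable gaps", {
  m <- glmvc_model("SNV", "t", 0, c(VP_vcf = 2, Q = 0.5), threshold = 0.5)
  rows <- tibble::tibble(VP_vcf = c(NA, 1), Q = c(2, NA))
  expect_warning(scored <- apply_model(m, rows), "missing")
  # row 1: VP_vcf imputed to 0 -> eta = 1 -> keep; imputed flag set
  expect_equal(scored$p_hat[1], plogis(1))
  expect_true(all(scored$imputed))
  # row 2: Q non-imputable -> kept fail-safe
  expect_identical(scored$decision[2], "KEEP")
})

test_that("train_pipeline composes screening, selection and thresholding", {
  tbl <- generate_profile_table(platform_profile("iontorrent-indel", seed = 11))
  m <- train_pipeline(tbl, platform = "IonTorrent")
  expect_s3_class(m, "glmvc_model")
  expect_true(m$converged)
  expect_gte(m$threshold, 0)
  scored <- apply_model(m, tbl)
  keep <- scored$decision == "KEEP"
  expect_identical(sum(keep & tbl$label == "TP"), sum(tbl$label == "TP"))
  expect_gte(mean(!keep[tbl$label == "FP"]), 0.9)
})

test_that("train_pipeline handles tiny and degenerate training sets", {
  tiny <- tibble::tibble(
    chrom = "c", pos = c(1, 2), ref = "A", alt = "G", type = "SNV",
    label = c("TP", "FP"), Q = c(100, 10))
  m <- train_pipeline(tiny, candidates = "Q")
  p_fp <- predict_prob(m, tiny[2, ])
  expect_true(m$threshold %in% c(0, p_fp))
  # empty candidate list: intercept-only model with a threshold
  m0 <- train_pipeline(tiny, candidates = character())
  expect_identical(length(m0$coefficients), 0L)
  # no FP rows: error
  expect_error(train_pipeline(dplyr::mutate(tiny, label = "TP"),
                              candidates = "Q"), "FP")
})

test_that("two-threshold triage routes the uncertain band to review", {
  m <- glmvc_model("SNV", "t", 0, c(Q = 1), threshold = 0.2)
  rows <- tibble::tibble(Q = qlogis(c(0.05, 0.5, 0.95)))
  tri <- triage_calls(m, rows, t_low = 0.2, t_high = 0.8)
  expect_identical(tri$triage, c("FILTER", "REVIEW", "KEEP"))
})
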