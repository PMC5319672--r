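# Independent oracles, coded without the package's fitting path.

# Logistic log-likelihood maximized with optim (BFGS) — independent of
# stats::glm's IRLS. Returns intercept-first coefficient vector and AIC.
oracle_logistic <- function(rows, covariates) {
  y <- as.integer(rows$label == "TP")
  X <- cbind(1, as.matrix(rows[, covariates, drop = FALSE]))
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  k <- length(covariates)
  list(beta = fit$par, loglik = -fit$value, aic = 2 * (k + 1) + 2 * fit$value)
}

# Brute-force raw RVI over an explicit subset enumeration, using the optim
# likelihood above for every AIC.
oracle_raw_rvi <- function(rows, params, forbidden = NULL) {
  subsets <- list()
  for (k in seq_along(params)) {
    cmb <- combn(params, k, simplify = FALSE)
    for (s in cmb) {
      bad <- FALSE
      if (!is.null(forbidden)) {
        for (r in seq_len(nrow(forbidden))) {
          if (forbidden[[1]][r] %in% s && forbidden[[2]][r] %in% s) bad <- TRUE
        }
      }
      if (!bad) subsets[[length(subsets) + 1]] <- s
    }
  }
  aics <- vapply(subsets, function(s) oracle_logistic(rows, s)$aic, numeric(1))
  d <- aics - min(aics)
  w <- exp(-d / 2); w <- w / sum(w)
  sapply(setNames(params, params), function(p) {
    sum(w[vapply(subsets, function(s) p %in% s, logical(1))])
  })
}

# Tiny SAM text -> sorted, indexed BAM in a temp dir.
sam_to_bam <- function(sam_lines, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  writeLines(sam_lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

# Minimal SAM alignment line; flag 0 = forward, 16 = reverse.
sam_line <- function(qname, flag, chrom, pos, cigar, seq, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Phred 40
  paste(qname, flag, chrom, pos, 60, cigar, "*", 0, 0, seq, qual, sep = "\t")
}

sam_header <- function(contigs) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
}

# Construct a calls set and disjoint truth remainder realizing exact
# TP/FP/FN counts, for table-arithmetic checks.
counts_to_sets <- function(tp, fp, fn, chrom = "chr1") {
  calls <- tibble::tibble(
    chrom = chrom, pos = seq_len(tp + fp) * 10, ref = "A",
    alt = c(rep("G", tp), rep("C", fp))
  )
  truth <- tibble::tibble(
    chrom = chrom,
    pos = c(seq_len(tp) * 10, 1e6 + seq_len(fn) * 10),
    ref = "A", alt = "G"
  )
  if (tp == 0) truth <- truth[truth$pos > 1e6, , drop = FALSE]
  list(calls = calls, truth = truth)
}
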