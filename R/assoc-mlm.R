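#' Centered (VanRaden) kinship matrix
#'
#' K = Z Z' / (2 * sum(p*q)) with Z the dosage matrix centered by twice the
#' allele frequency. Missing dosages are mean-imputed before centering.
#'
#' @param g genotype_matrix.
#' @return symmetric n x n matrix of class `kinship_matrix` (plain matrix
#'   with sample ids as dimnames).
#' @export
kinship <- function(g) {
  d <- g$dosages
  storage.mode(d) <- "double"
  p <- allele_stats(g)$alt_freq
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("kinship needs polymorphic variants")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- (2 * p)[idx[, 2]]
  }
  Z <- sweep(d, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(sample_ids(g), sample_ids(g))
  K
}

## Internal: negative REML log-likelihood profile in delta = s2e/s2g on
## eigen-rotated data (EMMA parameterization). lam = eigenvalues of K,
## ys/Xs = rotated response/fixed effects.
reml_negll <- function(log_delta, lam, ys, Xs) {
  delta <- exp(log_delta)
  w <- 1 / (lam + delta)
  n <- length(ys); p <- ncol(Xs)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  qrx <- qr(Xw)
  res <- qr.resid(qrx, yw)
  rss <- sum(res^2)
  ldXtWX <- sum(log(abs(diag(qr.R(qrx)))^2))
  0.5 * ((n - p) * log(rss) - sum(log(w)) + ldXtWX)
}

## Internal: one-time spectral machinery for mixed-model scans.
mlm_setup <- function(y, X, K) {
  keep <- is.finite(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; K <- K[keep, keep]
  eg <- eigen(K, symmetric = TRUE)
  lam <- eg$values
  if (any(lam < -1e-8)) warning("kinship not PSD; eigenvalues floored at 0")
  lam <- pmax(lam, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  grid <- seq(-10, 10, length.out = 100)
  nll <- vapply(grid, reml_negll, numeric(1), lam = lam, ys = ys, Xs = Xs)
  i <- which.min(nll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(reml_negll, c(lo, hi), lam = lam, ys = ys, Xs = Xs)
  delta <- exp(opt$minimum)
  list(keep = keep, U = U, lam = lam, ys = ys, Xs = Xs, delta = delta)
}

## Internal: GLS scan of rotated SNP columns given a setup.
mlm_gls <- function(setup, Gs) {
  w <- 1 / (setup$lam + setup$delta)
  sw <- sqrt(w)
  yw <- setup$ys * sw
  Xw <- setup$Xs * sw
  Gw <- Gs * sw
  qrx <- qr(Xw)
  yr <- qr.resid(qrx, yw)
  Gr <- qr.resid(qrx, Gw)
  gss <- colSums(Gr^2)
  gty <- colSums(Gr * yr)
  n <- length(yw); p <- ncol(Xw)
  df <- n - p - 1
  beta <- gty / gss
  rss <- sum(yr^2) - beta^2 * gss
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  zero <- !is.finite(gss) | gss < 1e-10
  beta[zero] <- se[zero] <- NA_real_
  pval[zero] <- NA_real_
  list(beta = beta, se = se, p = pval, df = df)
}

#' Mixed-model association scan (EMMA-style)
#'
#' Single-locus mixed linear model with fixed covariates (intercept +
#' population structure Q) and a random polygenic term with covariance K.
#' The variance ratio delta = s2_e/s2_g is REML-estimated once under the
#' null (no SNP) by profiling on a 100-point log-delta grid with local
#' refinement; each SNP is then tested by generalized least squares on the
#' eigen-rotated data (Wald t-test).
#'
#' @param g genotype_matrix.
#' @param y numeric phenotype vector aligned to the samples of `g` (NA
#'   drops the sample).
#' @param Q_covariates fixed structure covariates (n x q matrix); default
#'   uses the first 3 genotype PCs.
#' @param K kinship matrix; default [kinship()] of `g`.
#' @param min_maf variants below this MAF are excluded from the scan.
#' @param cofactor_ids variant ids forced into the fixed part (used by
#'   [mlmm_scan()]).
#' @return data.frame of class `scan_result`: `id`, `chrom`, `pos`, `maf`,
#'   `effect`, `stderr`, `p_value`; attributes `model`, `delta`,
#'   `pve_polygenic` (s2_g/(s2_g + s2_e) = 1/(1 + delta)), `n`.
#' @export
mlm_scan <- function(g, y, Q_covariates = NULL, K = NULL, min_maf = 0.03,
                     cofactor_ids = character()) {
  if (is.null(K)) K <- kinship(g)
  if (is.null(Q_covariates)) {
    pc <- snp_pca(g, min_maf = min_maf, n_pcs = 3)
    Q_covariates <- pc$scores
  }
  st <- allele_stats(g)
  keep_v <- !is.na(st$maf) & st$maf >= min_maf & st$maf > 0
  keep_v[match(cofactor_ids, st$id)] <- FALSE  # cofactors move to fixed part
  D <- g$dosages
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- (2 * st$alt_freq)[idx[, 2]]
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(Q_covariates))
  if (length(cofactor_ids)) {
    cof <- D[, match(cofactor_ids, st$id), drop = FALSE]
    colnames(cof) <- cofactor_ids
    X <- cbind(X, cof)
  }
  setup <- mlm_setup(y, X, K)
  Gs <- crossprod(setup$U, D[setup$keep, keep_v, drop = FALSE])
  fit <- mlm_gls(setup, Gs)
  res <- data.frame(id = st$id[keep_v], chrom = st$chrom[keep_v],
                    pos = st$pos[keep_v], maf = st$maf[keep_v],
                    effect = fit$beta, stderr = fit$se, p_value = fit$p,
                    stringsAsFactors = FALSE)
  class(res) <- c("scan_result", "data.frame")
  attr(res, "model") <- if (length(cofactor_ids)) "MLM+cofactors" else "MLM"
  attr(res, "delta") <- setup$delta
  attr(res, "pve_polygenic") <- 1 / (1 + setup$delta)
  attr(res, "cofactors") <- cofactor_ids
  attr(res, "n") <- sum(setup$keep)
  res
}

#' Genomic inflation factor of a scan
#'
#' lambda = median(chi2(p)) / qchisq(0.5, 1).
#'
#' @param scan scan_result (or numeric p-values).
#' @return lambda.
#' @export
genomic_inflation <- function(scan) {
  p <- if (is.numeric(scan)) scan else scan$p_value
  p <- p[is.finite(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}

#' Multi-locus mixed-model scan (MLMM)
#'
#' Forward stepwise extension of [mlm_scan()]: at each step the most
#' significant SNP with p below the threshold is added as a fixed
#' cofactor, the variance components are re-estimated, and any cofactor
#' whose own p-value rises above the threshold is removed (backward step).
#' The reported scan is from the final forward model.
#'
#' @inheritParams mlm_scan
#' @param max_cofactors maximum number of forward steps.
#' @param threshold inclusion p-value threshold; default is the Bonferroni
#'   level 0.05 / number of tested markers.
#' @return `scan_result` of the final model with attributes `cofactors`
#'   (selected ids in inclusion order) and `path` (data.frame of step,
#'   id, p at inclusion).
#' @export
mlmm_scan <- function(g, y, Q_covariates = NULL, K = NULL, min_maf = 0.03,
                      max_cofactors = 10, threshold = NULL) {
  if (is.null(K)) K <- kinship(g)
  if (is.null(Q_covariates)) {
    pc <- snp_pca(g, min_maf = min_maf, n_pcs = 3)
    Q_covariates <- pc$scores
  }
  st <- allele_stats(g)
  m <- sum(!is.na(st$maf) & st$maf >= min_maf & st$maf > 0)
  if (is.null(threshold)) threshold <- 0.05 / m
  cof <- character()
  path <- data.frame(step = integer(), id = character(), p = numeric(),
                     stringsAsFactors = FALSE)
  scan <- mlm_scan(g, y, Q_covariates, K, min_maf)
  for (step in seq_len(max_cofactors)) {
    pmin_ <- suppressWarnings(min(scan$p_value, na.rm = TRUE))
    if (!is.finite(pmin_) || pmin_ > threshold) break
    best <- scan$id[which.min(scan$p_value)]
    cof <- c(cof, best)
    path <- rbind(path, data.frame(step = step, id = best, p = pmin_,
                                   stringsAsFactors = FALSE))
    scan <- mlm_scan(g, y, Q_covariates, K, min_maf, cofactor_ids = cof)
    # backward: drop cofactors that lost significance in the joint model
    if (length(cof) > 1) {
      pc_ <- cofactor_pvalues(g, y, Q_covariates, K, min_maf, cof)
      weak <- names(pc_)[pc_ > threshold]
      if (length(weak)) {
        cof <- setdiff(cof, weak)
        scan <- mlm_scan(g, y, Q_covariates, K, min_maf, cofactor_ids = cof)
      }
    }
  }
  attr(scan, "model") <- "MLMM"
  attr(scan, "cofactors") <- cof
  attr(scan, "path") <- path
  attr(scan, "threshold") <- threshold
  scan
}

## Internal: Wald p of each cofactor within the joint fixed model.
cofactor_pvalues <- function(g, y, Q, K, min_maf, cof) {
  st <- allele_stats(g)
  D <- g$dosages
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- (2 * st$alt_freq)[idx[, 2]]
  }
  out <- setNames(numeric(length(cof)), cof)
  for (cid in cof) {
    others <- setdiff(cof, cid)
    X <- cbind(1, as.matrix(Q))
    if (length(others)) X <- cbind(X, D[, match(others, st$id), drop = FALSE])
    setup <- mlm_setup(y, X, K)
    Gs <- crossprod(setup$U, D[setup$keep, match(cid, st$id), drop = FALSE])
    out[cid] <- mlm_gls(setup, Gs)$p
  }
  out
}
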