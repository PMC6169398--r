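#' Redundancy-analysis R-squared of a multivariate response
#'
#' Multivariate least squares of the column-centered response matrix Y on
#' (intercept + standardized predictors). The fit is computed through the
#' n x n projection (QR of the predictor matrix), so a wide Y (m >> n) is
#' cheap: R2 = trace(SS_fitted)/trace(SS_total), and the Ezekiel adjustment
#' adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1).
#'
#' @param Y n x m numeric response matrix (genotype dosages; centered
#'   internally, missing values mean-imputed).
#' @param X n x p predictor matrix or data.frame.
#' @return list with `r2`, `adj_r2`, `rank` (predictor rank used, excluding
#'   the intercept). Collinear predictor columns are dropped with a
#'   warning.
#' @export
rda_r2 <- function(Y, X) {
  pr <- rda_prepare(Y, X)
  ss_fit <- sum(crossprod(pr$Q, pr$Yc)^2)
  r2 <- ss_fit / pr$ss_tot
  list(r2 = r2, adj_r2 = adjust_r2(r2, pr$n, pr$rank), rank = pr$rank)
}

## Internal: center/impute Y, standardize X, return the orthonormal basis
## of the (intercept-residualized) predictor space.
rda_prepare <- function(Y, X) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  Xs <- scale(X)
  const <- !is.finite(colSums(Xs)) | apply(X, 2, function(v) sd(v) == 0)
  if (any(const)) {
    warning("dropping constant predictor column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    Xs <- Xs[, !const, drop = FALSE]
  }
  qr_ <- qr(cbind(1, Xs))
  rank <- qr_$rank - 1
  if (rank < ncol(Xs))
    warning("rank-deficient predictors: using rank ", rank, " of ", ncol(Xs))
  if (rank >= n - 1) stop("predictor rank must be < n - 1")
  Q <- qr.Q(qr_)[, 2:(rank + 1), drop = FALSE]
  list(Q = Q, Yc = Yc, ss_tot = sum(Yc^2), n = n, rank = rank)
}

adjust_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Two-set variance partitioning of SNP variation
#'
#' Partitions the adjusted R-squared of the genotype matrix into the
#' fraction explained uniquely by climate [a], jointly (collinear) by
#' climate and space [b], uniquely by space [c], and the residual, from the
#' three RDA fits \{climate\}, \{space\} and \{climate + space\}:
#' a = adjR2(c+s) - adjR2(s); c = adjR2(c+s) - adjR2(c);
#' b = adjR2(c) + adjR2(s) - adjR2(c+s); residual = 1 - adjR2(c+s).
#' The four fractions sum to 1 by construction. Negative adjusted
#' fractions are reported as computed.
#'
#' @param Y n x m genotype dosage matrix.
#' @param X_climate n x p climate predictor matrix.
#' @param X_space n x 2 spatial predictor matrix (latitude, longitude).
#' @return list of class `varpart_result` with the fractions, the three
#'   adjusted R2 values, and slots for the permutation test (filled by
#'   [permute_collinear_test()]).
#' @export
varpart2 <- function(Y, X_climate, X_space) {
  fits <- varpart2_fits(Y, X_climate, X_space)
  res <- varpart2_fractions(fits$adj)
  structure(c(res, list(adj_r2 = fits$adj, n = fits$n,
                        n_permutations = NULL, perm_p_collinear = NULL,
                        perm_null_values = NULL)),
            class = "varpart_result")
}

## Internal: the three model fits sharing one prepared Y.
varpart2_fits <- function(Y, X_climate, X_space) {
  Xc <- as.matrix(X_climate); Xs <- as.matrix(X_space)
  prc <- rda_prepare(Y, Xc)
  prs <- rda_prepare(Y, Xs)
  prb <- rda_prepare(Y, cbind(Xc, Xs))
  Yc <- prb$Yc; ss <- prb$ss_tot; n <- prb$n
  adj <- c(climate = adjust_r2(sum(crossprod(prc$Q, Yc)^2) / ss, n, prc$rank),
           space = adjust_r2(sum(crossprod(prs$Q, Yc)^2) / ss, n, prs$rank),
           both = adjust_r2(sum(crossprod(prb$Q, Yc)^2) / ss, n, prb$rank))
  list(adj = adj, n = n, Yc = Yc, ss = ss,
       Q = list(climate = prc$Q, space = prs$Q, both = prb$Q),
       ranks = c(prc$rank, prs$rank, prb$rank))
}

varpart2_fractions <- function(adj) {
  list(frac_climate_unique = unname(adj["both"] - adj["space"]),
       frac_collinear = unname(adj["climate"] + adj["space"] - adj["both"]),
       frac_space_unique = unname(adj["both"] - adj["climate"]),
       frac_residual = unname(1 - adj["both"]))
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("RDA variance partitioning (adjusted R2 fractions):\n")
  cat(sprintf("  climate unique [a]     : %7.4f\n", x$frac_climate_unique))
  cat(sprintf("  climate~space [b]      : %7.4f\n", x$frac_collinear))
  cat(sprintf("  space unique [c]       : %7.4f\n", x$frac_space_unique))
  cat(sprintf("  residual               : %7.4f\n", x$frac_residual))
  if (!is.null(x$perm_p_collinear))
    cat(sprintf("  permutation p ([b], %d perms): %.4g\n",
                x$n_permutations, x$perm_p_collinear))
  invisible(x)
}

#' Permutation test for the climate-collinear fraction
#'
#' Re-fits the variance partition after jointly shuffling the rows of the
#' genotype matrix against both predictor sets (randomizing individuals),
#' and reports the upper-tail add-one permutation p-value for the
#' collinear fraction [b]:
#' p = (1 + #\{permuted b >= observed b\}) / (n_perm + 1).
#'
#' @inheritParams varpart2
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return `varpart_result` with `perm_p_collinear`, `perm_null_values` and
#'   `n_permutations` filled in.
#' @export
permute_collinear_test <- function(Y, X_climate, X_space, n_perm = 1000,
                                   seed = 1) {
  stopifnot(n_perm >= 99)
  fits <- varpart2_fits(Y, X_climate, X_space)
  obs <- varpart2_fractions(fits$adj)
  set.seed(seed)
  n <- fits$n
  ranks <- fits$ranks
  Yc <- fits$Yc; ss <- fits$ss; Q <- fits$Q
  null_b <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    Yp <- Yc[sample.int(n), , drop = FALSE]
    a3 <- c(adjust_r2(sum(crossprod(Q$climate, Yp)^2) / ss, n, ranks[1]),
            adjust_r2(sum(crossprod(Q$space, Yp)^2) / ss, n, ranks[2]),
            adjust_r2(sum(crossprod(Q$both, Yp)^2) / ss, n, ranks[3]))
    null_b[i] <- a3[1] + a3[2] - a3[3]
  }
  p <- (1 + sum(null_b >= obs$frac_collinear)) / (n_perm + 1)
  structure(c(obs, list(adj_r2 = fits$adj, n = n,
                        n_permutations = n_perm, perm_p_collinear = p,
                        perm_null_values = null_b)),
            class = "varpart_result")
}
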