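#' Naive environmental association scan (GLM)
#'
#' Per-SNP simple linear regression of the environmental variable on the
#' allele dosage, with no structure or kinship correction (deliberately,
#' to avoid the false negatives that structure correction causes for
#' clinal variables). Closed-form least squares on pairwise-complete
#' samples with a t-test p-value; the direction of the regression is
#' immaterial for the p-value.
#'
#' @param g genotype_matrix.
#' @param env_values numeric vector aligned to the samples of `g`.
#' @param min_maf variants below this minor allele frequency are skipped.
#' @return `scan_result` data.frame (`effect` is the slope of env on
#'   dosage), zero-variance SNPs skipped.
#' @export
glm_scan <- function(g, env_values, min_maf = 0.03) {
  stopifnot(length(env_values) == nrow(g$dosages))
  keep_s <- is.finite(env_values)
  d <- g$dosages[keep_s, , drop = FALSE]
  storage.mode(d) <- "double"
  env <- env_values[keep_s]
  st <- allele_stats(g[keep_s, ])
  called <- !is.na(d)
  dz <- d; dz[!called] <- 0
  n <- colSums(called)
  sx <- colSums(dz)
  sxx <- colSums(dz^2)
  sy <- colSums(env * called)
  syy <- colSums(env^2 * called)
  sxy <- colSums(env * dz)
  Sxx <- sxx - sx^2 / n
  Syy <- syy - sy^2 / n
  Sxy <- sxy - sx * sy / n
  ok <- !is.na(st$maf) & st$maf >= min_maf & Sxx > 1e-12 & n > 2
  beta <- Sxy / Sxx
  rss <- Syy - beta * Sxy
  se <- sqrt(pmax(rss, 0) / ((n - 2) * Sxx))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), n - 2)
  pval[se == 0] <- 0          # exact linear relationship
  res <- data.frame(id = st$id[ok], chrom = st$chrom[ok], pos = st$pos[ok],
                    maf = st$maf[ok], effect = beta[ok], stderr = se[ok],
                    p_value = pval[ok], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("scan_result", "data.frame")
  attr(res, "model") <- "GLM"
  attr(res, "n") <- sum(keep_s)
  res
}

#' Flag empirical outliers of an association scan
#'
#' Flags the SNPs whose p-value lies at or below the empirical `quantile`
#' of the scan's p-values (type-1 quantile, so without ties exactly
#' `quantile * m` SNPs are flagged; ties at the cutoff are all included).
#'
#' @param scan scan_result.
#' @param quantile outlier fraction (default top 1%).
#' @return the scan with a logical `outlier` column; attribute
#'   `outlier_cutoff` holds the p-value cutoff.
#' @export
select_outliers <- function(scan, quantile = 0.01) {
  p <- scan$p_value
  cutoff <- stats::quantile(p, probs = quantile, type = 1, na.rm = TRUE,
                            names = FALSE)
  out <- !is.na(p) & p <= cutoff
  if (all(out[!is.na(p)]))
    warning("all p-values tied at the cutoff; every SNP flagged")
  scan$outlier <- out
  attr(scan, "outlier_cutoff") <- cutoff
  attr(scan, "n_outliers") <- sum(out)
  scan
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("%s scan: %d SNPs", attr(x, "model") %||% "association",
              nrow(x)))
  if (!is.null(attr(x, "cofactors")) && length(attr(x, "cofactors")))
    cat(sprintf(", %d cofactor(s): %s", length(attr(x, "cofactors")),
                paste(attr(x, "cofactors"), collapse = ", ")))
  if (!is.null(x$outlier)) cat(sprintf(", %d outlier(s)", sum(x$outlier)))
  cat("\n")
  top <- x[order(x$p_value), , drop = FALSE]
  print(utils::head(as.data.frame(top), 5))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
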