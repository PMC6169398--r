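#' Weir & Cockerham (1984) FST
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) for r populations with
#' unequal sample sizes, from allele frequencies and observed heterozygote
#' proportions. The combined estimate is the ratio of sums
#' sum(a) / sum(a + b + c) (the weighted, VCFtools-style estimator);
#' per-site theta values are also returned, unclamped (negative values are
#' kept, preserving the unbiasedness of the components).
#'
#' @param g genotype_matrix.
#' @param group_labels vector (coercible to factor) of population labels,
#'   one per sample; NA samples are dropped.
#' @param window_bp optional window width; when given, a windowed
#'   ratio-of-sums estimate is returned as well.
#' @return list of class `fst_result`: `per_site` (data.frame with a, b, c,
#'   theta), `global` (ratio-of-sums over all usable sites), `n_sites`,
#'   and `windows` (when `window_bp` is given).
#' @export
weir_cockerham_fst <- function(g, group_labels, window_bp = NULL) {
  grp <- factor(group_labels)
  keep <- !is.na(grp)
  d <- g$dosages[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  r_all <- nlevels(grp)
  if (r_all < 2) stop("need at least two populations")
  m <- ncol(d)
  # per-pop per-site counts (pops x sites)
  pops <- levels(grp)
  ncall <- het <- asum <- matrix(0, nrow = r_all, ncol = m)
  for (i in seq_len(r_all)) {
    di <- d[grp == pops[i], , drop = FALSE]
    ncall[i, ] <- colSums(!is.na(di))
    asum[i, ] <- colSums(di, na.rm = TRUE)
    het[i, ] <- colSums(di == 1L, na.rm = TRUE)
  }
  comp <- wc_components(ncall, asum, het)
  per_site <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                         pos = g$variants$pos,
                         a = comp$a, b = comp$b, c = comp$c,
                         theta = comp$theta, stringsAsFactors = FALSE)
  usable <- !is.na(comp$a) & (comp$a + comp$b + comp$c) != 0
  global <- sum(comp$a[usable]) /
    sum(comp$a[usable] + comp$b[usable] + comp$c[usable])
  out <- list(per_site = per_site, global = global, n_sites = sum(usable))
  if (!is.null(window_bp)) {
    key <- window_key(g$variants$chrom, g$variants$pos, window_bp)
    ksub <- key[usable]
    aa <- tapply(comp$a[usable], ksub, sum)
    tt <- tapply((comp$a + comp$b + comp$c)[usable], ksub, sum)
    parts <- strsplit(names(aa), "\r", fixed = TRUE)
    out$windows <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.numeric(vapply(parts, `[`, "", 2)) * window_bp,
      end = (as.numeric(vapply(parts, `[`, "", 2)) + 1) * window_bp,
      value = as.numeric(aa / tt),
      n_sites = as.integer(table(ksub)[names(aa)]),
      stringsAsFactors = FALSE)
    out$windows <- out$windows[order(natural_chrom_rank(out$windows$chrom),
                                     out$windows$start), ]
    rownames(out$windows) <- NULL
  }
  class(out) <- "fst_result"
  out
}

## Internal: vectorized W&C 1984 components from per-pop counts.
## ncall: diploid calls per pop x site; asum: ALT allele sums; het:
## heterozygote counts. Sites with < 2 pops having calls, or nbar <= 1,
## yield NA components.
wc_components <- function(ncall, asum, het) {
  present <- ncall > 0
  r_eff <- colSums(present)
  n_tot <- colSums(ncall)
  p <- ifelse(ncall > 0, asum / (2 * ncall), 0)
  hprop <- ifelse(ncall > 0, het / ncall, 0)
  nbar <- n_tot / r_eff
  pbar <- colSums(ncall * p) / n_tot
  s2 <- colSums(ncall * (p - rep(pbar, each = nrow(ncall)))^2 * present) /
    ((r_eff - 1) * nbar)
  hbar <- colSums(ncall * hprop) / n_tot
  nc <- (n_tot - colSums(ncall^2) / n_tot) / (r_eff - 1)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 -
                            hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  bad <- r_eff < 2 | nbar <= 1 | nc <= 0
  a[bad] <- b[bad] <- c_[bad] <- NA_real_
  denom <- a + b + c_
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = c_, theta = theta)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST (ratio of sums over %d sites): %.4f\n",
              x$n_sites, x$global))
  invisible(x)
}
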