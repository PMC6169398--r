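#' Per-variant allele statistics
#'
#' Frequencies are computed on non-missing calls only.
#'
#' @param g genotype_matrix.
#' @return data.frame with one row per variant: `id`, `chrom`, `pos`,
#'   `alt_freq`, `maf`, `mac` (minor allele count), `missing_rate`,
#'   `n_called` (non-missing diploid calls). All-missing sites get NA
#'   frequencies.
#' @export
allele_stats <- function(g) {
  d <- g$dosages
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  mac <- pmin(alt, 2 * n_called - alt)
  data.frame(id = g$variants$id, chrom = g$variants$chrom,
             pos = g$variants$pos,
             alt_freq = p, maf = pmin(p, 1 - p), mac = mac,
             missing_rate = 1 - n_called / nrow(d),
             n_called = n_called,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter variants on missingness, frequency and polymorphism
#'
#' Rules are applied in sequence (missingness, monomorphic, minor allele
#' count, minor allele frequency) and the per-rule removal counts reported.
#' A minor-allele-count threshold of 3 removes singletons and doubletons.
#'
#' @param g genotype_matrix.
#' @param max_missing maximum tolerated per-site missing fraction; sites
#'   with a strictly larger fraction are removed.
#' @param min_maf minimum minor allele frequency (0 disables).
#' @param min_mac minimum minor allele count (0 disables).
#' @param drop_monomorphic remove sites with no observed polymorphism.
#' @return list with `genotypes` (filtered genotype_matrix; may have zero
#'   variants, with a warning) and `report` (named removal counts).
#' @export
filter_variants <- function(g, max_missing = 0.2, min_maf = 0, min_mac = 0,
                            drop_monomorphic = TRUE) {
  st <- allele_stats(g)
  keep <- rep(TRUE, nrow(st))
  report <- c(missingness = 0L, monomorphic = 0L, mac = 0L, maf = 0L)
  r1 <- keep & (st$missing_rate > max_missing | st$n_called == 0)
  report["missingness"] <- sum(r1); keep <- keep & !r1
  if (drop_monomorphic) {
    r2 <- keep & (is.na(st$maf) | st$maf == 0)
    report["monomorphic"] <- sum(r2); keep <- keep & !r2
  }
  if (min_mac > 0) {
    r3 <- keep & st$mac < min_mac
    report["mac"] <- sum(r3); keep <- keep & !r3
  }
  if (min_maf > 0) {
    r4 <- keep & (is.na(st$maf) | st$maf < min_maf)
    report["maf"] <- sum(r4); keep <- keep & !r4
  }
  if (!any(keep)) warning("all variants removed by filters")
  list(genotypes = g[, keep], report = report,
       n_in = nrow(st), n_out = sum(keep))
}

## Internal: per-site unbiased pairwise diversity from dosages.
## pi_site = 2 * c_alt * c_ref / (n_al * (n_al - 1)) with n_al = called
## allele count; equals the average pairwise difference among the 2n
## sampled allele copies.
site_pi <- function(d) {
  n_al <- 2 * colSums(!is.na(d))
  ca <- colSums(d, na.rm = TRUE)
  cr <- n_al - ca
  out <- ifelse(n_al > 1, 2 * ca * cr / (n_al * (n_al - 1)), NA_real_)
  out
}

## Internal: assign variants to half-open windows tiling each chromosome
## from position 0 ([0, w), [w, 2w), ...); returns per-variant window key.
window_key <- function(chrom, pos, window_bp) {
  idx <- (pos - 1L) %/% as.integer(window_bp)
  paste(chrom, idx, sep = "\r")
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site unbiased pairwise diversity 2*p*q*2n/(2n - 1) is summed over the
#' sites of each window and divided by the window width in bp (per-bp
#' convention). Windows tile each chromosome from position 0, half-open;
#' the trailing partial window is kept with the nominal width as
#' denominator. Windows containing no segregating site get pi = 0 only if
#' they fall inside the tiled span (windows are emitted from 0 up to the
#' last variant-bearing window of each chromosome).
#'
#' @param g genotype_matrix (variants sorted).
#' @param window_bp window width in bp.
#' @return data.frame of class `window_stat`: `chrom`, `start`, `end`
#'   (0-based half-open), `value` (pi per bp), `n_sites` (segregating sites
#'   used).
#' @export
nucleotide_diversity_windows <- function(g, window_bp = 1000) {
  v <- g$variants
  pis <- site_pi(g$dosages)
  seg <- !is.na(pis) & pis > 0
  out <- list()
  for (chr in unique(v$chrom)) {
    sel <- v$chrom == chr
    idx <- (v$pos[sel] - 1L) %/% as.integer(window_bp)
    last <- max(idx)
    val <- nsit <- numeric(last + 1)
    agg <- tapply(pis[sel], idx, sum, na.rm = TRUE)
    cnt <- tapply(seg[sel], idx, sum)
    val[as.integer(names(agg)) + 1] <- agg
    nsit[as.integer(names(cnt)) + 1] <- cnt
    out[[chr]] <- data.frame(chrom = chr,
                             start = (0:last) * window_bp,
                             end = (0:last + 1) * window_bp,
                             value = val / window_bp, n_sites = nsit,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_stat", "data.frame")
  attr(res, "stat") <- "pi"
  res
}

## Internal: Tajima (1989) constants for n sampled chromosomes.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from site counts
#'
#' Core evaluation of D = (pi_sum - S/a1) / sqrt(e1*S + e2*S*(S-1)) with the
#' Tajima (1989) constants for `n` sampled chromosomes.
#'
#' @param S number of segregating sites.
#' @param pi_sum sum over sites of the average pairwise difference.
#' @param n number of sampled chromosomes (allele copies).
#' @return D, or NA when S = 0, n < 4 or the variance term is zero.
#' @export
tajima_d <- function(S, pi_sum, n) {
  if (is.na(S) || S == 0 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  vr <- k$e1 * S + k$e2 * S * (S - 1)
  if (vr <= 0) return(NA_real_)
  (pi_sum - S / k$a1) / sqrt(vr)
}

#' Tajima's D for a haplotype matrix
#'
#' @param H binary matrix, rows = chromosomes, columns = sites.
#' @return D (NA when no site segregates).
#' @export
tajima_d_haplotypes <- function(H) {
  n <- nrow(H)
  c1 <- colSums(H)
  seg <- c1 > 0 & c1 < n
  S <- sum(seg)
  pi_sum <- sum(2 * c1[seg] * (n - c1[seg]) / (n * (n - 1)))
  tajima_d(S, pi_sum, n)
}

#' Windowed Tajima's D
#'
#' Windows tile each chromosome from 0, half-open. Within a window, S is
#' the number of segregating sites, pi_sum the summed per-site average
#' pairwise difference, and the chromosome count is twice the mean
#' non-missing diploid count over the window's segregating sites (rounded);
#' with complete data this is simply 2n.
#'
#' @param g genotype_matrix.
#' @param window_bp window width in bp.
#' @param min_sites windows with fewer segregating sites get NA.
#' @return `window_stat` data.frame (`value` = D, `n_sites` = S).
#' @export
tajima_d_windows <- function(g, window_bp = 1e5, min_sites = 3) {
  v <- g$variants
  d <- g$dosages
  pis <- site_pi(d)
  nc <- colSums(!is.na(d))
  p <- allele_stats(g)$alt_freq
  seg <- !is.na(p) & p > 0 & p < 1
  out <- list()
  for (chr in unique(v$chrom)) {
    sel <- which(v$chrom == chr)
    idx <- (v$pos[sel] - 1L) %/% as.integer(window_bp)
    last <- max(idx)
    res <- data.frame(chrom = chr, start = (0:last) * window_bp,
                      end = (0:last + 1) * window_bp,
                      value = NA_real_, n_sites = 0L,
                      stringsAsFactors = FALSE)
    for (w in unique(idx)) {
      ss <- sel[idx == w & seg[sel]]
      S <- length(ss)
      res$n_sites[w + 1] <- S
      if (S >= min_sites) {
        nchr <- round(2 * mean(nc[ss]))
        res$value[w + 1] <- tajima_d(S, sum(pis[ss]), nchr)
      }
    }
    out[[chr]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_stat", "data.frame")
  attr(res, "stat") <- "tajima_d"
  res
}
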