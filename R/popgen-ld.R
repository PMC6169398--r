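#' Linkage disequilibrium decay curve
#'
#' Squared Pearson correlation of dosage vectors (pairwise-complete
#' samples) for all same-chromosome variant pairs up to `max_dist_bp`,
#' binned by distance, with a cubic smoothing spline over the bin
#' midpoints (weighted by pair counts). Threshold crossings are read off
#' the smoothed curve by linear interpolation.
#'
#' @param g genotype_matrix (variants sorted).
#' @param max_dist_bp maximum pair distance in bp.
#' @param min_maf variants below this minor allele frequency are excluded.
#' @param bin_bp distance bin width.
#' @param spline_df degrees of freedom of the smoothing spline.
#' @param thresholds r-squared levels at which to report crossing
#'   distances.
#' @return list of class `ld_decay`: `bins` (data.frame with `mid`,
#'   `mean_r2`, `smooth_r2`, `n_pairs`), `crossings` (named distances, NA
#'   when not reached), `half_decay_distance` (where the smoothed curve
#'   first falls to half its initial value).
#' @export
ld_decay <- function(g, max_dist_bp = 2e5, min_maf = 0.05, bin_bp = 5000,
                     spline_df = 10, thresholds = c(0.2, 0.1)) {
  st <- allele_stats(g)
  keep <- !is.na(st$maf) & st$maf >= min_maf
  g <- g[, keep]
  v <- g$variants
  dist_all <- r2_all <- list()
  for (chr in unique(v$chrom)) {
    sel <- which(v$chrom == chr)
    if (length(sel) < 2) next
    d <- g$dosages[, sel, drop = FALSE]
    sds <- apply(d, 2, sd, na.rm = TRUE)
    ok <- !is.na(sds) & sds > 0
    d <- d[, ok, drop = FALSE]
    pos <- v$pos[sel][ok]
    if (ncol(d) < 2) next
    cc <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
    dm <- abs(outer(pos, pos, `-`))
    ut <- upper.tri(dm)
    inrange <- ut & dm <= max_dist_bp
    dist_all[[chr]] <- dm[inrange]
    r2_all[[chr]] <- cc[inrange]^2
  }
  dist <- unlist(dist_all, use.names = FALSE)
  r2 <- unlist(r2_all, use.names = FALSE)
  ok <- !is.na(r2)
  dist <- dist[ok]; r2 <- r2[ok]
  if (!length(dist)) stop("no usable variant pairs within max_dist_bp")
  bin <- pmin(dist %/% bin_bp, max_dist_bp %/% bin_bp - 1)
  mids <- (sort(unique(bin)) + 0.5) * bin_bp
  mean_r2 <- as.numeric(tapply(r2, bin, mean))
  n_pairs <- as.integer(table(bin))
  smooth_r2 <- if (length(mids) >= 4) {
    sp <- smooth.spline(mids, mean_r2, w = n_pairs,
                        df = min(spline_df, length(mids) - 1))
    pmax(predict(sp, mids)$y, 0)
  } else mean_r2
  crossing <- function(level) {
    below <- which(smooth_r2 <= level)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1) return(mids[1])
    # linear interpolation between the bracketing midpoints
    x0 <- mids[i - 1]; x1 <- mids[i]
    y0 <- smooth_r2[i - 1]; y1 <- smooth_r2[i]
    x0 + (y0 - level) / (y0 - y1) * (x1 - x0)
  }
  crossings <- vapply(thresholds, crossing, numeric(1))
  names(crossings) <- paste0("r2_", thresholds)
  structure(list(bins = data.frame(mid = mids, mean_r2 = mean_r2,
                                   smooth_r2 = smooth_r2, n_pairs = n_pairs),
                 crossings = crossings,
                 half_decay_distance = crossing(smooth_r2[1] / 2),
                 n_pairs_total = length(r2)),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay over %d pairs; r2[first bin] = %.3f\n",
              x$n_pairs_total, x$bins$smooth_r2[1]))
  for (nm in names(x$crossings))
    cat(sprintf("  %s crossed at %s bp\n", nm,
                format(round(x$crossings[[nm]]))))
  invisible(x)
}

#' Per-sample heterozygosity and inbreeding
#'
#' Observed heterozygosity is the fraction of a sample's non-missing calls
#' that are heterozygous. The inbreeding coefficient is the
#' method-of-moments F = 1 - O(het)/E(het), with E(het) the sum of 2*p*q
#' (panel-wide allele frequencies) over that sample's non-missing sites.
#'
#' @param g genotype_matrix.
#' @return data.frame of class `sample_qc`: `sample_id`, `n_called`,
#'   `observed_het`, `inbreeding_f` (NA when the sample covers no
#'   polymorphic site).
#' @export
sample_qc <- function(g) {
  d <- g$dosages
  p <- allele_stats(g)$alt_freq
  ehet_site <- 2 * p * (1 - p)
  ehet_site[is.na(ehet_site)] <- 0
  called <- !is.na(d)
  n_called <- rowSums(called)
  o_het <- rowSums(d == 1L, na.rm = TRUE)
  e_het <- as.vector(called %*% ehet_site)
  f <- ifelse(e_het > 0, 1 - o_het / e_het, NA_real_)
  data.frame(sample_id = rownames(d), n_called = n_called,
             observed_het = ifelse(n_called > 0, o_het / n_called, NA_real_),
             inbreeding_f = f, stringsAsFactors = FALSE, row.names = NULL)
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` variants with step `step` along each
#' chromosome; within a window, for every pair of still-kept variants with
#' r-squared above the threshold the later-position variant is dropped.
#'
#' @param g genotype_matrix (variants sorted).
#' @param r2_threshold squared-correlation threshold.
#' @param window window size in number of variants.
#' @param step slide step in number of variants.
#' @return pruned genotype_matrix.
#' @export
ld_prune <- function(g, r2_threshold = 0.5, window = 50, step = 25) {
  v <- g$variants
  keep <- rep(TRUE, nrow(v))
  for (chr in unique(v$chrom)) {
    sel <- which(v$chrom == chr)
    starts <- seq(1, max(1, length(sel) - 1), by = step)
    for (s in starts) {
      win <- sel[s:min(s + window - 1, length(sel))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      d <- g$dosages[, win, drop = FALSE]
      cc <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
      for (i in seq_len(length(win) - 1)) {
        if (!keep[win[i]]) next
        drop <- which(cc[i, ] > r2_threshold & seq_along(win) > i &
                        keep[win])
        keep[win[drop]] <- FALSE
      }
      if (s + window - 1 >= length(sel)) break
    }
  }
  g[, keep]
}
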