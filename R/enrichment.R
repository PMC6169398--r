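#' Colocalize outlier SNPs or windows with genes
#'
#' A gene is "hit" when the minimum distance between the gene interval and
#' any point is at most `window_bp` (0 when overlapping). All interval
#' arithmetic is 0-based half-open; a SNP at 1-based position p occupies
#' [p-1, p), so the distance to a gene ending at (half-open) e is p-1-e
#' when the SNP lies beyond the gene.
#'
#' @param points data.frame with `chrom` and either `pos` (1-based SNP
#'   position) or `start`/`end` (0-based half-open windows).
#' @param genes gene_annotation data.frame.
#' @param window_bp maximum hit distance in bp.
#' @return list of class `coloc_result`: `genes` (annotation plus `hit`,
#'   `min_distance`), `points` (per-point nearest gene and distance),
#'   `window_bp`.
#' @export
colocalize <- function(points, genes, window_bp = 1e5) {
  stopifnot("chrom" %in% names(points))
  if ("pos" %in% names(points)) {
    ps <- points$pos - 1L
    pe <- points$pos
  } else {
    stopifnot(all(c("start", "end") %in% names(points)))
    ps <- points$start
    pe <- points$end
  }
  off <- setdiff(unique(points$chrom), unique(genes$chrom))
  if (length(off))
    stop("point chromosome(s) absent from annotation: ",
         paste(off, collapse = ", "))
  ng <- nrow(genes); np <- nrow(points)
  gene_min <- rep(Inf, ng)
  point_min <- rep(Inf, np)
  point_gene <- rep(NA_character_, np)
  for (chr in unique(points$chrom)) {
    gi <- which(genes$chrom == chr)
    pi <- which(points$chrom == chr)
    if (!length(gi)) next
    # pairwise gap between [gs, ge) and [ps, pe): max(0, gs - pe, ps - ge)
    gap <- pmax(outer(genes$start[gi], pe[pi], `-`),
                outer(-genes$end[gi], ps[pi], `+`))
    gap[gap < 0] <- 0
    gene_min[gi] <- pmin(gene_min[gi], apply(gap, 1, min))
    pm <- apply(gap, 2, which.min)
    pd <- gap[cbind(pm, seq_along(pi))]
    point_min[pi] <- pd
    point_gene[pi] <- genes$gene_id[gi][pm]
  }
  gtab <- as.data.frame(genes)
  gtab$min_distance <- ifelse(is.finite(gene_min), gene_min, NA_real_)
  gtab$hit <- !is.na(gtab$min_distance) & gtab$min_distance <= window_bp
  ptab <- as.data.frame(points)
  ptab$nearest_gene <- point_gene
  ptab$distance <- point_min
  structure(list(genes = gtab, points = ptab, window_bp = window_bp),
            class = "coloc_result")
}

#' Chi-square enrichment of candidate genes among hits
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of gene
#' class (a-priori candidate vs other) by hit status.
#'
#' @param candidate_hits logical vector: hit flag of each candidate gene.
#' @param all_gene_hits logical vector: hit flag of every annotated gene
#'   (candidates included).
#' @return list of class `enrichment_result` with counts, proportions,
#'   `chi2_statistic` and `chi2_p` (NA with a warning when an expected
#'   cell is zero).
#' @export
chisq_enrichment <- function(candidate_hits, all_gene_hits) {
  nc <- length(candidate_hits); na_ <- length(all_gene_hits)
  stopifnot(nc <= na_)
  ch <- sum(candidate_hits)
  ah <- sum(all_gene_hits)
  tab <- matrix(c(ch, nc - ch, ah - ch, (na_ - nc) - (ah - ch)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "other"), c("hit", "no_hit")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    warning("zero expected cell; chi-square p unavailable")
    stat <- p <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- unname(ct$p.value)
  }
  structure(list(n_candidates_hit = ch, n_candidates = nc,
                 n_all_genes_hit = ah, n_all_genes = na_,
                 prop_candidates = ch / nc, prop_all = ah / na_,
                 table = tab, chi2_statistic = stat, chi2_p = p,
                 perm_p = NULL, n_perm = NULL, null_hit_counts = NULL),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d candidates hit (%.1f%%) vs %d/%d genes (%.1f%%)\n",
              x$n_candidates_hit, x$n_candidates, 100 * x$prop_candidates,
              x$n_all_genes_hit, x$n_all_genes, 100 * x$prop_all))
  if (!is.null(x$chi2_statistic) && is.finite(x$chi2_statistic))
    cat(sprintf("  chi-square = %.3f, p = %.4g\n", x$chi2_statistic,
                x$chi2_p))
  if (!is.null(x$perm_p))
    cat(sprintf("  permutation p (%d perms) = %.4g\n", x$n_perm, x$perm_p))
  invisible(x)
}

#' Whole-genome gene-permutation enrichment for Tajima's D
#'
#' Observed statistic: number of candidate genes overlapping windows with
#' D above `d_threshold` (default 0, i.e. "positive-D windows"). The null
#' draws the same number of genes uniformly without replacement from all
#' annotated genes, `n_perm` times; p is the upper-tail add-one
#' permutation p-value.
#'
#' @param window_stats `window_stat` data.frame from [tajima_d_windows()].
#' @param genes gene_annotation.
#' @param candidate_ids character vector of candidate gene ids (subset of
#'   `genes$gene_id`).
#' @param d_threshold windows with `value > d_threshold` count as high-D.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return `enrichment_result` with `perm_p`, `null_hit_counts`.
#' @export
tajima_gene_permutation <- function(window_stats, genes, candidate_ids,
                                    d_threshold = 0, n_perm = 1000,
                                    seed = 1) {
  stopifnot(all(candidate_ids %in% genes$gene_id))
  if (length(candidate_ids) > nrow(genes))
    stop("more candidates than genes")
  hot <- window_stats[!is.na(window_stats$value) &
                        window_stats$value > d_threshold, , drop = FALSE]
  hit <- gene_window_overlap(genes, hot)
  obs <- sum(hit[match(candidate_ids, genes$gene_id)])
  set.seed(seed)
  k <- length(candidate_ids)
  null_counts <- vapply(seq_len(n_perm), function(i)
    sum(hit[sample.int(nrow(genes), k)]), integer(1))
  p <- (1 + sum(null_counts >= obs)) / (n_perm + 1)
  structure(list(n_candidates_hit = obs, n_candidates = k,
                 n_all_genes_hit = sum(hit), n_all_genes = nrow(genes),
                 prop_candidates = obs / k,
                 prop_all = sum(hit) / nrow(genes),
                 chi2_statistic = NULL, chi2_p = NULL,
                 perm_p = p, n_perm = n_perm,
                 null_hit_counts = null_counts,
                 d_threshold = d_threshold),
            class = "enrichment_result")
}

## Internal: logical per-gene flag for overlap with any listed window
## (both 0-based half-open).
gene_window_overlap <- function(genes, windows) {
  hit <- logical(nrow(genes))
  if (!nrow(windows)) return(hit)
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    wi <- which(windows$chrom == chr)
    if (!length(wi)) next
    ov <- outer(genes$start[gi], windows$end[wi], `<`) &
      outer(genes$end[gi], windows$start[wi], `>`)
    hit[gi] <- rowSums(ov) > 0
  }
  hit
}
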