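#' Principal component analysis of genotypes
#'
#' Columns are centered by twice the allele frequency and optionally scaled
#' by sqrt(2*p*q); missing dosages are mean-imputed (set to 0 after
#' centering). Scores come from the singular value decomposition of the
#' centered matrix, with a deterministic sign convention: in each loading
#' vector the largest-magnitude element is positive.
#'
#' @param g genotype_matrix.
#' @param min_maf variants below this minor allele frequency are excluded
#'   before the decomposition.
#' @param scaling `"none"` (covariance PCA) or `"sd"` (scale columns by
#'   sqrt(2*p*q), Patterson-style).
#' @param n_pcs number of components to return.
#' @return list of class `pca_result`: `scores` (n x n_pcs), `loadings`
#'   (m x n_pcs), `explained` (fraction of total variance per PC, over all
#'   components so the returned head sums to < 1), `variant_ids`.
#' @export
snp_pca <- function(g, min_maf = 0.05, scaling = c("none", "sd"),
                    n_pcs = 10) {
  scaling <- match.arg(scaling)
  st <- allele_stats(g)
  keep <- !is.na(st$maf) & st$maf >= min_maf & st$maf > 0
  if (!any(keep)) stop("no polymorphic variants at min_maf = ", min_maf)
  d <- g$dosages[, keep, drop = FALSE]
  p <- st$alt_freq[keep]
  X <- sweep(d, 2, 2 * p)
  X[is.na(X)] <- 0
  if (scaling == "sd") X <- sweep(X, 2, sqrt(2 * p * (1 - p)), `/`)
  if (all(abs(X) < 1e-12)) stop("zero-variance genotype matrix")
  sv <- svd(X)
  k <- min(n_pcs, length(sv$d))
  expl <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {               # sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(sample_ids(g), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained = expl[seq_len(k)],
                 variant_ids = g$variants$id[keep]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d PCs; explained =", nrow(x$scores),
              ncol(x$scores)),
      paste0(sprintf("%.1f", 100 * x$explained), "%"), "\n")
  invisible(x)
}

#' DAPC-style cluster discovery (k-means on PCs with BIC selection)
#'
#' Runs multi-start k-means on retained principal component scores for
#' k = 1..k_max and selects k by the BIC
#' `n * log(WSS/n) + k * log(n)` (WSS = total within-cluster sum of
#' squares), ties resolved to the smallest k. Linear discriminant axes are
#' then fit on the selected clustering.
#'
#' @param g genotype_matrix.
#' @param k_max largest number of clusters tried (must be < n samples).
#' @param n_pcs_retained number of PCs fed to k-means; default retains
#'   enough PCs for 80% of variance.
#' @param n_starts k-means restarts per k.
#' @param seed integer seed for the k-means initialization stream.
#' @param min_maf passed to [snp_pca()].
#' @return list of class `dapc_result`: `k_selected`, `bic_by_k`,
#'   `assignments` (named integer vector), `discriminant` (sample scores on
#'   the LD axes, NULL when k = 1), `pca`.
#' @export
dapc_find_clusters <- function(g, k_max = 8, n_pcs_retained = NULL,
                               n_starts = 10, seed = 1, min_maf = 0.05) {
  n <- nrow(g$dosages)
  if (k_max >= n) stop("k_max must be smaller than the number of samples")
  pc <- snp_pca(g, min_maf = min_maf, n_pcs = min(n - 1, 40))
  if (is.null(n_pcs_retained)) {
    cum <- cumsum(pc$explained) / sum(pc$explained)
    n_pcs_retained <- max(2, min(which(cum >= 0.8), length(pc$explained)))
  }
  n_pcs_retained <- min(n_pcs_retained, ncol(pc$scores), n - 1)
  S <- pc$scores[, seq_len(n_pcs_retained), drop = FALSE]
  set.seed(seed)
  bic <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      wss <- sum(scale(S, scale = FALSE)^2)
      fits[[k]] <- list(cluster = rep(1L, n))
    } else {
      km <- kmeans(S, centers = k, nstart = n_starts, iter.max = 50)
      wss <- km$tot.withinss
      fits[[k]] <- km
    }
    bic[k] <- n * log(wss / n) + k * log(n)
  }
  k_sel <- which.min(bic)  # which.min takes the first (smallest k) on ties
  cl <- fits[[k_sel]]$cluster
  disc <- NULL
  if (k_sel > 1) {
    ld <- MASS::lda(S, grouping = factor(cl))
    disc <- as.matrix(S %*% ld$scaling)
  }
  structure(list(k_selected = k_sel, bic_by_k = setNames(bic, seq_len(k_max)),
                 assignments = setNames(as.integer(cl), sample_ids(g)),
                 discriminant = disc, n_pcs_retained = n_pcs_retained,
                 pca = pc),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: k = %d selected by BIC (retained %d PCs)\n",
              x$k_selected, x$n_pcs_retained))
  print(table(x$assignments))
  invisible(x)
}

#' Agreement of cluster assignments with reference labels
#'
#' Best-matching fraction of samples assigned to the reference partition
#' over all label permutations (exact for small k via greedy matching on
#' the confusion matrix).
#'
#' @param assign integer/factor assignments.
#' @param truth reference labels, same length.
#' @return fraction in [0, 1].
#' @export
cluster_agreement <- function(assign, truth) {
  tab <- table(assign, truth)
  total <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    total <- total + tab[i[1], i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  total / length(assign)
}

#' Identity-by-state distance matrix
#'
#' Distance = 1 - mean IBS share, where the IBS share of a sample pair at a
#' site is (2 - |d1 - d2|)/2, averaged over sites where both calls are
#' present.
#'
#' @param g genotype_matrix.
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
ibs_distance <- function(g) {
  d <- g$dosages
  called <- !is.na(d)
  I0 <- (d == 0L) & called; I1 <- (d == 1L) & called; I2 <- (d == 2L) & called
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <-
    storage.mode(called) <- "double"
  n2 <- I0 %*% t(I2); n2 <- n2 + t(n2)               # dosage diff 2
  hom <- I0 + I2
  n1 <- I1 %*% t(hom); n1 <- n1 + t(n1)              # dosage diff 1
  shared <- called %*% t(called)
  D <- (2 * n2 + n1) / (2 * shared)
  D[shared == 0] <- NA
  diag(D) <- 0
  dimnames(D) <- list(sample_ids(g), sample_ids(g))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`). Negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero with
#' the magnitude transferred to the sibling branch at the same node
#' (standard practice); the tree is flagged when this happens.
#'
#' @param D symmetric distance matrix with zero diagonal, n >= 3, or a
#'   `dist` object.
#' @return list of class `nj_tree`: `phylo` (ape tree),
#'   `negative_branches_adjusted` count.
#' @export
nj_tree <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    stopifnot(isSymmetric(unname(D), tol = 1e-8), all(abs(diag(D)) < 1e-12))
    D <- stats::as.dist(D)
  }
  if (attr(D, "Size") < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(D)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    amt <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + amt
  }
  structure(list(phylo = tr, negative_branches_adjusted = length(neg)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf("NJ tree with %d tips (%d negative branch(es) adjusted)\n",
              length(x$phylo$tip.label), x$negative_branches_adjusted))
  invisible(x)
}
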