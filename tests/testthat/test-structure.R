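make_g <- function(d, chrom = "Chr01", pos = NULL) {
  d <- as.matrix(d); storage.mode(d) <- "integer"
  m <- ncol(d)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(d, paste0("s", seq_len(nrow(d))),
                  data.frame(chrom = chrom, pos = as.integer(pos),
                             ref = "A", alt = "C", id = paste0("v", 1:m)))
}

test_that("LD pruning follows the greedy keep-earlier rule", {
  set.seed(2)
  base <- sample(0:2, 40, TRUE, prob = c(.3, .4, .3))
  d <- cbind(base, base, sample(0:2, 40, TRUE), sample(0:2, 40, TRUE))
  g <- make_g(d)
  gp <- ld_prune(g, r2_threshold = 0.5, window = 10, step = 5)
  expect_equal(gp$variants$id, c("v1", "v3", "v4"))  # later duplicate drops

  # 6-variant toy with a known correlation structure, hand-run greedy:
  # v1=v2=v3 (pairwise r2 = 1), v4 independent, v5 = v4, v6 independent
  set.seed(3)
  a <- sample(0:2, 60, TRUE); b <- sample(0:2, 60, TRUE)
  e <- sample(0:2, 60, TRUE)
  g6 <- make_g(cbind(a, a, a, b, b, e))
  gp6 <- ld_prune(g6, r2_threshold = 0.5, window = 6, step = 3)
  expect_equal(gp6$variants$id, c("v1", "v4", "v6"))

  # independent simulated sites survive whole
  gi <- random_g(500, 40, seed = 7, n_chrom = 1)
  expect_equal(ncol(ld_prune(gi, 0.5, window = 20, step = 10)$dosages), 40)
})

test_that("PCA matches an SVD oracle and uses a stable sign convention", {
  g <- random_g(30, 80, seed = 4, miss = 0.05)
  pc <- snp_pca(g, min_maf = 0, n_pcs = 5)
  # oracle: explicit centering + svd
  st <- allele_stats(g)
  keep <- st$maf > 0
  X <- sweep(g$dosages[, keep], 2, 2 * st$alt_freq[keep])
  X[is.na(X)] <- 0
  sv <- svd(X)
  for (k in 1:5) {
    ok <- sv$u[, k] * sv$d[k]
    expect_equal(abs(pc$scores[, k]), abs(ok), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # sign convention: largest-|loading| entry positive
  for (k in 1:5)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)

  # sample permutation only permutes scores (up to sign, fixed by rule)
  perm <- sample(30)
  gp <- genotype_matrix(g$dosages[perm, ], rownames(g$dosages)[perm],
                        g$variants)
  pcp <- snp_pca(gp, min_maf = 0, n_pcs = 3)
  expect_equal(pcp$scores[rownames(pc$scores), ], pc$scores[, 1:3],
               tolerance = 1e-8)
})

test_that("PCA separates duplicated groups on PC1", {
  set.seed(5)
  proto1 <- sample(0:2, 60, TRUE); proto2 <- sample(0:2, 60, TRUE)
  d <- rbind(matrix(proto1, 10, 60, byrow = TRUE),
             matrix(proto2, 10, 60, byrow = TRUE))
  pc <- snp_pca(make_g(d), min_maf = 0)
  s1 <- pc$scores[1:10, 1]; s2 <- pc$scores[11:20, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_gt(pc$explained[1], 0.99)
  expect_error(snp_pca(make_g(matrix(1L, 5, 4)), min_maf = 0),
               "zero-variance")
})

test_that("DAPC selects the planted k and recovers the partition", {
  sim <- simulate_landscape(landscape_config(n_samples = 120, n_snps = 800,
                                             seed = 19))
  dp <- dapc_find_clusters(sim$genotypes, k_max = 6, seed = 3)
  expect_equal(dp$k_selected, 3L)
  expect_gte(cluster_agreement(dp$assignments, sim$truth$group), 0.95)
  expect_equal(length(dp$assignments), 120L)
  expect_equal(unname(dp$bic_by_k[dp$k_selected]), min(dp$bic_by_k))

  # panmictic population: BIC prefers k = 1 in most seeds
  k1 <- vapply(1:10, function(s) {
    sim0 <- simulate_landscape(landscape_config(n_samples = 100,
                                                n_snps = 600, k_groups = 1,
                                                seed = s))
    dapc_find_clusters(sim0$genotypes, k_max = 4, seed = s)$k_selected
  }, integer(1))
  expect_gte(mean(k1 == 1L), 0.9)

  expect_error(dapc_find_clusters(sim$genotypes[1:5, ], k_max = 6), "k_max")
})

test_that("IBS distance is a masked mean of dosage mismatches", {
  d <- rbind(c(0L, 2L, 1L), c(2L, 0L, 1L), c(0L, 2L, 1L))
  g <- make_g(d)
  D <- ibs_distance(g)
  expect_equal(D["s1", "s3"], 0)          # identical samples
  expect_equal(D["s1", "s2"], (2 + 2 + 0) / 6)
  expect_true(isSymmetric(D))

  # masking: NA sites excluded pairwise
  d2 <- rbind(c(0L, NA, 2L), c(0L, 2L, 0L))
  D2 <- ibs_distance(make_g(d2))
  expect_equal(D2[1, 2], (0 + 2) / 4)
})

test_that("neighbor joining is exact on an additive 4-taxon matrix", {
  # tree: (A:1,B:2):0.5 with (C:3,D:4) across an internal edge of 0.5
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 4.5
  D["A", "D"] <- D["D", "A"] <- 5.5
  D["B", "C"] <- D["C", "B"] <- 5.5
  D["B", "D"] <- D["D", "B"] <- 6.5
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)
  expect_equal(tr$negative_branches_adjusted, 0L)
  expect_setequal(tr$phylo$tip.label, LETTERS[1:4])
  # path lengths reproduce the input distances exactly
  path <- ape::cophenetic.phylo(tr$phylo)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(path), unname(D), tolerance = 1e-12)

  # Newick round trip preserves the topology
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr$phylo)), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
})
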