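test_that("single-garden BLUPs equal the closed-form shrinkage", {
  set.seed(1)
  n_acc <- 40; r <- 4
  acc <- rep(paste0("a", seq_len(n_acc)), each = r)
  u <- rnorm(n_acc, 0, 2)
  rec <- data.frame(accession = acc, garden = "g1",
                    value = 50 + u[match(acc, unique(acc))] + rnorm(n_acc * r))
  expect_warning(bl <- estimate_blups(rec), "single common garden")
  vc <- attr(bl, "varcomp")[[1]]
  mu <- mean(tapply(rec$value, rec$accession, mean))
  shrink <- r * vc["accession"] / (r * vc["accession"] + vc["residual"])
  means <- tapply(rec$value, rec$accession, mean)[bl$accession_id]
  closed <- mu + shrink * (means - mu)
  expect_equal(bl$blup, as.numeric(closed), tolerance = 1e-8)
  # shrinkage property: BLUP deviations never exceed raw deviations
  expect_true(all(abs(bl$blup - mu) <= abs(means - mu) + 1e-10))
})

test_that("a null trait shrinks BLUPs to the grand mean", {
  set.seed(2)
  rec <- data.frame(accession = rep(paste0("a", 1:30), each = 3),
                    garden = rep(paste0("g", 1:3), 30),
                    value = rnorm(90, 10, 1))
  bl <- estimate_blups(rec)
  expect_lt(sd(bl$blup), 0.25 * sd(tapply(rec$value, rec$accession, mean)) + 0.1)
})

test_that("BLUPs beat garden-pooled means at recovering genetic values", {
  wins <- vapply(1:10, function(s) {
    sim <- simulate_landscape(landscape_config(n_samples = 200,
                                               n_snps = 300, seed = s))
    rec <- simulate_phenotypes(sim$truth, sim$samples, h2 = 0.4,
                               garden_effects = 3, n_gardens = 3, seed = s)
    # unbalanced design: drop a third of the records
    set.seed(s); rec <- rec[runif(nrow(rec)) > 1 / 3, ]
    bl <- estimate_blups(rec)
    gv <- sim$truth$genetic_value[bl$accession_id]
    raw <- tapply(rec$value, rec$accession, mean)[bl$accession_id]
    cor(bl$blup, gv) >= cor(raw, gv)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("kinship matches a double-loop covariance oracle", {
  g <- random_g(12, 60, seed = 3, miss = 0.05)
  K <- kinship(g)
  st <- allele_stats(g)
  keep <- st$maf > 0
  d <- g$dosages[, keep]
  p <- st$alt_freq[keep]
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  denom <- 2 * sum(p * (1 - p))
  for (i in sample(12, 4)) for (k in sample(12, 4)) {
    o <- sum((d[i, ] - 2 * p) * (d[k, ] - 2 * p)) / denom
    expect_equal(K[i, k], o, tolerance = 1e-10)
  }
  # duplicated samples: off-diagonal equals the diagonal value
  d2 <- rbind(g$dosages[1, ], g$dosages[1, ], g$dosages[2:5, ])
  g2 <- genotype_matrix(d2, paste0("s", 1:6), g$variants)
  K2 <- kinship(g2)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-10)
  expect_error(kinship(genotype_matrix(matrix(2L, 4, 2), paste0("s", 1:4),
    data.frame(chrom = "Chr01", pos = c(1L, 5L), ref = "A", alt = "C",
               id = c("x", "y")))), "polymorphic")

  # unrelated panmictic panel: off-diagonal mean near 0
  g3 <- random_g(200, 800, seed = 9)
  K3 <- kinship(g3)
  expect_lt(abs(mean(K3[upper.tri(K3)])), 0.02)
})

test_that("the mixed model collapses to OLS when K is the identity", {
  sim <- simulate_landscape(landscape_config(n_samples = 60, n_snps = 150,
                                             k_groups = 1, seed = 4))
  g <- sim$genotypes
  set.seed(5)
  y <- rnorm(60)
  K <- diag(60); dimnames(K) <- list(sample_ids(g), sample_ids(g))
  Q <- matrix(rnorm(180), 60, 3)
  sc <- mlm_scan(g, y, Q_covariates = Q, K = K, min_maf = 0.05)
  for (i in sample(nrow(sc), 10)) {
    x <- g$dosages[, sc$id[i]]
    p_ols <- summary(lm(y ~ Q + x))$coefficients["x", 4]
    expect_equal(sc$p_value[i], p_ols, tolerance = 1e-6)
  }
})

test_that("the GLM scan equals hand-computed least squares", {
  g <- genotype_matrix(matrix(c(0L, 1L, 1L, 2L), 4, 1), paste0("s", 1:4),
                       data.frame(chrom = "Chr01", pos = 100L, ref = "A",
                                  alt = "C", id = "v1"))
  env <- c(1, 2, 3, 4)
  sc <- glm_scan(g, env, min_maf = 0)
  x <- c(0, 1, 1, 2)
  Sxx <- sum((x - mean(x))^2); Sxy <- sum((x - mean(x)) * (env - mean(env)))
  beta <- Sxy / Sxx
  rss <- sum((env - mean(env) - beta * (x - mean(x)))^2)
  se <- sqrt(rss / 2 / Sxx)
  expect_equal(sc$effect, beta, tolerance = 1e-12)
  expect_equal(sc$p_value, 2 * pt(-abs(beta / se), 2), tolerance = 1e-12)

  # exact linear relation: slope recovered, p ~ 0
  g2 <- genotype_matrix(matrix(rep(0:2, 10), 30, 1), paste0("s", 1:30),
                        g$variants)
  env2 <- 3 + 2 * rep(0:2, 10)
  sc2 <- glm_scan(g2, env2, min_maf = 0)
  expect_equal(sc2$effect, 2, tolerance = 1e-12)
  expect_lt(sc2$p_value, 1e-50)
})

test_that("GLM p-values are uniform under permuted environments", {
  sim <- simulate_landscape(landscape_scenario("null", n_samples = 150,
                                               n_snps = 3000, seed = 6))
  set.seed(7)
  env <- sample(sim$samples$bio12)
  sc <- glm_scan(sim$genotypes, env, min_maf = 0.03)
  ks <- suppressWarnings(ks.test(sc$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("outlier selection is a sort-and-slice with tie handling", {
  set.seed(8)
  p <- runif(1000)
  sc <- structure(data.frame(id = paste0("v", 1:1000), p_value = p),
                  class = c("scan_result", "data.frame"))
  so <- select_outliers(sc, quantile = 0.01)
  expect_equal(sum(so$outlier), 10L)
  expect_setequal(so$id[so$outlier], sc$id[order(p)[1:10]])
  # all-tied p-values: everything flagged, with a warning
  sc2 <- structure(data.frame(id = "a", p_value = rep(0.5, 8)),
                   class = c("scan_result", "data.frame"))
  expect_warning(so2 <- select_outliers(sc2), "tied")
  expect_true(all(so2$outlier))
})

test_that("MLM finds a planted QTL and MLMM steps are deterministic", {
  sim <- simulate_landscape(landscape_config(n_samples = 250,
                                             n_snps = 1500, seed = 9))
  g <- sim$genotypes
  st <- allele_stats(g)
  qtl <- st$id[which.min(abs(st$maf - 0.3))]
  tr <- set_causal_loci(sim$truth, g, qtl, 1)
  set.seed(10)
  gv <- scale(tr$genetic_value)[, 1]
  y <- sqrt(0.25) * gv + rnorm(250, 0, sqrt(0.75))
  K <- kinship(g)
  sc <- mlm_scan(g, y, K = K)
  expect_equal(sc$id[which.min(sc$p_value)], qtl)

  ml1 <- mlmm_scan(g, y, K = K, max_cofactors = 3)
  ml2 <- mlmm_scan(g, y, K = K, max_cofactors = 3)
  expect_identical(attr(ml1, "cofactors"), attr(ml2, "cofactors"))
  expect_identical(attr(ml1, "path"), attr(ml2, "path"))
  expect_true(qtl %in% attr(ml1, "cofactors"))
  # cofactors are excluded from the reported scan rows
  expect_false(any(attr(ml1, "cofactors") %in% ml1$id))
})

test_that("a zero-heritability trait selects no MLMM cofactors", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_landscape(landscape_config(n_samples = 150,
                                               n_snps = 800, seed = 20 + s))
    set.seed(s)
    y <- rnorm(150)
    length(attr(mlmm_scan(sim$genotypes, y, max_cofactors = 3),
                "cofactors"))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.8)
})
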