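test_that("allele statistics match a per-site loop on random matrices", {
  g <- random_g(20, 100, seed = 3, miss = 0.1)
  st <- allele_stats(g)
  for (j in sample(100, 25)) {
    x <- g$dosages[, j]
    ok <- !is.na(x)
    p <- sum(x[ok]) / (2 * sum(ok))
    expect_equal(st$alt_freq[j], p)
    expect_equal(st$maf[j], min(p, 1 - p))
    expect_equal(st$missing_rate[j], mean(!ok))
    expect_equal(st$mac[j], min(sum(x[ok]), 2 * sum(ok) - sum(x[ok])))
  }
  expect_equal(allele_stats(genotype_matrix(
    matrix(c(0L, 0L, NA), 3, 1), c("a", "b", "c"),
    data.frame(chrom = "Chr01", pos = 1L, ref = "A", alt = "C",
               id = "v1")))$missing_rate, 1 / 3)
})

test_that("variant filters reproduce a hand-enumerated 10-site toy", {
  # 8 samples; per-site fates worked out by hand for
  # max_missing = 0.2, mac >= 3, maf >= 0.2, monomorphic dropped
  cols <- list(
    rep(0L, 8),                          # monomorphic       -> drop
    c(1L, rep(0L, 7)),                   # singleton mac=1   -> drop
    c(1L, 1L, rep(0L, 6)),               # doubleton mac=2   -> drop
    c(2L, 1L, rep(0L, 6)),               # mac=3, maf=0.1875 -> drop (maf)
    c(2L, 2L, rep(0L, 6)),               # mac=4, maf=0.25   -> keep
    c(rep(NA, 3), rep(1L, 5)),           # 37.5% missing     -> drop
    c(NA, NA, rep(1L, 6)),               # 25% missing       -> drop
    c(rep(2L, 4), rep(0L, 4)),           # maf=0.5           -> keep
    c(rep(2L, 7), 0L),                   # mac=2 (minor=ref) -> drop
    c(1L, 1L, 1L, rep(0L, 5)))           # mac=3, maf=0.1875 -> drop (maf)
  d <- do.call(cbind, cols)
  g <- genotype_matrix(d, paste0("s", 1:8),
                       data.frame(chrom = "Chr01", pos = 1:10 * 10L,
                                  ref = "A", alt = "C",
                                  id = paste0("v", 1:10)))
  res <- filter_variants(g, max_missing = 0.2, min_maf = 0.2, min_mac = 3)
  expect_equal(res$genotypes$variants$id, c("v5", "v8"))
  expect_equal(unname(res$report),
               c(2L, 1L, 3L, 2L))  # missingness, monomorphic, mac, maf
  expect_warning(filter_variants(g, min_maf = 0.9), "all variants")
})

test_that("windowed pi matches the unbiased formula and pairwise oracle", {
  # one site, p = 0.5, 2 diploids, 1 kb window
  g <- genotype_matrix(matrix(c(0L, 2L), 2, 1), c("a", "b"),
                       data.frame(chrom = "Chr01", pos = 500L, ref = "A",
                                  alt = "C", id = "v1"))
  pw <- nucleotide_diversity_windows(g, window_bp = 1000)
  expect_equal(pw$value, (2 * 0.25 * 4 / 3) / 1000)
  expect_equal(pw$start, 0)
  expect_equal(pw$end, 1000)

  # random matrix: window sums equal the per-site pairwise-difference oracle
  g2 <- random_g(6, 40, seed = 9, miss = 0.1, n_chrom = 1)
  pw2 <- nucleotide_diversity_windows(g2, window_bp = 1e5)
  ora <- vapply(seq_len(40), function(j) {
    v <- oracle_pi_site(g2$dosages[, j]); if (is.na(v)) 0 else v
  }, numeric(1))
  key <- (g2$variants$pos - 1) %/% 1e5
  exp_val <- vapply(seq_len(nrow(pw2)), function(k)
    sum(ora[key == pw2$start[k] / 1e5]) / 1e5, numeric(1))
  expect_equal(pw2$value, exp_val, tolerance = 1e-12)

  # monomorphic window
  g3 <- genotype_matrix(matrix(2L, 3, 1), c("a", "b", "c"),
                        data.frame(chrom = "Chr01", pos = 10L, ref = "A",
                                   alt = "C", id = "v"))
  expect_equal(nucleotide_diversity_windows(g3, 1000)$value, 0)
})

test_that("pi is invariant to sample order and allele swap", {
  g <- random_g(10, 50, seed = 21, miss = 0.05, n_chrom = 1)
  p1 <- nucleotide_diversity_windows(g, 5e4)
  perm <- sample(10)
  gp <- genotype_matrix(g$dosages[perm, ], rownames(g$dosages)[perm],
                        g$variants)
  expect_equal(nucleotide_diversity_windows(gp, 5e4)$value, p1$value)
  gs <- genotype_matrix(2L - g$dosages, rownames(g$dosages), g$variants)
  expect_equal(nucleotide_diversity_windows(gs, 5e4)$value, p1$value)
})

test_that("Weir-Cockerham components match the scalar oracle", {
  set.seed(14)
  for (rep in 1:50) {
    n_pop <- sample(2:4, 1)
    n <- sample(3:8, 1) * n_pop
    g <- random_g(n, 6, seed = 1000 + rep, miss = 0.1)
    grp <- sample(rep_len(seq_len(n_pop), n))
    res <- weir_cockerham_fst(g, grp)
    for (j in 1:6) {
      o <- oracle_wc_site(g$dosages[, j], grp)
      expect_equal(res$per_site$a[j], unname(o["a"]), tolerance = 1e-12)
      expect_equal(res$per_site$b[j], unname(o["b"]), tolerance = 1e-12)
      expect_equal(res$per_site$c[j], unname(o["c"]), tolerance = 1e-12)
    }
  }
})

test_that("FST is 1 for fixed differences and near 0 under panmixia", {
  d <- rbind(matrix(0L, 5, 10), matrix(2L, 5, 10))
  g <- genotype_matrix(d, paste0("s", 1:10),
                       data.frame(chrom = "Chr01", pos = 1:10 * 100L,
                                  ref = "A", alt = "C",
                                  id = paste0("v", 1:10)))
  res <- weir_cockerham_fst(g, rep(1:2, each = 5))
  expect_equal(res$global, 1)
  expect_true(all(abs(res$per_site$theta - 1) < 1e-12))

  gp <- random_g(60, 5000, seed = 33)
  resp <- weir_cockerham_fst(gp, rep(1:2, 30))
  expect_lt(abs(resp$global), 0.01)
  expect_error(weir_cockerham_fst(gp, rep(1, 60)), "two populations")
})

test_that("windowed FST is the ratio of summed components", {
  g <- random_g(24, 60, seed = 5, miss = 0.05, n_chrom = 2)
  grp <- rep(1:3, 8)
  res <- weir_cockerham_fst(g, grp, window_bp = 2e5)
  ps <- res$per_site
  usable <- !is.na(ps$a) & (ps$a + ps$b + ps$c) != 0
  for (k in seq_len(nrow(res$windows))) {
    w <- res$windows[k, ]
    sel <- usable & ps$chrom == w$chrom & ps$pos > w$start & ps$pos <= w$end
    expect_equal(w$value, sum(ps$a[sel]) /
                   sum(ps$a[sel] + ps$b[sel] + ps$c[sel]))
  }
})

test_that("Tajima's D equals the direct 1989 formulas", {
  # 4 haplotypes, 3 segregating sites with derived counts 1, 2, 3
  H <- cbind(c(0, 0, 0, 1), c(0, 0, 1, 1), c(0, 1, 1, 1))
  pi_sum <- sum(2 * c(1, 2, 3) * c(3, 2, 1) / (4 * 3))
  expect_equal(tajima_d_haplotypes(H), oracle_tajima_d(3, pi_sum, 4))

  # same data as 2 diploids through the windowed scan
  d <- rbind(colSums(H[1:2, ]), colSums(H[3:4, ]))
  storage.mode(d) <- "integer"
  g <- genotype_matrix(d, c("a", "b"),
                       data.frame(chrom = "Chr01", pos = c(10L, 20L, 30L),
                                  ref = "A", alt = "C",
                                  id = paste0("v", 1:3)))
  tw <- tajima_d_windows(g, 1000, min_sites = 1)
  expect_equal(tw$value, oracle_tajima_d(3, pi_sum, 4))

  # no segregating site -> missing
  g0 <- genotype_matrix(matrix(0L, 4, 2), paste0("s", 1:4),
                        data.frame(chrom = "Chr01", pos = c(1L, 2L),
                                   ref = "A", alt = "C", id = c("a", "b")))
  expect_true(is.na(tajima_d_windows(g0, 1000, min_sites = 1)$value))
})

test_that("LD decay: duplicates give r2 = 1, independent sites near 0", {
  set.seed(8)
  n <- 500
  base <- sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
  d <- cbind(base, base, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  storage.mode(d) <- "integer"
  g <- genotype_matrix(d, paste0("s", 1:n),
                       data.frame(chrom = "Chr01",
                                  pos = c(100L, 1100L, 60000L, 150000L),
                                  ref = "A", alt = "C",
                                  id = paste0("v", 1:4)))
  ld <- ld_decay(g, max_dist_bp = 2e5, bin_bp = 2000, min_maf = 0.05)
  first <- ld$bins[ld$bins$mid == min(ld$bins$mid), ]
  expect_equal(first$mean_r2, 1)           # the duplicated pair
  far <- ld$bins$mean_r2[ld$bins$n_pairs > 0 & ld$bins$mid > 4e4]
  expect_true(all(far < 0.05))             # independent pairs ~ 1/n

  # r2 is invariant to flipping dosages (2 - g) at any subset of sites
  gf <- genotype_matrix(cbind(d[, 1:2], 2L - d[, 3:4]), rownames(g$dosages),
                        g$variants)
  ldf <- ld_decay(gf, max_dist_bp = 2e5, bin_bp = 2000, min_maf = 0.05)
  expect_equal(ldf$bins$mean_r2, ld$bins$mean_r2, tolerance = 1e-12)
})

test_that("LD decay crossing matches a designed geometric decay rate", {
  # Markov construction: each variant copies its neighbor except with
  # redraw probability q per step, so r^2(d) ~ (1-q)^(2 d / spacing);
  # q chosen for r^2 = 0.1 at 40 kb with 2 kb spacing.
  set.seed(10)
  n <- 400; spacing <- 2000L; m <- 60
  target_bp <- 40000
  q <- 1 - 0.1^(spacing / (2 * target_bp))
  d <- matrix(0L, n, m)
  d[, 1] <- sample(0:2, n, TRUE, prob = c(.25, .5, .25))
  for (j in 2:m) {
    redraw <- runif(n) < q
    d[, j] <- ifelse(redraw, sample(0:2, n, TRUE, prob = c(.25, .5, .25)),
                     d[, j - 1])
  }
  g <- genotype_matrix(d, paste0("s", 1:n),
                       data.frame(chrom = "Chr01",
                                  pos = spacing * (seq_len(m) - 1L) + 1L,
                                  ref = "A", alt = "C",
                                  id = paste0("v", seq_len(m))))
  ld <- ld_decay(g, max_dist_bp = 1e5, bin_bp = 5000, spline_df = 8)
  cross <- ld$crossings[["r2_0.1"]]
  expect_false(is.na(cross))
  expect_equal(cross, target_bp, tolerance = 0.25)
  # curve decreasing overall
  expect_gt(ld$bins$smooth_r2[1], ld$bins$smooth_r2[nrow(ld$bins)])
  expect_true(all(diff(ld$bins$smooth_r2) < 0.02))
})

test_that("sample heterozygosity and inbreeding behave as defined", {
  d <- rbind(c(0L, 1L, 1L, 2L),     # 2/4 het
             c(0L, 0L, 2L, 2L),     # all hom
             c(1L, 1L, 1L, 1L))
  g <- genotype_matrix(d, c("a", "b", "c"),
                       data.frame(chrom = "Chr01", pos = 1:4 * 10L,
                                  ref = "A", alt = "C",
                                  id = paste0("v", 1:4)))
  qc <- sample_qc(g)
  expect_equal(qc$observed_het, c(0.5, 0, 1))
  expect_equal(qc$inbreeding_f[2], 1)

  sim <- simulate_landscape(landscape_config(n_samples = 300, n_snps = 800,
                                             selfing_f = 0.8, seed = 17))
  expect_equal(mean(sample_qc(sim$genotypes)$inbreeding_f), 0.8,
               tolerance = 0.05)
})
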