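# Independent brute-force oracles used across the suite. These are written
# as literal transcriptions of the defining formulas (scalar loops,
# explicit enumeration) and deliberately share no code with the package
# implementations they check.

# random small genotype matrix with optional missingness
random_g <- function(n, m, seed, miss = 0, n_chrom = 2) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) d[runif(n * m) < miss] <- NA
  chrom <- sort(sample(sprintf("Chr%02d", seq_len(n_chrom)), m, replace = TRUE))
  pos <- unlist(lapply(table(chrom), function(k) sort(sample.int(1e6, k))))
  genotype_matrix(d, paste0("s", seq_len(n)),
                  data.frame(chrom = chrom, pos = as.integer(pos),
                             ref = "A", alt = "C",
                             id = paste0("v", seq_len(m))))
}

# Weir & Cockerham (1984) per-site components, scalar transcription
oracle_wc_site <- function(dos, grp) {
  grp <- factor(grp)
  pops <- levels(grp)
  ni <- pi_ <- hi <- numeric(0)
  for (pp in pops) {
    x <- dos[grp == pp]
    x <- x[!is.na(x)]
    if (length(x) == 0) next
    ni <- c(ni, length(x))
    pi_ <- c(pi_, sum(x) / (2 * length(x)))
    hi <- c(hi, mean(x == 1))
  }
  r <- length(ni)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  nbar <- mean(ni)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(c(a = NA, b = NA, c = NA))
  pbar <- sum(ni * pi_) / (r * nbar)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# average pairwise difference among the called allele copies of one site
oracle_pi_site <- function(dos) {
  x <- dos[!is.na(dos)]
  copies <- unlist(lapply(x, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(copies)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff <- diff + (copies[i] != copies[j])
  diff / choose(n, 2)
}

# Tajima (1989) D, direct transcription
oracle_tajima_d <- function(S, pi_sum, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# all-pairs point-gene distances (0-based half-open gap)
oracle_coloc_flags <- function(points, genes, window_bp) {
  hit <- logical(nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    dmin <- Inf
    for (pj in seq_len(nrow(points))) {
      if (points$chrom[pj] != genes$chrom[gi]) next
      ps <- points$pos[pj] - 1; pe <- points$pos[pj]
      gap <- max(0, genes$start[gi] - pe, ps - genes$end[gi])
      dmin <- min(dmin, gap)
    }
    hit[gi] <- dmin <= window_bp
  }
  hit
}

# minimal VCF writer for fixture construction (independent of write_vcf)
write_fixture_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
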