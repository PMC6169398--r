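#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate a West-African-style landrace panel: three genetic
#' groups differentiated at Wright's F around 0.2, a dominant precipitation
#' gradient strongly collinear with latitude (r about -0.86), high selfing
#' (within-individual inbreeding F about 0.8), and a small set of loci whose
#' allele frequencies follow logistic clines on the climate gradient.
#'
#' @param n_samples number of diploid accessions.
#' @param n_snps number of biallelic SNPs (spread uniformly over
#'   `n_chromosomes` chromosomes of `chrom_length_bp` bp).
#' @param k_groups number of genetic groups (Balding-Nichols model).
#' @param fst_target Wright's F of the Balding-Nichols draw, in (0, 1).
#' @param n_clinal_loci number of loci given group-independent logistic
#'   frequency clines on the standardized primary climate variable.
#' @param clinal_slope logistic slope (logit allele frequency per SD of
#'   climate) of the planted clines.
#' @param climate_space_r target Pearson correlation between the primary
#'   climate variable and latitude, in [-1, 1].
#' @param selfing_f within-individual inbreeding coefficient in [0, 1].
#' @param h2 default narrow-sense heritability used by
#'   [simulate_phenotypes()].
#' @param n_gardens number of common gardens for phenotype records.
#' @param n_qtl number of causal loci planted for the default trait.
#' @param n_climate_vars total number of climate columns emitted; columns
#'   beyond the first are noisy copies of the primary gradient.
#' @param climate_copy_r correlation of the extra climate columns with the
#'   primary one.
#' @param group_lat_spread half-width (degrees) of each group's latitude
#'   band.
#' @param group_lat_shift separation (degrees) between adjacent group
#'   latitude centers; 0 makes group membership spatially unstructured.
#' @param n_chromosomes,chrom_length_bp genome layout.
#' @param cluster_clinal_loci if TRUE, clinal loci are planted in contiguous
#'   position clusters (tight genomic blocks) instead of scattered singles.
#' @param seed integer seed; the whole draw is deterministic given the seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_samples = 300, n_snps = 5000, k_groups = 3,
                             fst_target = 0.2, n_clinal_loci = 0,
                             clinal_slope = 1.5, climate_space_r = -0.86,
                             selfing_f = 0.8, h2 = 0.5, n_gardens = 2,
                             n_qtl = 10, n_climate_vars = 10,
                             climate_copy_r = 0.8, group_lat_spread = 3,
                             group_lat_shift = 2, n_chromosomes = 10,
                             chrom_length_bp = 2e6,
                             cluster_clinal_loci = FALSE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$fst_target > 0, cfg$fst_target < 1,
            cfg$h2 >= 0, cfg$h2 <= 1,
            cfg$selfing_f >= 0, cfg$selfing_f <= 1,
            cfg$k_groups >= 1, cfg$n_clinal_loci <= cfg$n_snps)
  if (abs(cfg$climate_space_r) > 1)
    stop("infeasible climate-latitude correlation target: ",
         cfg$climate_space_r)
  class(cfg) <- "landscape_config"
  cfg
}

#' Canned landscape scenarios
#'
#' Three pre-calibrated configurations used throughout the package's
#' calibration and power analyses:
#' * `"null"` — no clinal loci, climate decoupled from both latitude and
#'   genotype, panmictic background (k = 1): any genotype-climate
#'   association test should be calibrated at its nominal level on this.
#' * `"clinal"` — 8% of SNPs carry logistic clines of slope 2 on the
#'   climate gradient and group membership is spatially unstructured;
#'   calibrated so that the expected climate-collinear fraction [b] of the
#'   SNP variance is about 0.03.
#' * `"clinal-strong"` — clustered clinal loci with slope 3 on a panmictic
#'   background; used for enrichment power analyses where candidate genes
#'   are placed next to planted clines.
#'
#' @param scenario scenario name.
#' @param n_samples,n_snps,seed forwarded to [landscape_config()].
#' @param ... further overrides forwarded to [landscape_config()].
#' @return `landscape_config`.
#' @export
landscape_scenario <- function(scenario = c("null", "clinal",
                                            "clinal-strong"),
                               n_samples = 120, n_snps = 2000, seed = 1,
                               ...) {
  scenario <- match.arg(scenario)
  args <- switch(scenario,
    "null" = list(k_groups = 1, n_clinal_loci = 0, climate_space_r = 0,
                  group_lat_shift = 0),
    "clinal" = list(n_clinal_loci = round(0.08 * n_snps), clinal_slope = 2,
                    group_lat_shift = 0),
    "clinal-strong" = list(k_groups = 1, group_lat_shift = 0,
                           n_clinal_loci = round(0.08 * n_snps),
                           clinal_slope = 3, cluster_clinal_loci = TRUE))
  do.call(landscape_config,
          utils::modifyList(c(list(n_samples = n_samples, n_snps = n_snps,
                                   seed = seed), args), list(...)))
}

#' Simulate a clinal landscape with known truth
#'
#' Draws group allele frequencies from the Balding-Nichols model around a
#' Uniform(0.05, 0.95) ancestral frequency, places samples in latitude bands
#' by group, builds a primary climate variable linear in latitude with noise
#' calibrated to the target climate-latitude correlation, gives
#' `n_clinal_loci` loci group-independent logistic frequency clines on the
#' standardized climate, and draws diploid genotypes with inbreeding
#' coefficient `selfing_f` (genotype frequencies p^2 + pqF, 2pq(1-F),
#' q^2 + pqF).
#'
#' @param config a [landscape_config()].
#' @return list with `genotypes` ([genotype_matrix()]), `samples`
#'   ([sample_table()], climate columns `bio12`, `clim2`, ...), and `truth`
#'   (true group labels, clinal locus ids and slopes, causal trait loci and
#'   effects, per-sample genetic values, genome layout).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_snps; K <- cfg$k_groups
  F <- cfg$fst_target

  # genome layout: variants uniform over chromosomes, sorted
  chrom <- sort(sample.int(cfg$n_chromosomes, m, replace = TRUE))
  pos <- integer(m)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(sample.int(cfg$chrom_length_bp, length(idx)))
  }
  chrom_names <- sprintf("Chr%02d", chrom)
  ids <- paste0("S", chrom, "_", pos)

  # clinal loci: scattered singles, or contiguous blocks so that local
  # windows accumulate several intermediate-frequency sites
  if (cfg$n_clinal_loci > 0) {
    if (cfg$cluster_clinal_loci) {
      block <- 5L
      n_blocks <- ceiling(cfg$n_clinal_loci / block)
      starts <- sample(seq_len(max(1L, m - block)), n_blocks)
      clin_idx <- unique(as.vector(outer(starts, 0:(block - 1L), `+`)))
      clin_idx <- clin_idx[clin_idx <= m]
      short <- cfg$n_clinal_loci - length(clin_idx)
      if (short > 0)
        clin_idx <- c(clin_idx,
                      sample(setdiff(seq_len(m), clin_idx), short))
      clin_idx <- sort(clin_idx[seq_len(cfg$n_clinal_loci)])
    } else {
      clin_idx <- sort(sample.int(m, cfg$n_clinal_loci))
    }
  } else clin_idx <- integer(0)

  # samples: groups in latitude bands, primary climate linear in latitude
  group <- rep_len(seq_len(K), n)
  centers <- 9 + (seq_len(K) - (K + 1) / 2) * cfg$group_lat_shift
  lat <- centers[group] + runif(n, -cfg$group_lat_spread, cfg$group_lat_spread)
  lon <- runif(n, 3, 14)
  r <- cfg$climate_space_r
  slope_sign <- if (r <= 0) -1 else 1
  if (r == 0) {
    clim1 <- rnorm(n)  # fully decoupled from space
  } else {
    clim1 <- slope_sign * scale(lat)[, 1]
    if (abs(r) < 1)
      clim1 <- clim1 + rnorm(n, 0, sqrt(1 / r^2 - 1) * sd(clim1))
  }
  clim_z <- scale(clim1)[, 1]
  climate <- matrix(NA_real_, n, cfg$n_climate_vars)
  climate[, 1] <- 800 - 180 * clim_z * slope_sign  # mm-scale precipitation
  if (cfg$n_climate_vars > 1) {
    cr <- cfg$climate_copy_r
    for (j in 2:cfg$n_climate_vars)
      climate[, j] <- cr * clim_z + sqrt(1 - cr^2) * rnorm(n)
  }
  colnames(climate) <- c("bio12", paste0("clim", seq_len(cfg$n_climate_vars))[-1])

  # allele frequencies: Balding-Nichols per group; logistic clines per
  # individual at clinal loci
  p0 <- runif(m, 0.05, 0.95)
  shape <- (1 - F) / F
  pk <- matrix(rbeta(K * m, rep(p0 * shape, each = K),
                     rep((1 - p0) * shape, each = K)), nrow = K)
  pmat <- t(pk)[, group, drop = FALSE]  # m x n individual freqs
  if (length(clin_idx)) {
    lg <- log(p0[clin_idx] / (1 - p0[clin_idx]))
    pmat[clin_idx, ] <- stats::plogis(outer(lg, rep(1, n)) +
                                      cfg$clinal_slope * outer(rep(1, length(clin_idx)), clim_z))
  }
  pmat <- pmin(pmax(pmat, 1e-6), 1 - 1e-6)

  # genotypes with inbreeding: P(2)=p^2+pqF, P(1)=2pq(1-F), P(0)=q^2+pqF
  fs <- cfg$selfing_f
  q <- 1 - pmat
  p2 <- pmat^2 + pmat * q * fs
  p1 <- 2 * pmat * q * (1 - fs)
  u <- matrix(runif(m * n), m, n)
  dos <- matrix(0L, m, n)
  dos[u < p2 + p1] <- 1L
  dos[u < p2] <- 2L
  g <- genotype_matrix(t(dos), paste0("acc", sprintf("%04d", seq_len(n))),
                       data.frame(chrom = chrom_names, pos = pos,
                                  ref = "A", alt = "T", id = ids,
                                  stringsAsFactors = FALSE))

  # trait truth: additive causal loci among non-clinal SNPs
  qtl_idx <- if (cfg$n_qtl > 0)
    sort(sample(setdiff(seq_len(m), clin_idx), cfg$n_qtl)) else integer(0)
  effects <- if (cfg$n_qtl > 0) rnorm(cfg$n_qtl) else numeric(0)
  gv <- if (length(qtl_idx))
    as.vector(g$dosages[, qtl_idx, drop = FALSE] %*% effects) else rep(0, n)

  st <- sample_table(data.frame(sample_id = sample_ids(g), latitude = lat,
                                longitude = lon, climate, group = group,
                                stringsAsFactors = FALSE),
                     climate_vars = colnames(climate))
  truth <- list(group = setNames(group, sample_ids(g)),
                clinal_locus_ids = ids[clin_idx],
                clinal_slope = cfg$clinal_slope,
                causal = data.frame(id = ids[qtl_idx], effect = effects,
                                    stringsAsFactors = FALSE),
                genetic_value = setNames(gv, sample_ids(g)),
                n_chromosomes = cfg$n_chromosomes,
                chrom_length_bp = cfg$chrom_length_bp,
                chrom_names = sprintf("Chr%02d", seq_len(cfg$n_chromosomes)),
                config = cfg)
  list(genotypes = g, samples = st, truth = truth)
}

#' Replace the causal loci of a simulated landscape
#'
#' Re-plants the trait architecture of a landscape truth object on chosen
#' variants and recomputes per-sample genetic values; used to set up GWAS
#' power experiments with known QTL.
#'
#' @param truth truth list from [simulate_landscape()].
#' @param g the matching genotype_matrix.
#' @param ids variant ids to use as causal loci.
#' @param effects additive allele effects, same length as `ids`.
#' @return updated truth list.
#' @export
set_causal_loci <- function(truth, g, ids, effects) {
  j <- match(ids, g$variants$id)
  if (anyNA(j)) stop("unknown variant id(s): ",
                     paste(ids[is.na(j)], collapse = ", "))
  stopifnot(length(effects) == length(ids))
  d <- g$dosages[, j, drop = FALSE]
  d[is.na(d)] <- 0
  truth$causal <- data.frame(id = ids, effect = effects,
                             stringsAsFactors = FALSE)
  truth$genetic_value <- setNames(as.vector(d %*% effects), sample_ids(g))
  truth
}

#' Simulate multi-garden phenotype records
#'
#' Emits one record per accession per common garden following
#' y = mu + genetic value + garden effect + residual, with the genetic and
#' residual scales set so that the genetic share of within-garden variance
#' equals `h2`.
#'
#' @param truth truth list carrying per-sample genetic values.
#' @param st sample_table (defines the accession set and order).
#' @param h2 heritability in [0, 1]; 0 drops the genetic term entirely.
#' @param garden_effects either a single standard deviation for random
#'   garden effects or a numeric vector of fixed per-garden offsets.
#' @param n_gardens number of gardens (ignored when `garden_effects` is a
#'   vector).
#' @param mu grand mean.
#' @param seed integer seed.
#' @return data.frame of class `phenotype_records` with columns
#'   `accession`, `garden`, `value`.
#' @export
simulate_phenotypes <- function(truth, st, h2 = truth$config$h2,
                                garden_effects = 1,
                                n_gardens = truth$config$n_gardens,
                                mu = 100, seed = 1) {
  set.seed(seed)
  gv <- truth$genetic_value[st$sample_id]
  if (h2 > 0 && (length(gv) == 0 || sd(gv) == 0))
    stop("h2 > 0 requires non-degenerate causal effects in truth")
  n <- length(gv)
  gscaled <- if (h2 > 0) sqrt(h2) * (gv - mean(gv)) / sd(gv) else rep(0, n)
  if (length(garden_effects) > 1) {
    geff <- garden_effects
    n_gardens <- length(geff)
  } else {
    geff <- rnorm(n_gardens, 0, garden_effects)
  }
  rec <- expand.grid(accession = st$sample_id,
                     garden = paste0("garden", seq_len(n_gardens)),
                     stringsAsFactors = FALSE)
  rec$value <- mu + rep(gscaled, n_gardens) + geff[match(rec$garden,
                 paste0("garden", seq_len(n_gardens)))] +
               rnorm(nrow(rec), 0, sqrt(1 - h2))
  class(rec) <- c("phenotype_records", "data.frame")
  rec
}

#' Place genes (and a-priori candidates) on a simulated genome
#'
#' Non-candidate genes are placed uniformly. A `linked_fraction` of the
#' candidate genes is placed within `window_bp` of a planted clinal locus
#' (uniform offset up to 90% of the window so the distance criterion holds
#' with margin); the remaining candidates are placed uniformly.
#'
#' @param truth truth list from [simulate_landscape()] (supplies the genome
#'   layout and clinal locus positions).
#' @param n_genes total number of genes.
#' @param n_candidates number of genes flagged as a-priori candidates.
#' @param linked_fraction fraction of candidates linked to clinal loci.
#' @param window_bp linkage window in bp.
#' @param gene_length_bp gene length (fixed, bp).
#' @param seed integer seed.
#' @return gene_annotation data.frame with `is_candidate` flags.
#' @export
place_candidate_genes <- function(truth, n_genes = 500, n_candidates = 50,
                                  linked_fraction = 0, window_bp = 1e5,
                                  gene_length_bp = 3000, seed = 1) {
  stopifnot(linked_fraction >= 0, linked_fraction <= 1,
            n_candidates <= n_genes)
  set.seed(seed)
  n_linked <- round(linked_fraction * n_candidates)
  clin <- truth$clinal_locus_ids
  if (n_linked > 0 && length(clin) == 0)
    stop("cannot link candidates: no clinal loci in truth")
  L <- truth$chrom_length_bp
  gl <- gene_length_bp
  placed_chrom <- character(n_genes)
  placed_start <- integer(n_genes)
  if (n_linked > 0) {
    pick <- sample(clin, n_linked, replace = TRUE)
    pc <- sub("^S([0-9]+)_.*$", "\\1", pick)
    pp <- as.integer(sub("^S[0-9]+_", "", pick))
    off <- round(runif(n_linked, -0.9 * window_bp, 0.9 * window_bp))
    placed_chrom[seq_len(n_linked)] <- sprintf("Chr%02d", as.integer(pc))
    placed_start[seq_len(n_linked)] <- pmin(pmax(pp - 1L + off, 0L), L - gl - 1L)
  }
  rest <- if (n_linked < n_genes) (n_linked + 1):n_genes else integer(0)
  if (length(rest)) {
    placed_chrom[rest] <- sprintf("Chr%02d",
                                  sample.int(truth$n_chromosomes,
                                             length(rest), replace = TRUE))
    placed_start[rest] <- sample.int(L - gl - 1L, length(rest), replace = TRUE)
  }
  df <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                   chrom = placed_chrom, start = placed_start,
                   end = placed_start + gl, stringsAsFactors = FALSE)
  # candidates: the linked ones plus a uniform draw from the rest
  cand <- c(df$gene_id[seq_len(n_linked)],
            if (n_candidates > n_linked)
              sample(df$gene_id[rest], n_candidates - n_linked))
  gene_annotation(df, candidate_list = cand)
}
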