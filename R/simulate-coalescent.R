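#' Simulate haplotypes under the standard neutral coalescent
#'
#' Kingman coalescent with infinite-sites mutation: exponential coalescence
#' times with rate choose(k, 2) while k lineages remain, and Poisson
#' mutations at rate theta/2 per branch length unit, each creating one
#' segregating site carried by the tips below the branch. Used to calibrate
#' Tajima's D (neutral expectation near 0) and the segregating-sites
#' expectation E[S] = theta * sum(1/i, i = 1..n-1).
#'
#' @param n_chromosomes number of sampled haploid sequences (>= 2).
#' @param theta population mutation rate 4*Ne*mu per locus (> 0).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return binary matrix, `n_chromosomes` rows x S columns (S segregating
#'   sites; zero columns when no mutation falls on the tree).
#' @export
simulate_coalescent_sites <- function(n_chromosomes, theta, seed = NULL) {
  stopifnot(n_chromosomes >= 2, theta > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_chromosomes
  # active lineages as lists of tip indices, with their birth times
  tips <- as.list(seq_len(n))
  birth <- rep(0, n)
  t_now <- 0
  carriers <- list()
  while (length(tips) > 1) {
    k <- length(tips)
    t_now <- t_now + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (i in pair) {
      blen <- t_now - birth[i]
      nmut <- rpois(1, theta / 2 * blen)
      if (nmut > 0)
        carriers <- c(carriers, rep(list(tips[[i]]), nmut))
    }
    merged <- c(tips[[pair[1]]], tips[[pair[2]]])
    tips[[pair[1]]] <- merged
    tips[pair[2]] <- NULL
    birth[pair[1]] <- t_now
    birth <- birth[-pair[2]]
  }
  S <- length(carriers)
  H <- matrix(0L, nrow = n, ncol = S)
  for (s in seq_len(S)) H[carriers[[s]], s] <- 1L
  H
}
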