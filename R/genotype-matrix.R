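#' Construct a genotype matrix object
#'
#' The central container of the package: a samples x variants matrix of
#' diploid ALT-allele dosages (0, 1, 2; `NA` = missing call) together with
#' variant coordinates. Variants are kept sorted by chromosome (natural
#' order, so "Chr2" sorts before "Chr10") and position.
#'
#' @param dosages integer matrix, one row per sample, one column per variant;
#'   values in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, `id`; one row per variant. Must be biallelic SNPs.
#' @return An object of class `genotype_matrix` with elements `dosages`
#'   (rownames = samples, colnames = variant ids) and `variants`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (any(variants$pos < 1)) stop("variant positions must be >= 1 (1-based)")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  ord <- order(natural_chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d chromosomes, %.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom)),
              100 * nm / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x genotype_matrix.
#' @param i sample index (logical, integer or character).
#' @param j variant index (logical, integer or character).
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$variants$id)
  d <- x$dosages[i, j, drop = FALSE]
  genotype_matrix(d, rownames(d), x$variants[j, , drop = FALSE])
}

#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.genotype_matrix <- function(x) rownames(x$dosages)

#' Natural-order rank of chromosome names
#'
#' Ranks chromosome names so that any trailing integer sorts numerically
#' ("Chr2" < "Chr10"); purely alphabetic names sort lexicographically after
#' splitting off the shared prefix.
#'
#' @param chrom character vector.
#' @return integer rank usable as a sort key.
#' @keywords internal
natural_chrom_rank <- function(chrom) {
  u <- unique(chrom)
  pre <- sub("([0-9]+)$", "", u)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", u)))
  num[pre == u] <- NA  # no numeric suffix
  ord <- order(pre, num, u, na.last = TRUE)
  match(chrom, u[ord])
}
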