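#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into a [genotype_matrix()] of
#' ALT-allele dosages. Multiallelic records are dropped with a message
#' (downstream statistics assume biallelic SNPs). `"./."` and half-missing
#' calls (`"./1"`) become missing; non-diploid GT strings are an error.
#'
#' @param path VCF file (plain text or gzipped).
#' @param missing_policy `"mask"` keeps missing calls as `NA`;
#'   `"mode-impute"` replaces them with the most frequent dosage at the site
#'   (ties to the lower dosage).
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, missing_policy = c("mask", "mode-impute")) {
  missing_policy <- match.arg(missing_policy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi)) {
    message("dropping ", sum(multi), " multiallelic/non-SNP record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    if (nrow(fix) == 0) stop("no biallelic SNP records left")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  gt[is.na(gt)] <- "./."
  alleles <- strsplit(gsub("\\|", "/", as.vector(gt)), "/", fixed = TRUE)
  nall <- lengths(alleles)
  if (any(nall != 2)) stop("unsupported ploidy: GT with ", nall[nall != 2][1],
                           " allele(s) found; diploid GT required")
  a <- matrix(unlist(alleles), nrow = 2)
  dos <- suppressWarnings(as.integer(a[1, ]) + as.integer(a[2, ]))
  dos[a[1, ] == "." | a[2, ] == "."] <- NA_integer_
  if (any(dos > 2, na.rm = TRUE)) stop("allele index > 1 in biallelic record")
  dosages <- t(matrix(dos, nrow = nrow(fix), ncol = length(samples)))
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix$CHROM[blank], "_", fix$POS[blank])
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, id = ids,
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(dosages, samples, variants)
  if (missing_policy == "mode-impute") g <- impute_mode(g)
  g
}

#' Replace missing dosages with the per-site modal dosage
#'
#' @param g genotype_matrix.
#' @return genotype_matrix with no missing calls (all-missing sites stay NA).
#' @export
impute_mode <- function(g) {
  d <- g$dosages
  for (j in which(colSums(is.na(d)) > 0)) {
    x <- d[, j]
    tab <- tabulate(x + 1L, nbins = 3L)
    if (all(tab == 0L)) next
    d[is.na(x), j] <- which.max(tab) - 1L
  }
  genotype_matrix(d, rownames(d), g$variants)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits a plain-text VCF with a GT-only FORMAT so that
#' `read_vcf(write_vcf(g))` round-trips dosages and coordinates exactly
#' (dosage 1 is written as the unphased heterozygote `0/1`).
#'
#' @param g genotype_matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=clinalscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids(g)), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(g$dosages), ncol = nrow(g$dosages))
  ok <- !is.na(t(g$dosages))
  gt[ok] <- code[t(g$dosages)[ok] + 1L]
  v <- g$variants
  lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
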