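#' Common-garden BLUPs of accession trait values
#'
#' Fits y = mu + garden(random) + accession(random) + residual by REML
#' (through `lme4::lmer`) and returns mu + the accession BLUP for each
#' accession. With a single garden the garden variance is fixed at zero
#' (with a warning) and the model reduces to the classical one-way
#' shrinkage of accession means.
#'
#' @param records data.frame with columns `accession`, `garden`, `value`
#'   and optionally `trait` (one model per trait).
#' @return data.frame of class `blup_table`: `accession_id`, `trait`,
#'   `blup`, `n_records`; attribute `varcomp` holds the estimated variance
#'   components (garden, accession, residual) per trait.
#' @export
estimate_blups <- function(records) {
  stopifnot(all(c("accession", "garden", "value") %in% names(records)))
  records <- records[!is.na(records$value), , drop = FALSE]
  if (!"trait" %in% names(records)) records$trait <- "trait"
  out <- list(); vc <- list()
  for (tr in unique(records$trait)) {
    rec <- records[records$trait == tr, , drop = FALSE]
    if (length(unique(rec$accession)) < 2)
      stop("need at least two accessions for trait ", tr)
    one_garden <- length(unique(rec$garden)) < 2
    if (one_garden) {
      warning("trait ", tr,
              ": single common garden; garden variance fixed at 0")
      fit <- lme4::lmer(value ~ (1 | accession), data = rec, REML = TRUE)
    } else {
      fit <- lme4::lmer(value ~ (1 | garden) + (1 | accession), data = rec,
                        REML = TRUE)
    }
    mu <- unname(lme4::fixef(fit)[1])
    re <- lme4::ranef(fit)$accession
    vcd <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(grp) {
      i <- match(grp, vcd$grp)
      if (is.na(i)) 0 else vcd$vcov[i]
    }
    vc[[tr]] <- c(garden = getv("garden"), accession = getv("accession"),
                  residual = getv("Residual"))
    nrec <- table(rec$accession)
    out[[tr]] <- data.frame(accession_id = rownames(re), trait = tr,
                            blup = mu + re[[1]],
                            n_records = as.integer(nrec[rownames(re)]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "varcomp") <- vc
  class(res) <- c("blup_table", "data.frame")
  res
}
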