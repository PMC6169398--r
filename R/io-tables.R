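#' Read a georeferenced sample table
#'
#' Reads a delimited text table (header required) with one row per
#' accession: `sample_id`, `latitude`, `longitude`, any number of numeric
#' climate columns, and optional `race` / `group` columns. Accessions with
#' missing coordinates are retained (they can be genotyped without being
#' georeferenced); use [georeferenced()] to subset to mappable samples.
#'
#' @param path delimited text file; separator auto-detected (tab or comma).
#' @param climate_vars optional character vector naming the climate columns;
#'   defaults to all numeric columns other than latitude/longitude/group.
#' @return data.frame of class `sample_table` with attribute `climate_vars`.
#' @export
read_sample_table <- function(path, climate_vars = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE)
  sample_table(df, climate_vars = climate_vars)
}

#' Construct a sample table from a data.frame
#'
#' @param df data.frame with at least a `sample_id` column.
#' @inheritParams read_sample_table
#' @return data.frame of class `sample_table`.
#' @export
sample_table <- function(df, climate_vars = NULL) {
  if (!"sample_id" %in% names(df)) stop("sample table needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (is.null(climate_vars)) {
    numc <- names(df)[vapply(df, is.numeric, logical(1))]
    climate_vars <- setdiff(numc, c("latitude", "longitude", "group"))
  }
  bad <- vapply(df[climate_vars], function(x) any(is.infinite(x)), logical(1))
  if (any(bad)) stop("non-finite climate values in: ",
                     paste(climate_vars[bad], collapse = ", "))
  structure(df, climate_vars = climate_vars,
            class = c("sample_table", "data.frame"))
}

#' Subset a sample table to georeferenced accessions
#'
#' @param st sample_table.
#' @return sample_table with finite latitude and longitude only.
#' @export
georeferenced <- function(st) {
  keep <- is.finite(st$latitude) & is.finite(st$longitude)
  sample_table(as.data.frame(st)[keep, , drop = FALSE],
               climate_vars = attr(st, "climate_vars"))
}

#' Align a sample table with a genotype matrix
#'
#' @param st sample_table.
#' @param g genotype_matrix.
#' @return list with the table rows matching `g` in genotype order and the
#'   ids present in only one of the two inputs.
#' @export
align_samples <- function(st, g) {
  ids <- sample_ids(g)
  m <- match(ids, st$sample_id)
  list(table = as.data.frame(st)[m, , drop = FALSE],
       missing_from_table = ids[is.na(m)],
       missing_from_genotypes = setdiff(st$sample_id, ids))
}

#' Read a gene annotation from GFF3 or BED
#'
#' Format is auto-detected from the file extension (`.gff`/`.gff3` 1-based
#' closed, `.bed` 0-based half-open). Coordinates are normalized internally
#' to 0-based half-open. For GFF3, rows of type `gene` are used when
#' present (otherwise all rows); the gene id is taken from the `ID`
#' attribute (falling back to `Name`).
#'
#' @param path annotation file.
#' @param candidate_list character vector of a-priori candidate gene ids;
#'   membership sets the `is_candidate` flag.
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open) and `is_candidate`.
#' @export
read_genes <- function(path, candidate_list = character()) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
         else if ("Name" %in% names(mc)) as.character(mc$Name)
         else if ("name" %in% names(mc)) as.character(mc$name)
         else paste0("gene", seq_along(gr))
  gene_annotation(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE), candidate_list)
}

#' Construct a gene annotation table
#'
#' @param df data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @inheritParams read_genes
#' @return gene_annotation data.frame.
#' @export
gene_annotation <- function(df, candidate_list = character()) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("gene intervals need start < end")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df$is_candidate <- df$gene_id %in% candidate_list
  df <- df[order(natural_chrom_rank(df$chrom), df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` phylo object (e.g. from [nj_tree()]).
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "nj_tree")) tree <- tree$phylo
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a table as tab-delimited text
#'
#' Numeric columns are written at full precision (`%.15g`) so that
#' write/read round trips preserve values to 1e-12.
#'
#' @param obj data.frame.
#' @param path output file.
#' @export
write_table <- function(obj, path) {
  df <- as.data.frame(obj)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
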