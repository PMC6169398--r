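#' Run the full clinal-adaptation analysis pipeline
#'
#' Executes QC filtering, population-genetic summaries, structure analysis,
#' RDA variance partitioning with its permutation test, environmental
#' association scans with outlier selection, and candidate-gene
#' colocalization/enrichment, from a single configuration. Each stage
#' writes its output to `<out_dir>/<stage>.rds` and is skipped on rerun if
#' that file already exists (checkpointing); a JSON summary of headline
#' numbers and every threshold used is written at the end.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `vcf`, `sample_table`, `genes`, `candidates` (input paths), or
#'   `simulate` (a list of [landscape_config()] arguments used instead of
#'   file input); `filters` (`max_missing`, `min_maf`, `min_mac`);
#'   `windows` (`pi_bp`, `tajima_bp`, `coloc_bp`); `prune_r2`; `n_perm`;
#'   `outlier_quantile`; `k_max`; `climate_vars` (column names scanned;
#'   default all climate columns); `seed`.
#' @param out_dir run directory (created if needed).
#' @param overwrite if TRUE, existing stage outputs are recomputed.
#' @return list with the stage results and the summary (invisibly also
#'   written to `summary.json` and `run.log` under `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(filters = list(max_missing = 0.2, min_maf = 0.03,
                                  min_mac = 3),
                   windows = list(pi_bp = 1000, tajima_bp = 1e5,
                                  coloc_bp = 1e5),
                   prune_r2 = 0.5, n_perm = 1000, outlier_quantile = 0.01,
                   k_max = 6, seed = 1)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                sprintf(...), "\n", file = logfile,
                                append = TRUE)
  stage <- function(name, fun) {
    path <- file.path(out_dir, paste0(name, ".rds"))
    if (file.exists(path) && !overwrite) {
      log_line("[%s] reusing checkpoint", name)
      return(readRDS(path))
    }
    log_line("[%s] computing", name)
    val <- fun()
    saveRDS(val, path)
    val
  }

  inputs <- stage("input", function() {
    if (!is.null(config$simulate)) {
      lc_args <- config$simulate[intersect(names(config$simulate),
                                           names(formals(landscape_config)))]
      sim <- simulate_landscape(do.call(landscape_config, lc_args))
      genes <- place_candidate_genes(
        sim$truth,
        n_genes = config$simulate$n_genes %||% 500,
        n_candidates = config$simulate$n_candidates %||% 50,
        linked_fraction = config$simulate$linked_fraction %||% 0,
        window_bp = config$windows$coloc_bp,
        seed = config$seed)
      list(genotypes = sim$genotypes, samples = sim$samples,
           truth = sim$truth, genes = genes)
    } else {
      cand <- if (!is.null(config$candidates))
        readLines(config$candidates) else character()
      list(genotypes = read_vcf(config$vcf),
           samples = read_sample_table(config$sample_table),
           truth = NULL,
           genes = if (!is.null(config$genes))
             read_genes(config$genes, cand) else NULL)
    }
  })

  qc <- stage("qc", function() {
    filt <- filter_variants(inputs$genotypes,
                            max_missing = config$filters$max_missing,
                            min_maf = config$filters$min_maf,
                            min_mac = config$filters$min_mac)
    filt$sample_qc <- sample_qc(filt$genotypes)
    filt
  })
  g <- qc$genotypes

  popgen <- stage("popgen", function() {
    list(pi = nucleotide_diversity_windows(g, config$windows$pi_bp),
         tajima = tajima_d_windows(g, config$windows$tajima_bp))
  })

  struct <- stage("structure", function() {
    gp <- ld_prune(g, r2_threshold = config$prune_r2)
    dapc <- dapc_find_clusters(gp, k_max = config$k_max, seed = config$seed)
    fst <- weir_cockerham_fst(g, dapc$assignments)
    list(pruned_n = ncol(gp$dosages), dapc = dapc, fst_groups = fst)
  })

  al <- align_samples(inputs$samples, g)
  geo <- is.finite(al$table$latitude) & is.finite(al$table$longitude)
  climate_vars <- config$climate_vars %||% attr(inputs$samples, "climate_vars")

  vp <- stage("varpart", function() {
    Xc <- as.matrix(al$table[geo, climate_vars, drop = FALSE])
    Xs <- as.matrix(al$table[geo, c("latitude", "longitude")])
    Y <- g$dosages[geo, , drop = FALSE]
    permute_collinear_test(Y, Xc, Xs, n_perm = config$n_perm,
                           seed = config$seed)
  })

  scans <- stage("scans", function() {
    lapply(setNames(climate_vars, climate_vars), function(v) {
      sc <- glm_scan(g[geo, ], al$table[geo, v],
                     min_maf = config$filters$min_maf)
      select_outliers(sc, quantile = config$outlier_quantile)
    })
  })

  enrich <- stage("enrichment", function() {
    if (is.null(inputs$genes)) return(NULL)
    cand_ids <- inputs$genes$gene_id[inputs$genes$is_candidate]
    per_var <- lapply(scans, function(sc) {
      pts <- sc[sc$outlier, c("chrom", "pos")]
      cl <- colocalize(pts, inputs$genes, window_bp = config$windows$coloc_bp)
      chisq_enrichment(cl$genes$hit[cl$genes$is_candidate], cl$genes$hit)
    })
    tj <- tajima_gene_permutation(popgen$tajima, inputs$genes, cand_ids,
                                  d_threshold = 0, n_perm = config$n_perm,
                                  seed = config$seed)
    list(coloc_chisq = per_var, tajima_perm = tj)
  })

  summary <- list(
    config = config[c("filters", "windows", "prune_r2", "n_perm",
                      "outlier_quantile", "k_max", "seed")],
    n_samples = nrow(g$dosages),
    n_variants_in = qc$n_in, n_variants_kept = qc$n_out,
    filter_report = as.list(qc$report),
    mean_observed_het = mean(qc$sample_qc$observed_het, na.rm = TRUE),
    mean_inbreeding_f = mean(qc$sample_qc$inbreeding_f, na.rm = TRUE),
    mean_pi_per_bp = mean(popgen$pi$value),
    mean_tajima_d = mean(popgen$tajima$value, na.rm = TRUE),
    k_selected = struct$dapc$k_selected,
    fst_among_groups = struct$fst_groups$global,
    varpart = list(climate_unique = vp$frac_climate_unique,
                   collinear = vp$frac_collinear,
                   space_unique = vp$frac_space_unique,
                   residual = vp$frac_residual,
                   perm_p = vp$perm_p_collinear),
    outlier_counts = lapply(scans, function(s) sum(s$outlier)),
    enrichment = if (!is.null(enrich)) list(
      chisq_p = lapply(enrich$coloc_chisq, function(e) e$chi2_p),
      tajima_perm_p = enrich$tajima_perm$perm_p) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_line("pipeline complete")
  invisible(list(inputs = inputs, qc = qc, popgen = popgen,
                 structure = struct, varpart = vp, scans = scans,
                 enrichment = enrich, summary = summary,
                 out_dir = out_dir))
}
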