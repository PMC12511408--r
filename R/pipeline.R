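#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Defaults follow the
#' analysis's standard parameters: 0.1% abundance / 2-specimen prevalence
#' filter, transit conditioning, 999 permutations, 60-degree projection
#' cone with 0.5 score cutoff, 500-bootstrap consensus network with 50%
#' edge retention.
#'
#' @param abundance_path,metadata_path Input TSV paths (ignored when a
#'   `generator` config is given).
#' @param generator Optional [cohort_config()]; when supplied the cohort is
#'   simulated instead of read from disk.
#' @param ko_path Optional KO abundance TSV for the GMM stage.
#' @param gmm_path Optional GMM definition TSV.
#' @param constraints SCFA constraint columns.
#' @param conditions Conditioning columns.
#' @param covariates Covariate columns for PERMANOVA adjustment and the
#'   per-feature linear models.
#' @param abundance_min,min_prevalent_samples Filter thresholds.
#' @param alr_reference ALR reference feature (`NULL` = automatic).
#' @param n_perm,cone_deg,score_min,n_boot,retention Stage parameters.
#' @param run_bn Run the consensus-network stage (the slowest; default
#'   `TRUE`).
#' @param seed Global seed fanned out to per-stage seeds by fixed offsets.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance_path = NULL, metadata_path = NULL,
                            generator = NULL, ko_path = NULL, gmm_path = NULL,
                            constraints = c("acetate", "butyrate", "propionate",
                                            "acetate_butyrate_ratio"),
                            conditions = "transit_days",
                            covariates = c("age", "sex", "bmi"),
                            abundance_min = 0.001, min_prevalent_samples = 2,
                            alr_reference = NULL,
                            n_perm = 999, cone_deg = 60, score_min = 0.5,
                            n_boot = 500, retention = 0.5,
                            run_bn = TRUE, seed = 1, out_dir = NULL) {
  if (is.null(generator) && (is.null(abundance_path) || is.null(metadata_path))) {
    abort("supply either input paths or a generator config",
          class = "scfamap_config_error")
  }
  if (n_perm < 1 || n_boot < 1 || cone_deg <= 0 || score_min < 0 ||
      retention < 0 || retention > 1) {
    abort("invalid stage parameter(s)", class = "scfamap_config_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments; an optional `generator` block is passed to
#'   [cohort_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  rlang::check_installed("yaml", reason = "to read YAML pipeline configs")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$generator)) {
    gen <- cfg$generator
    if (!is.null(gen$n_per_group)) gen$n_per_group <- unlist(gen$n_per_group)
    if (!is.null(gen$drivers)) gen$drivers <- bind_rows(gen$drivers)
    cfg$generator <- do.call(cohort_config, gen)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full microbe-SCFA analysis pipeline
#'
#' Executes, in order: load or simulate the cohort; align samples;
#' abundance/prevalence filter; ALR transform; Bray-Curtis PERMANOVA
#' (unadjusted and covariate-adjusted); transit-conditioned pCCA with
#' permutation test (overall cohort); per-group projection rankings;
#' bootstrap consensus network over retained taxa + SCFAs + transit;
#' trait comparisons and covariate-adjusted per-taxon models; optionally
#' the GMM/KO stage. A failure in the network stage does not abort earlier
#' results.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run`: stage results plus a `manifest`
#'   tibble of written files (when `out_dir` is set) and a `log` tibble of
#'   per-stage sample/feature counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- tibble(stage = stage, ...)
  }

  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator, seed = stage_seed(config$seed, 0))
    table <- cohort$table; meta <- cohort$meta
  } else {
    cohort <- NULL
    table <- read_abundance_table(config$abundance_path, kind = "relative",
                                  renormalize = TRUE)
    meta <- read_metadata(config$metadata_path)
    aligned <- align_samples(table, meta)
    table <- aligned$table; meta <- aligned$meta
  }
  note("input", n_samples = nrow(table), n_features = length(feature_ids(table)))

  filt <- filter_high_abundant(table, meta, config$abundance_min,
                               config$min_prevalent_samples)
  note("filter", n_samples = nrow(filt$table),
       n_features = length(feature_ids(filt$table)))
  # re-close the retained panel so downstream compositional math sees
  # proper compositions
  ftab <- relative_abundance(filt$table)
  alr <- alr_transform(ftab, reference = config$alr_reference)

  perm_unadj <- permanova(bray_curtis(table), meta, group = "group",
                          n_perm = config$n_perm,
                          seed = stage_seed(config$seed, 1))
  covs <- intersect(config$covariates, names(meta))
  perm_adj <- if (length(covs) > 0) {
    permanova(bray_curtis(table), meta, group = "group", covariates = covs,
              n_perm = config$n_perm, seed = stage_seed(config$seed, 2))
  } else NULL

  use <- complete.cases(meta[c(config$constraints, config$conditions)])
  pcca_test <- pcca_permutation_test(
    relative_abundance(ftab[use, , drop = FALSE]), meta[use, , drop = FALSE],
    constraints = config$constraints, conditions = config$conditions,
    n_perm = config$n_perm, seed = stage_seed(config$seed, 3))
  note("pcca", n_samples = sum(use),
       n_features = length(feature_ids(ftab)))

  rankings <- rank_by_group(table, meta, constraints = config$constraints,
                            conditions = config$conditions,
                            cone_deg = config$cone_deg,
                            score_min = config$score_min,
                            abundance_min = config$abundance_min,
                            min_prevalent_samples = config$min_prevalent_samples)

  network <- NULL
  if (isTRUE(config$run_bn)) {
    network <- tryCatch({
      # network over the taxa under validation (projection-retained), the
      # SCFA quantities and the conditioning variable
      ret_taxa <- unique(rankings$feature_id[rankings$retained])
      taxa_cols <- intersect(ret_taxa, names(alr))
      if (length(taxa_cols) == 0) taxa_cols <- setdiff(names(alr), "sample_id")
      nd <- bind_cols(alr[taxa_cols],
                      meta[c(config$constraints, config$conditions)])
      nd <- nd[complete.cases(nd), , drop = FALSE]
      bootstrap_consensus(nd, n_boot = config$n_boot,
                          retention = config$retention,
                          seed = stage_seed(config$seed, 4))
    }, error = function(e) {
      warn(sprintf("network stage failed (%s); earlier results kept",
                   conditionMessage(e)))
      NULL
    })
  }

  traits <- purrr::map(
    intersect(c(config$constraints, "total_scfa", config$conditions,
                "total_bile_acids", "pct_primary_bile_acids"), names(meta)),
    function(tr) tryCatch(glance(kruskal_dunn(meta, tr)), error = function(e) NULL)
  ) |> bind_rows()

  lev <- levels(droplevels(as.factor(meta$group)))
  diff_taxa <- if (length(lev) >= 2) {
    purrr::map(utils::combn(lev, 2, simplify = FALSE), function(pr) {
      adjusted_feature_model(alr, meta, covariates = covs,
                             contrast = c(pr[2], pr[1]))
    }) |> bind_rows()
  } else NULL
  folds <- fold_change_screen(table, meta)

  gmm_res <- NULL
  if (!is.null(config$gmm_path) &&
      (!is.null(config$ko_path) || !is.null(cohort))) {
    gmm_res <- tryCatch({
      gmm <- read_gmm_definitions(config$gmm_path)
      ko <- if (!is.null(config$ko_path)) {
        read_abundance_table(config$ko_path, kind = "counts")
      } else {
        generate_ko_table(cohort, gmm, seed = stage_seed(config$seed, 5))
      }
      gmm_associate(ko, gmm, meta, covariates = covs,
                    target = config$constraints[1])
    }, error = function(e) {
      warn(sprintf("GMM stage skipped (%s)", conditionMessage(e)))
      NULL
    })
  } else if (!is.null(config$gmm_path) || !is.null(config$ko_path)) {
    warn("GMM stage skipped: needs both a KO table (or generator) and GMM definitions")
  }

  results <- list(filter_report = filt$report,
                  permanova_unadjusted = perm_unadj,
                  permanova_adjusted = perm_adj,
                  pcca_test = pcca_test,
                  rankings = rankings,
                  ranking_counts = attr(rankings, "counts"),
                  network = network,
                  traits = traits,
                  differential_taxa = diff_taxa,
                  fold_changes = folds,
                  gmm = gmm_res)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    exportable <- list(
      filter_report = filt$report,
      permanova_unadjusted = tidy(perm_unadj),
      pcca_eigenvalues = tidy(pcca_test$fit, "eigenvalues"),
      pcca_species_scores = tidy(pcca_test$fit, "species"),
      pcca_biplot = tidy(pcca_test$fit, "biplot"),
      rankings = rankings,
      fold_changes = folds,
      traits = traits
    )
    if (!is.null(perm_adj)) exportable$permanova_adjusted <- tidy(perm_adj)
    if (!is.null(network)) exportable$network_edges <- tidy(network)
    if (!is.null(diff_taxa)) exportable$differential_taxa <- diff_taxa
    if (!is.null(gmm_res)) exportable$gmm_associations <- tidy(gmm_res)
    manifest <- write_result_tables(exportable, config$out_dir)
  }

  structure(c(results,
              list(manifest = manifest, log = bind_rows(log),
                   config = config, cohort = cohort)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("scfamap pipeline run\n")
  print(as.data.frame(x$log), row.names = FALSE)
  cat(sprintf("PERMANOVA (unadjusted): F = %.3f, p = %.4g\n",
              x$permanova_unadjusted$pseudo_F, x$permanova_unadjusted$p_value))
  cat(sprintf("pCCA: F = %.3f, p = %.4g, R2 = %.4f\n",
              x$pcca_test$pseudo_F, x$pcca_test$p_value, x$pcca_test$fit$R2))
  if (!is.null(x$ranking_counts)) {
    cat("retained taxa per group x SCFA:\n")
    print(as.data.frame(x$ranking_counts), row.names = FALSE)
  }
  invisible(x)
}
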