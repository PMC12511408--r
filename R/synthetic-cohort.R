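#' Synthetic cohort generator configuration
#'
#' Builds the configuration for [generate_cohort()]. Defaults emulate a
#' three-group stool-metagenome study (healthy volunteers and two IBS
#' subtypes): logistic-normal species compositions with a power-law
#' abundance skeleton, a colonic-transit covariate that confounds both taxa
#' and SCFA, a small set of planted "driver" taxa with signed loadings on
#' individual SCFAs, and measurement noise on the SCFA concentrations.
#'
#' Structural roles of taxa under the defaults: taxon 1 (most abundant) is
#' the generator's internal log-ratio reference and carries no effect; taxa
#' 2-11 are SCFA drivers (5 positive, 5 negative loadings, sign-balanced
#' within each of acetate, butyrate and propionate); taxa 31-40 respond to
#' transit (slopes `delta`), creating taxa-SCFA confounding through transit
#' without any direct coupling.
#'
#' @param n_per_group Named integer vector of samples per clinical group.
#' @param p_taxa Number of species-level taxa (>= 10).
#' @param drivers Tibble with columns `taxon` (index), `scfa` (one of
#'   `"acetate"`, `"butyrate"`, `"propionate"`), `beta` (signed loading on
#'   the taxon's log-ratio) and optionally `group` (restrict the loading to
#'   one clinical group; `NA` = all).
#' @param beta Default absolute driver loading used to build the default
#'   `drivers` table (µg/mg per unit log-ratio).
#' @param delta_taxa Indices of transit-responsive taxa.
#' @param delta Log-abundance slope per day of transit for `delta_taxa`
#'   (alternating sign across those taxa).
#' @param gamma Named per-SCFA slope on transit (µg/mg per day); negative
#'   values mean slower transit lowers the measured concentration.
#' @param scfa_intercept Named per-SCFA intercepts (µg/mg dry weight).
#' @param transit_meanlog Named per-group mean of log transit days.
#' @param transit_sdlog Log-scale SD of transit.
#' @param sigma_taxa Latent log-abundance dispersion (> 0).
#' @param sigma_scfa SCFA measurement noise SD (µg/mg, > 0).
#' @param base_logmean Log-abundance skeleton, length `p_taxa`; default is
#'   a power-law decay giving heavy right-skewed compositions.
#' @param guild_cor Correlation (0-1) of latent log-abundance among drivers
#'   of the same SCFA acting in the same direction, mimicking the
#'   co-occurrence of cross-feeding producer guilds.
#' @param count_depth If not `NULL`, also draw multinomial counts at this
#'   sequencing depth per sample.
#' @param bam_threshold Total stool bile-acid level (µmol/48h) above which
#'   the synthetic bile-acid-malabsorption flag is set.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HV = 17L, `IBS-C` = 15L, `IBS-D` = 26L),
                          p_taxa = 100L,
                          drivers = NULL,
                          beta = 2.0,
                          delta_taxa = 31:40,
                          delta = 0.8,
                          gamma = c(acetate = -1.5, butyrate = -0.6, propionate = -0.6),
                          scfa_intercept = c(acetate = 8, butyrate = 6, propionate = 6),
                          transit_meanlog = c(HV = log(1.4), `IBS-C` = log(1.5), `IBS-D` = log(0.9)),
                          transit_sdlog = 0.55,
                          sigma_taxa = 2.0,
                          sigma_scfa = 0.4,
                          base_logmean = NULL,
                          guild_cor = 0.8,
                          count_depth = NULL,
                          bam_threshold = 1000,
                          seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    abort("n_per_group must be a named vector of group sizes",
          class = "scfamap_config_error")
  }
  if (any(n_per_group < 1)) {
    abort("every included group needs at least 1 sample",
          class = "scfamap_config_error")
  }
  if (p_taxa < 10) {
    abort("p_taxa must be at least 10", class = "scfamap_config_error")
  }
  if (sigma_taxa <= 0 || sigma_scfa <= 0 || transit_sdlog <= 0) {
    abort("all dispersion parameters must be positive",
          class = "scfamap_config_error")
  }
  if (is.null(drivers)) {
    # 5 positive and 5 negative loadings, sign-balanced within each SCFA so
    # that the shared log-ratio reference channel cancels (an unbalanced set
    # leaks reference noise into every taxon's marginal association)
    drivers <- tibble(
      taxon = 2:11,
      scfa = rep(c("acetate", "butyrate", "propionate"), c(4, 4, 2)),
      beta = beta * rep(c(1, -1), length.out = 10),
      group = NA_character_
    )
  }
  drivers <- as_tibble(drivers)
  if (!"group" %in% names(drivers)) drivers$group <- NA_character_
  if (any(drivers$taxon > p_taxa) || any(drivers$taxon < 1)) {
    abort("driver taxon indices must lie in [1, p_taxa]",
          class = "scfamap_config_error")
  }
  if (!all(drivers$scfa %in% c("acetate", "butyrate", "propionate"))) {
    abort("driver scfa must be acetate, butyrate or propionate",
          class = "scfamap_config_error")
  }
  delta_taxa <- delta_taxa[delta_taxa <= p_taxa]
  if (is.null(base_logmean)) {
    base_logmean <- -1.2 * log(seq_len(p_taxa))
  }
  if (length(base_logmean) != p_taxa) {
    abort("base_logmean must have length p_taxa", class = "scfamap_config_error")
  }
  transit_meanlog <- transit_meanlog[groups]
  if (anyNA(transit_meanlog)) {
    transit_meanlog <- setNames(rep(log(1.2), length(groups)), groups)
  }
  structure(list(
    n_per_group = n_per_group, p_taxa = as.integer(p_taxa), drivers = drivers,
    delta_taxa = as.integer(delta_taxa), delta = delta, gamma = gamma,
    scfa_intercept = scfa_intercept, transit_meanlog = transit_meanlog,
    transit_sdlog = transit_sdlog, sigma_taxa = sigma_taxa,
    sigma_scfa = sigma_scfa, base_logmean = base_logmean,
    guild_cor = guild_cor,
    count_depth = count_depth, bam_threshold = bam_threshold,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Draw noise vectors repeatedly until value > 0 (truncation by resampling,
# which avoids a point mass at zero).
resample_positive <- function(mean_part, sd, max_iter = 1000L) {
  out <- mean_part + rnorm(length(mean_part), 0, sd)
  bad <- which(out <= 0)
  it <- 0L
  while (length(bad) > 0 && it < max_iter) {
    out[bad] <- mean_part[bad] + rnorm(length(bad), 0, sd)
    bad <- bad[out[bad] <= 0]
    it <- it + 1L
  }
  if (length(bad) > 0) out[bad] <- pmax(mean_part[bad], 0) + abs(rnorm(length(bad), 0, sd))
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-group transit times (log-normal), latent log-abundances
#' (skeleton + transit slopes + Gaussian dispersion), closes them to
#' compositions by softmax, and generates SCFA concentrations as linear
#' functions of driver-taxon log-ratios plus a transit slope plus Gaussian
#' noise truncated at zero by resampling. The acetate:butyrate ratio,
#' total SCFA, stool bile acids, a bile-acid-malabsorption flag and
#' baseline covariates (age, sex, BMI, diet) are derived alongside.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   (config, seed) pairs give bit-identical cohorts.
#' @return A list with `table` (relative-abundance tibble), `meta`
#'   (metadata tibble) and `truth` (list: `drivers`, `delta`, `gamma`,
#'   `latent_log`, `reference`, `config`, `seed`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = c(HV = 5, `IBS-D` = 5),
#'                                         p_taxa = 20), seed = 7)
#' dim(cohort$table)
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- as.integer(seed %||% config$seed)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  groups <- names(config$n_per_group)
  n <- sum(config$n_per_group)
  p <- config$p_taxa
  group <- factor(rep(groups, config$n_per_group), levels = groups)
  sample_id <- sprintf("S%03d", seq_len(n))

  transit <- rlnorm(n, meanlog = config$transit_meanlog[as.character(group)],
                    sdlog = config$transit_sdlog)

  delta_vec <- numeric(p)
  if (length(config$delta_taxa) > 0) {
    delta_vec[config$delta_taxa] <-
      config$delta * rep(c(1, -1), length.out = length(config$delta_taxa))
  }
  latent <- matrix(rnorm(n * p, 0, config$sigma_taxa), n, p)
  # producer-guild co-occurrence: drivers of the same SCFA acting in the
  # same direction share a latent factor
  rho <- config$guild_cor %||% 0
  if (rho > 0 && nrow(config$drivers) > 0) {
    guild_key <- paste(config$drivers$scfa, sign(config$drivers$beta))
    for (gk in unique(guild_key)) {
      members <- config$drivers$taxon[guild_key == gk]
      if (length(members) < 2) next
      shared <- rnorm(n, 0, config$sigma_taxa)
      latent[, members] <- sqrt(1 - rho) * latent[, members] +
        sqrt(rho) * shared
    }
  }
  latent <- sweep(latent, 2, config$base_logmean, "+") +
    outer(transit - exp(mean(config$transit_meanlog)), delta_vec)
  rownames(latent) <- sample_id
  colnames(latent) <- sprintf("taxon_%03d", seq_len(p))

  e <- exp(latent - apply(latent, 1, max))
  comp <- sweep(e, 1, rowSums(e), "/")

  if (!is.null(config$count_depth)) {
    counts <- t(apply(comp, 1, function(pr) {
      as.numeric(stats::rmultinom(1, size = config$count_depth, prob = pr))
    }))
    dimnames(counts) <- dimnames(comp)
    comp <- close_rows(counts)
  } else {
    counts <- NULL
  }

  # exact planted log-linear effects: ALR w.r.t. taxon 1 equals the latent
  # log difference, so beta acts on the scale the downstream ALR sees
  ref_idx <- 1L
  alr_latent <- latent - latent[, ref_idx]
  scfa_names <- c("acetate", "butyrate", "propionate")
  expected_alr <- config$base_logmean - config$base_logmean[ref_idx]

  scfa <- sapply(scfa_names, function(s) {
    mu <- rep(config$scfa_intercept[[s]], n)
    dr <- config$drivers[config$drivers$scfa == s, , drop = FALSE]
    if (nrow(dr) > 0) {
      for (k in seq_len(nrow(dr))) {
        contrib <- dr$beta[k] * (alr_latent[, dr$taxon[k]] - expected_alr[dr$taxon[k]])
        if (!is.na(dr$group[k])) contrib <- contrib * (group == dr$group[k])
        mu <- mu + contrib
      }
    }
    g <- config$gamma[[s]] %||% 0
    mu <- mu + g * (transit - exp(mean(config$transit_meanlog)))
    resample_positive(mu, config$sigma_scfa)
  })

  bile_med <- c(HV = 342, `IBS-C` = 190, `IBS-D` = 607)
  bl <- bile_med[as.character(group)]
  bl[is.na(bl)] <- 350
  total_bile <- rlnorm(n, meanlog = log(bl), sdlog = 0.7)
  pct_primary <- 100 * stats::rbeta(n, 1.2, 20)

  meta <- tibble(
    sample_id = sample_id,
    group = group,
    age = round(pmin(pmax(rnorm(n, 35.5, 13.8), 18), 65), 1),
    sex = stats::rbinom(n, 1, 0.75),
    bmi = round(pmin(pmax(rnorm(n, 26.2, 7.5), 16), 55), 1),
    energy_kcal = round(pmax(rnorm(n, 1800, 600), 600)),
    starch_g = round(pmax(rnorm(n, 100, 50), 5), 1),
    protein_g = round(pmax(rnorm(n, 90, 40), 10), 1),
    transit_days = transit,
    acetate = scfa[, "acetate"],
    butyrate = scfa[, "butyrate"],
    propionate = scfa[, "propionate"],
    total_scfa = rowSums(scfa),
    acetate_butyrate_ratio = scfa[, "acetate"] / scfa[, "butyrate"],
    total_bile_acids = total_bile,
    pct_primary_bile_acids = pct_primary,
    bam = total_bile > config$bam_threshold
  )

  truth <- list(
    drivers = mutate(config$drivers,
                     feature_id = sprintf("taxon_%03d", .data$taxon)),
    delta = setNames(delta_vec, colnames(latent)),
    gamma = config$gamma,
    latent_log = latent,
    counts = counts,
    reference = colnames(latent)[ref_idx],
    config = config,
    seed = seed
  )
  list(table = as_abundance_tibble(comp), meta = meta, truth = truth)
}

#' Generate a synthetic KO functional table tied to taxa
#'
#' Draws KO (KEGG orthogroup) abundances as noisy linear functions of
#' designated taxa in a generated cohort, for exercising the
#' gut-metabolic-module association stage with known ground truth.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param gmm GMM definition tibble ([read_gmm_definitions()] layout:
#'   `module_id`, `description`, list-column `ko_ids`).
#' @param ko_links Optional tibble `ko_id`, `feature_id`, `slope`; by
#'   default every KO in `gmm` is linked to a driver taxon (cycled) with
#'   slope 1.
#' @param noise_sd Gaussian noise SD on the KO scale.
#' @param seed Integer seed; defaults to the cohort's seed + 1.
#' @return An abundance tibble of KO columns (nonnegative values).
#' @export
generate_ko_table <- function(cohort, gmm, ko_links = NULL, noise_sd = 0.25,
                              seed = NULL) {
  if (is.null(gmm) || nrow(gmm) == 0) {
    abort("gmm definitions must be non-empty", class = "scfamap_config_error")
  }
  seed <- as.integer(seed %||% (cohort$truth$seed + 1L))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  kos <- unique(unlist(gmm$ko_ids))
  m <- abundance_matrix(cohort$table)
  if (is.null(ko_links)) {
    anchors <- cohort$truth$drivers$feature_id
    ko_links <- tibble(ko_id = kos,
                       feature_id = rep(anchors, length.out = length(kos)),
                       slope = 1)
  }
  ko_links <- ko_links[match(kos, ko_links$ko_id), , drop = FALSE]
  vals <- sapply(seq_along(kos), function(j) {
    x <- m[, ko_links$feature_id[j]]
    # scale taxon relative abundance to a comparable dynamic range
    z <- ko_links$slope[j] * x / max(stats::sd(x), 1e-12)
    pmax(z + rnorm(nrow(m), 0, noise_sd), 0)
  })
  colnames(vals) <- kos
  rownames(vals) <- rownames(m)
  as_abundance_tibble(vals)
}

# Seed scoping: set the RNG to `seed`, return a restorer closure.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}
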