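test_that("cohorts are deterministic, closed, and carry aligned ground truth", {
  cfg <- cohort_config(n_per_group = c(HV = 6, `IBS-C` = 5, `IBS-D` = 7),
                       p_taxa = 30)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$table, b$table)
  expect_identical(a$meta, b$meta)
  c_ <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$table, c_$table))

  m <- scfamap:::abundance_matrix(a$table)
  expect_equal(unname(rowSums(m)), rep(1, 18), tolerance = 1e-9)
  expect_true(all(m >= 0))
  expect_equal(a$meta$sample_id, a$table$sample_id)
  expect_equal(as.vector(table(a$meta$group)[c("HV", "IBS-C", "IBS-D")]),
               c(6L, 5L, 7L))
  expect_true(all(a$meta$acetate > 0 & a$meta$butyrate > 0))
  expect_equal(a$meta$acetate_butyrate_ratio,
               a$meta$acetate / a$meta$butyrate)
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(p_taxa = 5), class = "scfamap_config_error")
  expect_error(cohort_config(sigma_taxa = 0), class = "scfamap_config_error")
  expect_error(cohort_config(n_per_group = c(HV = 0, `IBS-D` = 5)),
               class = "scfamap_config_error")
  expect_error(cohort_config(drivers = tibble::tibble(
    taxon = 999, scfa = "acetate", beta = 1)), class = "scfamap_config_error")
  expect_error(cohort_config(drivers = tibble::tibble(
    taxon = 2, scfa = "lactate", beta = 1)), class = "scfamap_config_error")
})

test_that("with no planted effects taxa-SCFA correlations sit in the null band", {
  cfg <- cohort_config(
    n_per_group = c(HV = 100, `IBS-C` = 100, `IBS-D` = 100),
    drivers = tibble::tibble(taxon = integer(), scfa = character(),
                             beta = numeric(), group = character()),
    gamma = c(acetate = 0, butyrate = 0, propionate = 0),
    delta_taxa = integer())
  co <- generate_cohort(cfg, seed = 21)
  alr <- scfamap:::abundance_matrix(alr_transform(co$table))
  r <- abs(cor(alr, co$meta$acetate))
  # |r| < 0.15 for at least 95% of taxa at n = 300 (null band ~ 1.96/sqrt(n))
  expect_gt(mean(r < 0.15), 0.95)
})

test_that("a strong positive driver yields a positive ALR-SCFA correlation", {
  cfg <- cohort_config(
    n_per_group = c(HV = 150, `IBS-D` = 150),
    drivers = tibble::tibble(taxon = 2, scfa = "acetate", beta = 2,
                             group = NA_character_),
    sigma_scfa = 0.3)
  co <- generate_cohort(cfg, seed = 9)
  alr <- alr_transform(co$table, reference = co$truth$reference,
                       pseudocount = 1e-9)
  expect_gt(cor(scfamap:::abundance_matrix(alr)[, "taxon_002"],
                co$meta$acetate), 0.3)
})

test_that("transit confounds taxa and SCFA, and partialling transit removes it", {
  # gamma and delta nonzero but no direct taxa-SCFA coupling
  cfg <- cohort_config(
    n_per_group = c(HV = 100, `IBS-C` = 100, `IBS-D` = 100),
    drivers = tibble::tibble(taxon = integer(), scfa = character(),
                             beta = numeric(), group = character()),
    gamma = c(acetate = -3, butyrate = -1, propionate = -1),
    delta = 1.2)
  co <- generate_cohort(cfg, seed = 31)
  alr <- scfamap:::abundance_matrix(
    alr_transform(co$table, reference = co$truth$reference, pseudocount = 1e-9))
  delta_taxa <- names(which(co$truth$delta != 0))
  marg <- abs(cor(alr[, delta_taxa], co$meta$acetate))
  # unconditioned correlations biased away from zero
  expect_gt(median(marg), 0.15)
  # residualizing both sides on transit returns them to the null band
  rx <- apply(alr[, delta_taxa], 2, function(v)
    resid(lm(v ~ co$meta$transit_days)))
  ry <- resid(lm(co$meta$acetate ~ co$meta$transit_days))
  part <- abs(cor(rx, ry))
  expect_lt(median(part), 0.12)
  expect_gt(mean(part < 0.15), 0.9)
})

test_that("OLS on (driver ALR, transit) recovers the planted loading", {
  # moderate loadings and high intercepts keep the zero-truncation mass
  # negligible, so the planted linear model is exactly the data model
  cfg <- cohort_config(n_per_group = c(HV = 100, `IBS-C` = 100, `IBS-D` = 100),
                       beta = 0.5,
                       scfa_intercept = c(acetate = 40, butyrate = 40,
                                          propionate = 40))
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(cfg, seed = 400 + s)
    alr <- scfamap:::abundance_matrix(
      alr_transform(co$table, reference = co$truth$reference, pseudocount = 1e-9))
    dr <- co$truth$drivers[co$truth$drivers$scfa == "acetate", ]
    X <- cbind(alr[, dr$feature_id], transit = co$meta$transit_days)
    fit <- lm(co$meta$acetate ~ X)
    est <- coef(summary(fit))[1 + seq_len(nrow(dr)), ]
    ok <- abs(est[, "Estimate"] - dr$beta) <= 3 * est[, "Std. Error"]
    hits <- hits + all(ok)
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("KO tables track their anchor taxa and respect the seed", {
  gmm <- tibble::tibble(module_id = c("MF1", "MF2"),
                        description = c("a", "b"),
                        ko_ids = list(c("K00001", "K00002", "K00003"),
                                      c("K00004", "K00005", "K00006")))
  cfg <- cohort_config(n_per_group = c(HV = 150, `IBS-D` = 150), p_taxa = 30)
  co <- generate_cohort(cfg, seed = 12)
  ko <- generate_ko_table(co, gmm, noise_sd = 0.1, seed = 5)
  expect_equal(sort(scfamap:::feature_ids(ko)),
               sort(unlist(gmm$ko_ids)))
  expect_identical(ko, generate_ko_table(co, gmm, noise_sd = 0.1, seed = 5))
  # KO tied to a driver taxon with slope 1 and low noise correlates positively
  anchor <- co$truth$drivers$feature_id[1]
  expect_gt(cor(ko$K00001, scfamap:::abundance_matrix(co$table)[, anchor]), 0.5)
  expect_error(generate_ko_table(co, gmm[0, ]), class = "scfamap_config_error")
})
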