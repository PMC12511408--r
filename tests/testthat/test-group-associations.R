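test_that("Kruskal-Wallis H matches stats::kruskal.test with ties", {
  d <- tibble::tibble(group = factor(rep(c("HV", "IBS-C", "IBS-D"), each = 3)),
                      y = c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  tc <- kruskal_dunn(d, "y")
  ref <- kruskal.test(d$y, d$group)
  expect_equal(tc$kw_H, unname(ref$statistic))
  expect_equal(tc$kw_p, ref$p.value)
  expect_gt(tc$kw_p, 0.9)   # identical groups
  expect_equal(nrow(tc$pairwise), 3)

  set.seed(8)
  d2 <- tibble::tibble(group = factor(rep(c("a", "b", "c"), times = c(7, 9, 8))),
                       y = round(rnorm(24), 1))  # rounding forces ties
  tc2 <- kruskal_dunn(d2, "y")
  ref2 <- kruskal.test(d2$y, d2$group)
  expect_equal(tc2$kw_H, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(tc2$kw_p, ref2$p.value, tolerance = 1e-12)
})

test_that("Dunn z statistics match the mean-rank formula and Bonferroni triples p", {
  set.seed(3)
  d <- tibble::tibble(group = factor(rep(c("g1", "g2", "g3"), each = 8)),
                      y = c(rnorm(8), rnorm(8, 1), rnorm(8, 2)))
  tc <- kruskal_dunn(d, "y")
  # independent recomputation of one pair's z
  rk <- rank(d$y)
  n <- length(rk)
  mr <- tapply(rk, d$group, mean)
  ties <- table(rk)
  corr <- sum(ties^3 - ties) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - corr) * (1 / 8 + 1 / 8))
  z12 <- (mr[["g1"]] - mr[["g2"]]) / se
  row <- tc$pairwise[tc$pairwise$group_a == "g1" & tc$pairwise$group_b == "g2", ]
  expect_equal(row$dunn_z, z12, tolerance = 1e-12)
  expect_equal(row$p_raw, 2 * pnorm(-abs(z12)), tolerance = 1e-12)
  expect_equal(tc$pairwise$p_bonferroni,
               pmin(1, tc$pairwise$p_raw * 3), tolerance = 1e-12)
})

test_that("missing values are excluded per endpoint and degeneracy is flagged", {
  d <- tibble::tibble(group = factor(rep(c("A", "B"), each = 4)),
                      y = c(1, 2, 3, NA, 5, 6, 7, 8))
  tc <- kruskal_dunn(d, "y")
  expect_equal(tc$n_used, 7)
  dc <- tibble::tibble(group = factor(rep(c("A", "B"), each = 3)),
                       y = rep(2, 6))
  expect_warning(tcc <- kruskal_dunn(dc, "y"), "constant")
  expect_equal(tcc$kw_p, 1)
  expect_error(kruskal_dunn(tibble::tibble(group = factor("A"), y = 1), "y"),
               class = "scfamap_design_error")
})

test_that("the adjusted feature model reduces to the two-sample t-test without covariates", {
  set.seed(12)
  n <- 30
  feats <- scfamap:::as_abundance_tibble(
    matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("s%02d", 1:n),
                                               paste0("f", 1:4))))
  data <- data.frame(group = factor(rep(c("HV", "IBS-D"), each = 15)))
  res <- adjusted_feature_model(feats, data, contrast = c("IBS-D", "HV"))
  for (f in paste0("f", 1:4)) {
    tt <- t.test(scfamap:::abundance_matrix(feats)[16:30, f],
                 scfamap:::abundance_matrix(feats)[1:15, f],
                 var.equal = TRUE)
    row <- res[res$feature_id == f, ]
    expect_equal(row$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("covariate adjustment recovers a planted group shift and removes confounding", {
  set.seed(40)
  hits <- 0L
  for (s in 1:20) {
    n <- 60
    g <- rep(c(0, 1), each = n / 2)
    x <- rnorm(n)
    y <- 1.0 * g + 0.8 * x + rnorm(n, 0, 0.5)
    feats <- scfamap:::as_abundance_tibble(
      matrix(y, ncol = 1, dimnames = list(sprintf("s%02d", 1:n), "f1")))
    dat <- data.frame(group = factor(ifelse(g == 1, "IBS-D", "HV")), x = x)
    res <- adjusted_feature_model(feats, dat, covariates = "x",
                                  contrast = c("IBS-D", "HV"))
    hits <- hits + (res$estimate > 0.7 && res$estimate < 1.3)
  }
  expect_gte(hits / 20, 0.9)

  # purely covariate-driven feature: adjusted group p is non-significant
  # far more often than not
  set.seed(41)
  ps <- replicate(40, {
    n <- 50
    x <- c(rnorm(25, 0), rnorm(25, 1.5))   # covariate differs by group
    y <- x + rnorm(n, 0, 0.6)              # feature tracks covariate only
    feats <- scfamap:::as_abundance_tibble(
      matrix(y, ncol = 1, dimnames = list(sprintf("s%02d", 1:n), "f1")))
    dat <- data.frame(group = factor(rep(c("HV", "IBS-D"), each = 25)), x = x)
    adjusted_feature_model(feats, dat, covariates = "x",
                           contrast = c("IBS-D", "HV"))$p_value
  })
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("GMM association restricts to module KOs and reports per-module counts", {
  gmm <- tibble::tibble(
    module_id = c("MF_lactose", "MF_propionate"),
    description = c("lactose degradation", "propionate production"),
    ko_ids = list(c("K01190", "K01220"), c("K01026", "K00932")))
  cfg <- cohort_config(n_per_group = c(HV = 30, `IBS-D` = 30), p_taxa = 30)
  co <- generate_cohort(cfg, seed = 19)
  ko <- generate_ko_table(co, gmm, noise_sd = 0.15, seed = 2)

  # trait mode: KO anchored to an acetate driver carries the driver's sign
  res <- gmm_associate(ko, gmm, co$meta, covariates = c("age", "bmi"),
                       target = "acetate")
  expect_setequal(res$results$module_id, gmm$module_id)
  expect_equal(sort(unique(res$results$feature_id)),
               sort(unlist(gmm$ko_ids)))
  # K01190 is anchored (cyclically) to the first driver, a positive acetate
  # driver, so its acetate slope is positive
  first_driver <- co$truth$drivers[1, ]
  expect_equal(first_driver$scfa, "acetate")
  expect_gt(first_driver$beta, 0)
  first_ko <- res$results[res$results$feature_id == "K01190", ]
  expect_gt(first_ko$estimate, 0)

  # group mode runs the covariate-adjusted contrast per KO
  res2 <- gmm_associate(ko, gmm, co$meta, covariates = "age",
                        target = c("IBS-D", "HV"))
  expect_true(all(c("estimate", "p_value") %in% names(res2$results)))
  expect_equal(sum(res2$module_counts$n_ko), 4)

  bad <- ko
  names(bad)[-1] <- paste0("X", names(bad)[-1])
  expect_error(gmm_associate(bad, gmm, co$meta, target = "acetate"),
               class = "scfamap_coverage_error")
})
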