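test_that("constrained eigenvalues match the dense generalized-eigenproblem oracle", {
  for (s in 1:10) {
    tab <- random_rel_table(10, 6, seed = s)
    des <- random_design(10, 2, seed = s)
    fit <- pcca(tab, des, constraints = c("x1", "x2"))
    orc <- oracle_pcca(tab, des, constraints = c("x1", "x2"))
    expect_equal(unname(fit$eigenvalues), orc$eigenvalues, tolerance = 1e-8)
    expect_equal(fit$total_inertia, orc$total_inertia, tolerance = 1e-10)
    expect_equal(fit$constrained_inertia, orc$constrained_inertia,
                 tolerance = 1e-8)
  }
})

test_that("pCCA agrees with vegan on eigenvalues, inertia and the permutation F", {
  skip_if_not_installed("vegan")
  withr::local_package("vegan")
  co <- generate_cohort(cohort_config(n_per_group = c(HV = 12, `IBS-D` = 12),
                                      p_taxa = 20), seed = 4)
  Y <- scfamap:::abundance_matrix(co$table)
  meta <- as.data.frame(co$meta)
  fit <- pcca(co$table, co$meta, constraints = scfa_constraints,
              conditions = "transit_days")
  vfit <- vegan::cca(Y ~ acetate + butyrate + propionate +
                       Condition(transit_days), data = meta)
  expect_equal(unname(fit$eigenvalues), unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$total_inertia, vfit$tot.chi, tolerance = 1e-8)
  expect_equal(fit$conditional_inertia, vfit$pCCA$tot.chi, tolerance = 1e-8)
  expect_equal(fit$constrained_inertia, vfit$CCA$tot.chi, tolerance = 1e-8)

  # species scores agree with vegan's species scaling up to axis sign
  vs <- vegan::scores(vfit, display = "species", scaling = 2,
                      choices = 1:3)
  for (k in 1:3) {
    expect_equal(abs(unname(fit$species_scores[, k])), abs(unname(vs[, k])),
                 tolerance = 1e-6)
  }
  # pseudo-F matches vegan's anova statistic
  pt <- pcca_permutation_test(co$table, co$meta,
                              constraints = scfa_constraints,
                              conditions = "transit_days",
                              n_perm = 99, seed = 1)
  van <- vegan::anova.cca(vfit, permutations = 99)
  expect_equal(pt$pseudo_F, van$F[1], tolerance = 1e-8)
})

test_that("inertia partition is conserved and conditions remove their own span", {
  for (s in 1:8) {
    tab <- random_rel_table(12, 8, seed = 100 + s)
    des <- random_design(12, 4, seed = 100 + s)
    fit <- pcca(tab, des, constraints = c("x1", "x2", "x3"),
                conditions = "x4")
    expect_equal(fit$conditional_inertia + fit$constrained_inertia +
                   fit$residual_inertia, fit$total_inertia, tolerance = 1e-8)
  }
  # conditioning on the constraint itself leaves nothing to constrain
  tab <- random_rel_table(10, 6, seed = 50)
  des <- random_design(10, 1, seed = 50)
  des$dup <- des$x1
  expect_warning(fit <- pcca(tab, des, constraints = "x1", conditions = "dup"),
                 "absorbed")
  expect_lt(fit$constrained_inertia, 1e-8 * fit$total_inertia)
})

test_that("plain CCA with a spanning constraint set recovers total CA structure", {
  tab <- random_rel_table(6, 10, seed = 77)
  des <- random_design(6, 5, seed = 77)  # full column rank on 6 samples
  fit <- pcca(tab, des, constraints = paste0("x", 1:5))
  expect_equal(sum(fit$eigenvalues), fit$total_inertia, tolerance = 1e-8)
})

test_that("constrained inertia is invariant to invertible constraint reparameterization", {
  tab <- random_rel_table(12, 8, seed = 13)
  des <- random_design(12, 3, seed = 13)
  f1 <- pcca(tab, des, constraints = c("x1", "x2", "x3"), standardize = FALSE)
  mix <- as.data.frame(as.matrix(des) %*%
                         matrix(c(1, 0.5, 0, -1, 2, 0, 0.3, 0, 1), 3, 3))
  names(mix) <- c("m1", "m2", "m3")
  f2 <- pcca(tab, mix, constraints = c("m1", "m2", "m3"), standardize = FALSE)
  expect_equal(f1$constrained_inertia, f2$constrained_inertia, tolerance = 1e-8)
})

test_that("degenerate designs raise design errors naming the culprit", {
  tab <- random_rel_table(10, 6, seed = 8)
  des <- random_design(10, 2, seed = 8)
  des$x2 <- 2 * des$x1
  expect_error(pcca(tab, des, constraints = c("x1", "x2")),
               class = "scfamap_design_error")
  des$k <- 1
  expect_error(pcca(tab, des, constraints = "k"),
               class = "scfamap_design_error")
  expect_error(pcca(tab, des, constraints = "nope"),
               class = "scfamap_key_error")
})

test_that("permutation p-values respect the floor and the permutation count", {
  expect_error(
    pcca_permutation_test(random_rel_table(10, 6, seed = 1),
                          random_design(10, 1, seed = 1),
                          constraints = "x1", n_perm = 0),
    class = "scfamap_config_error")
  # overwhelming signal: no permuted F exceeds the observed, p = 1/(n+1)
  set.seed(99)
  n <- 30
  x <- rnorm(n)
  m <- cbind(t1 = exp(2 * x), t2 = exp(-2 * x), t3 = 1)
  m <- m / rowSums(m)
  rownames(m) <- sprintf("s%d", 1:n)
  tab <- scfamap:::as_abundance_tibble(m)
  pt <- pcca_permutation_test(tab, data.frame(x = x), constraints = "x",
                              n_perm = 999, seed = 3)
  expect_equal(pt$p_value, 1 / 1000)
})

test_that("tidy and glance expose scores and the inertia partition", {
  co <- generate_cohort(cohort_config(n_per_group = c(HV = 8, `IBS-D` = 8),
                                      p_taxa = 15), seed = 2)
  fit <- pcca(co$table, co$meta, constraints = scfa_constraints,
              conditions = "transit_days")
  sp <- generics::tidy(fit, "species")
  expect_equal(nrow(sp), 15)
  expect_true(all(c("feature_id", "CCA1") %in% names(sp)))
  bp <- generics::tidy(fit, "biplot")
  expect_equal(bp$constraint, scfa_constraints)
  g <- generics::glance(fit)
  expect_equal(g$R2, fit$R2)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
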