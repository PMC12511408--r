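#' Kruskal-Wallis test with Dunn's pairwise post hoc and Bonferroni
#'
#' Compares a quantitative trait across clinical groups with the
#' tie-corrected Kruskal-Wallis H test; when more than one pair exists,
#' pairwise Dunn z statistics on mean ranks are reported with Bonferroni
#' correction over the number of pairs actually tested.
#'
#' @param data Data frame with the trait and a grouping column; rows with a
#'   missing trait value are excluded for this endpoint.
#' @param trait Name of the numeric trait column.
#' @param group Name of the grouping column (default `"group"`).
#' @return A list of class `trait_comparison`: `trait`, `kw_H`, `kw_df`,
#'   `kw_p`, `pairwise` tibble (`group_a`, `group_b`, `dunn_z`, `p_raw`,
#'   `p_bonferroni`), `n_used`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 4)
#' kruskal_dunn(cohort$meta, "total_scfa")
kruskal_dunn <- function(data, trait, group = "group") {
  x <- data[[trait]]
  g <- droplevels(as.factor(data[[group]]))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  counts <- table(g)
  if (nlevels(g) < 2 || any(counts < 2)) {
    abort("need >= 2 groups with >= 2 non-missing values each",
          class = "scfamap_design_error")
  }
  n <- length(x)
  if (length(unique(x)) == 1L) {
    # fully tied trait: degenerate, flagged with H = 0, p = 1
    warn(sprintf("trait '%s' is constant; degenerate comparison", trait))
    kw_H <- 0; kw_p <- 1; kw_df <- nlevels(g) - 1L
  } else {
    kw <- kruskal.test(x, g)
    kw_H <- unname(kw$statistic); kw_p <- kw$p.value
    kw_df <- unname(kw$parameter)
  }
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, g, mean)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map(seq_len(n_pairs), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / counts[[a]] + 1 / counts[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p_raw <- 2 * pnorm(-abs(z))
    tibble(group_a = a, group_b = b, dunn_z = z, p_raw = p_raw,
           p_bonferroni = pmin(1, p_raw * n_pairs))
  }) |> bind_rows()
  structure(list(trait = trait, kw_H = kw_H, kw_df = kw_df, kw_p = kw_p,
                 pairwise = pw, n_used = n),
            class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: %s  H = %.3f (df = %d), p = %.4g, n = %d\n",
              x$trait, x$kw_H, x$kw_df, x$kw_p, x$n_used))
  print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.trait_comparison <- function(x, ...) {
  mutate(x$pairwise, trait = x$trait, .before = 1)
}

#' @export
glance.trait_comparison <- function(x, ...) {
  tibble(trait = x$trait, kw_H = x$kw_H, kw_df = x$kw_df, kw_p = x$kw_p,
         n_used = x$n_used)
}

#' Covariate-adjusted per-feature linear models
#'
#' For each feature (column of an ALR table or any per-sample feature
#' matrix), fits ordinary least squares of the feature on group indicators
#' plus covariates and reports the requested group contrast with its
#' standard error and two-sided t-test p-value. No multiplicity adjustment
#' is applied by default; set `p_adjust` for Bonferroni or
#' Benjamini-Hochberg.
#'
#' @param features Tibble `sample_id` + numeric feature columns (typically
#'   ALR-transformed, post abundance filter).
#' @param data Aligned data frame with `group` and covariate columns.
#' @param covariates Character vector of covariate columns (e.g.
#'   `c("age", "sex", "bmi")`); may be empty.
#' @param contrast Length-2 character vector `c(level_a, level_b)`: the
#'   estimate is the adjusted mean difference a - b. Default: first two
#'   group levels.
#' @param p_adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return A tibble `feature_id`, `term`, `estimate`, `se`, `statistic`,
#'   `p_value` (and `p_adjusted` unless `p_adjust = "none"`).
#' @export
adjusted_feature_model <- function(features, data, covariates = character(),
                                   contrast = NULL, p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  m <- abundance_matrix(features)
  stopifnot(nrow(data) == nrow(m))
  g <- droplevels(as.factor(data$group))
  lev <- levels(g)
  contrast <- contrast %||% lev[c(2, 1)]
  if (!all(contrast %in% lev)) {
    abort(sprintf("contrast levels must be among: %s", paste(lev, collapse = ", ")),
          class = "scfamap_design_error")
  }
  keep <- complete.cases(data[c("group", covariates)])
  m <- m[keep, , drop = FALSE]
  data <- data[keep, , drop = FALSE]
  g <- droplevels(as.factor(data$group))
  # design with group coded relative to contrast[2] so the contrast[1]
  # indicator coefficient is the adjusted a - b difference
  g2 <- stats::relevel(g, ref = contrast[2])
  df <- data.frame(g2 = g2)
  for (cv in covariates) df[[cv]] <- data[[cv]]
  mm <- stats::model.matrix(~., df)
  if (qr(mm)$rank < ncol(mm)) {
    abort("design matrix is rank-deficient (collinear covariates?)",
          class = "scfamap_design_error")
  }
  target <- paste0("g2", contrast[1])
  j <- match(target, colnames(mm))
  fit <- stats::lm.fit(mm, m)
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1, dimnames = list(names(cf), colnames(m)))
  res <- as.matrix(fit$residuals)
  df_res <- nrow(mm) - ncol(mm)
  rss <- colSums(res^2)
  sigma2 <- rss / df_res
  XtXinv_jj <- chol2inv(qr.R(qr(mm)))[j, j]
  est <- cf[j, ]
  se <- sqrt(sigma2 * XtXinv_jj)
  tstat <- ifelse(se > 0, est / se, 0)
  pval <- ifelse(se > 0, 2 * pt(-abs(tstat), df_res), 1)
  if (any(se == 0)) {
    warn("feature(s) with zero residual variance; p set to 1 (degenerate)")
  }
  out <- tibble(feature_id = colnames(m),
                term = paste(contrast[1], "vs", contrast[2]),
                estimate = unname(est), se = unname(se),
                statistic = unname(tstat), p_value = unname(pval))
  if (p_adjust != "none") {
    out$p_adjusted <- p.adjust(out$p_value, method = p_adjust)
  }
  arrange(out, .data$p_value)
}

#' Gut-metabolic-module KO association models
#'
#' Restricts a KO abundance table to the KOs of the supplied gut metabolic
#' modules, then per KO fits the covariate-adjusted linear model against
#' either a clinical-group contrast (`target` = length-2 group pair) or a
#' quantitative SCFA trait (`target` = a column name of `data`). Results
#' are grouped and counted per module.
#'
#' @param ko_table Abundance tibble of KO columns.
#' @param gmm GMM definition tibble ([read_gmm_definitions()] layout).
#' @param data Aligned metadata.
#' @param covariates Covariate columns for adjustment.
#' @param target Either `c(group_a, group_b)` (group mode) or a single
#'   trait column name (trait mode).
#' @param alpha Significance level used for the per-module significant-KO
#'   counts (default 0.05).
#' @return A list of class `gmm_association`: `results` tibble with
#'   `module_id` attached, and `module_counts` (`module_id`, `n_ko`,
#'   `n_significant`).
#' @export
gmm_associate <- function(ko_table, gmm, data, covariates = character(),
                          target, alpha = 0.05) {
  kos_all <- unique(unlist(gmm$ko_ids))
  present <- intersect(kos_all, feature_ids(ko_table))
  if (length(present) == 0) {
    abort(sprintf("no module KOs present in the table; missing: %s",
                  paste(head(kos_all, 10), collapse = ", ")),
          class = "scfamap_coverage_error")
  }
  tab <- ko_table[c("sample_id", present)]
  group_mode <- length(target) == 2 && all(target %in% as.character(data$group))
  if (group_mode) {
    res <- adjusted_feature_model(tab, data, covariates, contrast = target)
  } else {
    if (!(length(target) == 1 && target %in% names(data))) {
      abort("target must be a group pair or a metadata column name",
            class = "scfamap_config_error")
    }
    res <- trait_feature_model(tab, data, covariates, trait = target)
  }
  membership <- gmm |>
    select("module_id") |>
    mutate(feature_id = gmm$ko_ids) |>
    tidyr::unnest("feature_id")
  res <- left_join(membership, res, by = "feature_id") |>
    filter(!is.na(.data$estimate))
  counts <- res |>
    group_by(.data$module_id) |>
    summarise(n_ko = n(), n_significant = sum(.data$p_value < alpha),
              .groups = "drop")
  structure(list(results = res, module_counts = counts, target = target),
            class = "gmm_association")
}

# OLS of each feature on a quantitative trait + covariates; reports the
# trait slope.
trait_feature_model <- function(features, data, covariates, trait) {
  m <- abundance_matrix(features)
  keep <- complete.cases(data[c(trait, covariates)])
  m <- m[keep, , drop = FALSE]
  data <- data[keep, , drop = FALSE]
  df <- data.frame(.trait = data[[trait]])
  for (cv in covariates) df[[cv]] <- data[[cv]]
  mm <- stats::model.matrix(~., df)
  j <- match(".trait", colnames(mm))
  fit <- stats::lm.fit(mm, m)
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1, dimnames = list(names(cf), colnames(m)))
  df_res <- nrow(mm) - ncol(mm)
  sigma2 <- colSums(as.matrix(fit$residuals)^2) / df_res
  XtXinv_jj <- chol2inv(qr.R(qr(mm)))[j, j]
  est <- cf[j, ]
  se <- sqrt(sigma2 * XtXinv_jj)
  tstat <- ifelse(se > 0, est / se, 0)
  tibble(feature_id = colnames(m), term = trait, estimate = unname(est),
         se = unname(se), statistic = unname(tstat),
         p_value = unname(ifelse(se > 0, 2 * pt(-abs(tstat), df_res), 1))) |>
    arrange(.data$p_value)
}

#' @export
print.gmm_association <- function(x, ...) {
  cat(sprintf("GMM association (target: %s)\n", paste(x$target, collapse = " vs ")))
  print(as.data.frame(x$module_counts), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.gmm_association <- function(x, ...) x$results

#' @export
glance.gmm_association <- function(x, ...) x$module_counts
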