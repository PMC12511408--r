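#' Partial canonical correspondence analysis (pCCA)
#'
#' Constrained ordination of a chi-square-standardized abundance matrix on a
#' set of explanatory variables (the SCFA concentrations), optionally after
#' removing the variance explained by conditioning variables (colonic
#' transit time). Implemented from first principles via the weighted
#' chi-square residual matrix and its projection/SVD decomposition.
#'
#' The inertia partition is `total = conditional + constrained + residual`.
#' `R2` is `constrained / (total - conditional)`, the share of
#' transit-adjusted inertia explained by the constraints.
#'
#' @param table Relative- (or raw-) abundance tibble, samples as rows.
#' @param data Data frame of per-sample variables aligned to `table`
#'   (same row order).
#' @param constraints Character vector naming constraint columns of `data`
#'   (e.g. `c("acetate", "butyrate", "propionate", "acetate_butyrate_ratio")`).
#' @param conditions Character vector naming conditioning columns (default
#'   none; use `"transit_days"` for transit-conditioned pCCA).
#' @param standardize Standardize constraint columns to weighted mean 0,
#'   variance 1 before fitting (default `TRUE`), making biplot arrow lengths
#'   comparable across SCFAs with different units.
#' @param scaling `"species_focused"` (default; species scores and biplot
#'   arrows multiplied by the axis singular value, emphasising
#'   species-constraint geometry) or `"unit"` (orthonormal axis scores).
#' @return An object of class `pcca`: eigenvalues, the inertia partition,
#'   `species_scores`, `site_scores`, `biplot_scores`, `R2`, and fit
#'   internals used by [pcca_permutation_test()].
#' @seealso [pcca_permutation_test()], [project_taxa()]
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = c(HV = 10, `IBS-D` = 10),
#'                                         p_taxa = 30), seed = 1)
#' fit <- pcca(cohort$table, cohort$meta,
#'             constraints = c("acetate", "butyrate", "propionate"),
#'             conditions = "transit_days")
#' glance(fit)
pcca <- function(table, data, constraints, conditions = NULL,
                 standardize = TRUE,
                 scaling = c("species_focused", "unit")) {
  scaling <- match.arg(scaling)
  Y <- abundance_matrix(table)
  if (any(Y < 0)) {
    abort("abundances must be nonnegative", class = "scfamap_domain_error")
  }
  if (nrow(Y) < 3) {
    abort("pCCA needs at least 3 samples", class = "scfamap_design_error")
  }
  zero_col <- colSums(Y) <= 0
  if (any(zero_col)) {
    warn(sprintf("dropping %d all-zero feature(s) before ordination",
                 sum(zero_col)))
    Y <- Y[, !zero_col, drop = FALSE]
  }
  if (any(rowSums(Y) <= 0)) {
    abort("all-zero sample row; cannot form chi-square residuals",
          class = "scfamap_domain_error")
  }
  stopifnot(nrow(data) == nrow(Y))
  miss <- setdiff(c(constraints, conditions), names(data))
  if (length(miss) > 0) {
    abort(sprintf("variable(s) not in data: %s", paste(miss, collapse = ", ")),
          class = "scfamap_key_error")
  }

  P <- Y / sum(Y)
  r <- rowSums(P)
  cw <- colSums(P)
  sqr <- sqrt(r)
  Qbar <- (P - outer(r, cw)) / outer(sqr, sqrt(cw))
  total_inertia <- sum(Qbar^2)

  wcenter <- function(M) sweep(M, 2, colSums(M * r), "-")
  wscale <- function(M) {
    v <- colSums(M^2 * r)
    if (any(v <= 1e-12)) {
      abort(sprintf("constant/degenerate variable(s): %s",
                    paste(colnames(M)[v <= 1e-12], collapse = ", ")),
            class = "scfamap_design_error")
    }
    sweep(M, 2, sqrt(v), "/")
  }

  qrZ <- NULL
  conditional_inertia <- 0
  Qres <- Qbar
  z <- 0L
  if (!is.null(conditions) && length(conditions) > 0) {
    Z <- as.matrix(data[conditions])
    storage.mode(Z) <- "double"
    Zc <- wcenter(Z)
    Zw <- Zc * sqr
    qrZ <- qr(Zw)
    z <- qrZ$rank
    fitZ <- qr.fitted(qrZ, Qbar)
    conditional_inertia <- sum(fitZ^2)
    Qres <- Qbar - fitZ
  }

  X <- as.matrix(data[constraints])
  storage.mode(X) <- "double"
  Xc <- wcenter(X)
  if (standardize) Xc <- wscale(Xc)
  Xw <- Xc * sqr
  if (!is.null(qrZ)) {
    base_norm <- sqrt(colSums(Xw^2))
    Xw <- Xw - qr.fitted(qrZ, Xw)
    # constraints lying entirely in the conditions' span carry no
    # conditional-adjusted information; drop them rather than fitting noise
    absorbed <- sqrt(colSums(Xw^2)) <= 1e-8 * pmax(base_norm, 1e-300)
    if (any(absorbed)) {
      warn(sprintf("constraint(s) absorbed by the conditions: %s",
                   paste(colnames(Xw)[absorbed], collapse = ", ")))
      Xw <- Xw[, !absorbed, drop = FALSE]
      Xc <- Xc[, !absorbed, drop = FALSE]
    }
    if (ncol(Xw) == 0) {
      axnm <- character(0)
      return(structure(list(
        eigenvalues = setNames(numeric(0), axnm),
        total_inertia = total_inertia,
        conditional_inertia = conditional_inertia,
        constrained_inertia = 0,
        residual_inertia = total_inertia - conditional_inertia,
        R2 = 0,
        species_scores = matrix(0, ncol(Y), 0, dimnames = list(colnames(Y), NULL)),
        site_scores = matrix(0, nrow(Y), 0, dimnames = list(rownames(Y), NULL)),
        biplot_scores = matrix(0, 0, 0),
        scaling = scaling, constraints = character(0),
        conditions = conditions, n_samples = nrow(Y),
        rank = list(q = 0L, z = z),
        .internal = list(Qres = Qres, qrX = NULL, qrZ = qrZ, r = r)
      ), class = "pcca"))
    }
  }
  qrX <- qr(Xw)
  q <- qrX$rank
  if (q < ncol(Xw)) {
    piv <- qrX$pivot[(q + 1):ncol(Xw)]
    abort(sprintf("constraints are rank-deficient after conditioning; collinear: %s",
                  paste(colnames(Xw)[piv], collapse = ", ")),
          class = "scfamap_design_error")
  }
  fitted <- qr.fitted(qrX, Qres)
  sv <- svd(fitted)
  pos <- sv$d > max(sv$d[1], 0) * 1e-9
  n_axes <- min(sum(pos), q)
  d <- sv$d[seq_len(n_axes)]
  u <- sv$u[, seq_len(n_axes), drop = FALSE]
  v <- sv$v[, seq_len(n_axes), drop = FALSE]
  eig <- d^2
  constrained_inertia <- sum(fitted^2)
  residual_inertia <- total_inertia - conditional_inertia - constrained_inertia

  site_unit <- u / sqr                       # weighted-orthonormal site (LC) scores
  # r-weighted correlation of each constraint column with each site axis
  bip <- sapply(seq_len(n_axes), function(k) {
    s <- site_unit[, k]
    sc <- s - sum(r * s)
    sv_ <- sqrt(sum(r * sc^2))
    apply(Xc, 2, function(x) sum(r * x * sc) / (sqrt(sum(r * x^2)) * sv_))
  })
  bip <- matrix(bip, nrow = ncol(Xc), ncol = n_axes,
                dimnames = list(colnames(Xc), NULL))

  # orient each axis so the constraint with the largest |arrow| points positive
  for (k in seq_len(n_axes)) {
    jmax <- which.max(abs(bip[, k]))
    if (bip[jmax, k] < 0) {
      bip[, k] <- -bip[, k]; u[, k] <- -u[, k]; v[, k] <- -v[, k]
      site_unit[, k] <- -site_unit[, k]
    }
  }

  # species_focused reproduces the common community-ecology "species"
  # scaling: species scores stretched by the axis singular value, biplot
  # arrows as plain weighted correlations
  species_unit <- v / sqrt(cw)
  species_scores <- if (scaling == "species_focused") {
    sweep(species_unit, 2, d, "*")
  } else species_unit
  biplot_scores <- bip
  site_scores <- site_unit
  axnm <- paste0("CCA", seq_len(n_axes))
  dimnames(species_scores) <- list(colnames(Y), axnm)
  dimnames(site_scores) <- list(rownames(Y), axnm)
  dimnames(biplot_scores) <- list(colnames(Xc), axnm)
  names(eig) <- axnm

  structure(list(
    eigenvalues = eig,
    total_inertia = total_inertia,
    conditional_inertia = conditional_inertia,
    constrained_inertia = constrained_inertia,
    residual_inertia = residual_inertia,
    R2 = constrained_inertia / (total_inertia - conditional_inertia),
    species_scores = species_scores,
    site_scores = site_scores,
    biplot_scores = biplot_scores,
    scaling = scaling,
    constraints = colnames(Xc),
    conditions = conditions,
    n_samples = nrow(Y),
    rank = list(q = q, z = z),
    .internal = list(Qres = Qres, qrX = qrX, qrZ = qrZ, r = r)
  ), class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat("Partial canonical correspondence analysis\n")
  cat(sprintf("  samples: %d  constraints: %s\n", x$n_samples,
              paste(x$constraints, collapse = ", ")))
  if (!is.null(x$conditions)) {
    cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  }
  cat(sprintf("  inertia total %.4f = conditional %.4f + constrained %.4f + residual %.4f\n",
              x$total_inertia, x$conditional_inertia, x$constrained_inertia,
              x$residual_inertia))
  cat(sprintf("  R2 (of condition-adjusted inertia): %.4f\n", x$R2))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Permutation significance test for (partial) CCA
#'
#' Pseudo-F is `(constrained/q) / (residual/(n - q - z - 1))` with `q`
#' constraint axes and `z` condition columns. Significance uses
#' reduced-model residual permutation: the chi-square residuals left after
#' removing the conditions are row-permuted and the constrained fit is
#' recomputed, so the conditioning variable stays attached to its sample.
#'
#' @inheritParams pcca
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `pcca_test`: `pseudo_F`, `p_value`, `n_perm`,
#'   `seed`, plus the fitted `pcca` object as `$fit`.
#' @export
pcca_permutation_test <- function(table, data, constraints, conditions = NULL,
                                  n_perm = 999, seed = 1,
                                  standardize = TRUE) {
  if (n_perm < 1) {
    abort("n_perm must be at least 1", class = "scfamap_config_error")
  }
  fit <- pcca(table, data, constraints, conditions, standardize = standardize)
  n <- fit$n_samples
  q <- fit$rank$q
  z <- fit$rank$z
  df_res <- n - q - z - 1
  if (df_res < 1) {
    abort("not enough residual degrees of freedom for the pseudo-F test",
          class = "scfamap_design_error")
  }
  Qres <- fit$.internal$Qres
  qrX <- fit$.internal$qrX
  qrZ <- fit$.internal$qrZ
  f_stat <- function(E) {
    con <- sum(qr.fitted(qrX, E)^2)
    res <- sum(E^2) - con
    (con / q) / (res / df_res)
  }
  F_obs <- f_stat(Qres)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  F_perm <- vapply(seq_len(n_perm), function(i) {
    E <- Qres[sample.int(n), , drop = FALSE]
    if (!is.null(qrZ)) E <- E - qr.fitted(qrZ, E)
    f_stat(E)
  }, numeric(1))
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  structure(list(pseudo_F = F_obs, p_value = p, n_perm = n_perm, seed = seed,
                 fit = fit, F_perm = F_perm),
            class = "pcca_test")
}

#' @export
print.pcca_test <- function(x, ...) {
  cat(sprintf("pCCA permutation test: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_perm))
  invisible(x)
}

#' Tidy a pCCA fit
#'
#' @param x A `pcca` object.
#' @param what One of `"species"`, `"sites"`, `"biplot"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble of the requested scores, one row per feature/sample/
#'   constraint/axis.
#' @export
tidy.pcca <- function(x, what = c("species", "sites", "biplot", "eigenvalues"),
                      ...) {
  what <- match.arg(what)
  if (what == "eigenvalues") {
    return(tibble(axis = names(x$eigenvalues),
                  eigenvalue = unname(x$eigenvalues),
                  proportion = unname(x$eigenvalues) / x$constrained_inertia))
  }
  m <- switch(what, species = x$species_scores, sites = x$site_scores,
              biplot = x$biplot_scores)
  id_col <- switch(what, species = "feature_id", sites = "sample_id",
                   biplot = "constraint")
  as_tibble(m, rownames = id_col)
}

#' @export
glance.pcca <- function(x, ...) {
  tibble(total_inertia = x$total_inertia,
         conditional_inertia = x$conditional_inertia,
         constrained_inertia = x$constrained_inertia,
         residual_inertia = x$residual_inertia,
         R2 = x$R2,
         n_axes = length(x$eigenvalues),
         n_samples = x$n_samples)
}

#' @export
glance.pcca_test <- function(x, ...) {
  dplyr::bind_cols(tibble(pseudo_F = x$pseudo_F, p_value = x$p_value,
                          n_perm = x$n_perm), glance(x$fit))
}

#' Biplot of a pCCA fit
#'
#' Species points in the plane of the first two constrained axes with
#' constraint arrows overlaid.
#'
#' @param object A `pcca` object.
#' @param axes Pair of axis indices, default `c(1, 2)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcca <- function(object, axes = c(1, 2), ...) {
  if (length(object$eigenvalues) < 2) {
    abort("biplot needs at least two constrained axes",
          class = "scfamap_design_error")
  }
  sp <- tidy(object, "species")
  bp <- tidy(object, "biplot")
  ax <- paste0("CCA", axes)
  arrow_scale <- 0.9 * max(abs(sp[[ax[1]]]), abs(sp[[ax[2]]])) /
    max(sqrt(bp[[ax[1]]]^2 + bp[[ax[2]]]^2), 1e-9)
  ggplot2::ggplot(sp, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_segment(
      data = bp,
      ggplot2::aes(x = 0, y = 0, xend = .data[[ax[1]]] * arrow_scale,
                   yend = .data[[ax[2]]] * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
    ggplot2::geom_text(
      data = bp,
      ggplot2::aes(x = .data[[ax[1]]] * arrow_scale * 1.08,
                   y = .data[[ax[2]]] * arrow_scale * 1.08,
                   label = .data$constraint),
      colour = "firebrick", size = 3) +
    ggplot2::labs(x = ax[1], y = ax[2], title = "pCCA biplot") +
    ggplot2::theme_minimal()
}
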