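#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)`, the standard
#' abundance-based ecological distance in `[0, 1]`.
#'
#' @param table Abundance tibble (counts or relative), no all-zero rows.
#' @return A symmetric matrix with sample ids as dimnames and attribute
#'   `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  m <- abundance_matrix(table)
  if (any(m < 0)) {
    abort("Bray-Curtis requires nonnegative abundances",
          class = "scfamap_domain_error")
  }
  if (any(rowSums(m) <= 0)) {
    abort(sprintf("all-zero sample '%s' has undefined Bray-Curtis distances",
                  rownames(m)[which(rowSums(m) <= 0)[1]]),
          class = "scfamap_domain_error")
  }
  n <- nrow(m)
  rs <- rowSums(m)
  # sum of pairwise minima via crossprod trick: |a-b| = a + b - 2*min(a,b)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    mins <- colSums(pmin(t(m[(i + 1):n, , drop = FALSE]), m[i, ]))
    d <- 1 - 2 * mins / (rs[i] + rs[(i + 1):n])
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  attr(D, "metric") <- "bray_curtis"
  D
}

#' Euclidean distance on ALR-transformed abundances
#'
#' @param alr ALR tibble from [alr_transform()].
#' @return A symmetric distance matrix with attribute
#'   `metric = "euclidean_alr"`.
#' @export
euclidean_alr <- function(alr) {
  m <- abundance_matrix(alr)
  D <- as.matrix(dist(m))
  attr(D, "metric") <- "euclidean_alr"
  D
}

#' Distance-based PERMANOVA with optional covariate adjustment
#'
#' Partitions the Gower-centered inner-product form of a distance matrix by
#' a sequential (Type I) design — covariates first, the clinical group last —
#' and tests the group term by permutation of its pseudo-F. Without
#' covariates rows are permuted freely; with covariates the residuals of
#' the covariate model are permuted (Freedman-Lane).
#'
#' @param dist_matrix Symmetric distance matrix (samples x samples).
#' @param data Data frame aligned to the distance matrix rows.
#' @param group Name of the grouping column in `data`.
#' @param covariates Optional character vector of covariate columns entered
#'   before the group term.
#' @param n_perm Number of permutations, default 999.
#' @param seed Integer seed.
#' @return A list of class `permanova_fit` with the term table (`df`, `SS`,
#'   `R2`, `pseudo_F`, `p_value`) and the permutation settings.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = c(HV = 8, `IBS-D` = 8),
#'                                         p_taxa = 25), seed = 2)
#' fit <- permanova(bray_curtis(cohort$table), cohort$meta, group = "group",
#'                  n_perm = 99, seed = 1)
#' tidy(fit)
permanova <- function(dist_matrix, data, group, covariates = NULL,
                      n_perm = 999, seed = 1) {
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  stopifnot(nrow(data) == n)
  if (max(abs(D - t(D))) > 1e-12) {
    abort("distance matrix is not symmetric", class = "scfamap_domain_error")
  }
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) < 2) {
    abort("grouping factor must have at least 2 levels (no between-group df)",
          class = "scfamap_design_error")
  }

  # Gower-centered inner-product matrix G = -1/2 J D^2 J
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  SS_total <- sum(diag(G))

  Xg <- stats::model.matrix(~g)[, -1, drop = FALSE]
  has_cov <- !is.null(covariates) && length(covariates) > 0
  if (has_cov) {
    Z <- as.matrix(data[covariates])
    storage.mode(Z) <- "double"
    Z <- scale(Z, center = TRUE, scale = FALSE)
    qrZ <- qr(cbind(1, Z))
    if (qrZ$rank < ncol(Z) + 1) {
      abort("covariate design is singular", class = "scfamap_design_error")
    }
    HZ <- tcrossprod(qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE])
    qrFull <- qr(cbind(1, Z, Xg))
  } else {
    HZ <- matrix(1 / n, n, n)
    qrFull <- qr(cbind(1, Xg))
  }
  Hfull <- tcrossprod(qr.Q(qrFull)[, seq_len(qrFull$rank), drop = FALSE])
  df_cov <- if (has_cov) qr(cbind(1, Z))$rank - 1L else 0L
  df_group <- qrFull$rank - 1L - df_cov
  if (df_group < 1) {
    abort("group term has no degrees of freedom after covariates",
          class = "scfamap_design_error")
  }
  df_res <- n - 1L - df_cov - df_group

  SS_cov <- sum((HZ - matrix(1 / n, n, n)) * G)   # tr(H G) via elementwise
  SS_group <- sum((Hfull - HZ) * G)
  SS_res <- SS_total - SS_cov - SS_group
  F_obs <- (SS_group / df_group) / (SS_res / df_res)

  Hg <- Hfull - HZ
  Hr <- diag(n) - Hfull
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  if (has_cov) {
    # Freedman-Lane: permute the covariate-model residual structure
    R <- (diag(n) - HZ) %*% G %*% (diag(n) - HZ)
    F_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      Rp <- R[p, p]
      (sum(Hg * Rp) / df_group) / (sum(Hr * Rp) / df_res)
    }, numeric(1))
  } else {
    F_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      Gp <- G[p, p]
      (sum(Hg * Gp) / df_group) / (sum(Hr * Gp) / df_res)
    }, numeric(1))
  }
  p_value <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)

  terms <- tibble(
    term = c(if (has_cov) "covariates", "group", "residual", "total"),
    df = c(if (has_cov) df_cov, df_group, df_res, n - 1L),
    SS = c(if (has_cov) SS_cov, SS_group, SS_res, SS_total),
    R2 = c(if (has_cov) SS_cov, SS_group, SS_res, SS_total) / SS_total,
    pseudo_F = c(if (has_cov) NA_real_, F_obs, NA_real_, NA_real_),
    p_value = c(if (has_cov) NA_real_, p_value, NA_real_, NA_real_)
  )
  structure(list(terms = terms, pseudo_F = F_obs, R2 = SS_group / SS_total,
                 p_value = p_value, n_perm = n_perm, seed = seed,
                 metric = attr(dist_matrix, "metric") %||% "unknown"),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations)\n", x$metric, x$n_perm))
  print(as.data.frame(x$terms), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.permanova_fit <- function(x, ...) x$terms

#' @export
glance.permanova_fit <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
         n_perm = x$n_perm, metric = x$metric)
}
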