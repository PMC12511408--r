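# Shared fixtures: tiny deterministic tables and an independent dense-algebra
# CCA oracle used to cross-check the SVD-based implementation.

scfa_constraints <- c("acetate", "butyrate", "propionate")
all_constraints <- c(scfa_constraints, "acetate_butyrate_ratio")

# small counts table: 3 samples x 2 taxa, rows sum to 10
toy_counts_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("sample_id\ttaxon_a\ttaxon_b",
               "s1\t6\t4", "s2\t2\t8", "s3\t5\t5"), path)
  path
}

# random relative-abundance tibble
random_rel_table <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(n * p, shape = 0.7), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("t%02d", seq_len(p))))
  m <- m / rowSums(m)
  scfamap:::as_abundance_tibble(m)
}

random_design <- function(n, k, seed, prefix = "x") {
  set.seed(seed + 1000)
  d <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(d) <- paste0(prefix, seq_len(k))
  d
}

# Independent CCA/pCCA oracle: dense hat matrices and a generalized
# eigendecomposition, no QR/SVD shared with the implementation.
oracle_pcca <- function(table, data, constraints, conditions = NULL,
                        standardize = TRUE) {
  Y <- scfamap:::abundance_matrix(table)
  P <- Y / sum(Y)
  r <- rowSums(P); cw <- colSums(P)
  Qbar <- (P - outer(r, cw)) / sqrt(outer(r, cw))
  total <- sum(Qbar^2)
  wc <- function(M) sweep(M, 2, colSums(M * r), "-")
  Xc <- wc(as.matrix(data[constraints]))
  if (standardize) Xc <- sweep(Xc, 2, sqrt(colSums(Xc^2 * r)), "/")
  Xw <- Xc * sqrt(r)
  conditional <- 0
  Q1 <- Qbar
  if (!is.null(conditions)) {
    Zw <- wc(as.matrix(data[conditions])) * sqrt(r)
    Hz <- Zw %*% solve(crossprod(Zw)) %*% t(Zw)
    conditional <- sum((Hz %*% Qbar)^2)
    Q1 <- Qbar - Hz %*% Qbar
    Xw <- Xw - Hz %*% Xw
  }
  A <- t(Xw) %*% Q1 %*% t(Q1) %*% Xw
  B <- crossprod(Xw)
  ev <- eigen(solve(B) %*% A, only.values = TRUE)$values
  ev <- sort(Re(ev[Re(ev) > 1e-12]), decreasing = TRUE)
  H <- Xw %*% solve(B) %*% t(Xw)
  constrained <- sum((H %*% Q1)^2)
  list(eigenvalues = ev, total_inertia = total,
       conditional_inertia = conditional, constrained_inertia = constrained,
       residual_inertia = total - conditional - constrained)
}

# Minimal hand-built ordination object for projection-geometry tests.
fake_ordination <- function(species, arrows) {
  structure(list(
    eigenvalues = c(CCA1 = 1, CCA2 = 0.5),
    species_scores = species,
    biplot_scores = arrows,
    scaling = "species_focused"
  ), class = "pcca")
}
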