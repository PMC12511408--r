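#' Choose a default ALR reference feature
#'
#' The reference is the feature with the highest minimum relative abundance
#' across samples — the taxon most consistently present — which keeps the
#' log-ratio denominator away from zero.
#'
#' @param table Relative-abundance tibble.
#' @return The reference feature identifier (length-1 character).
#' @export
default_alr_reference <- function(table) {
  m <- abundance_matrix(table)
  mins <- apply(m, 2, min)
  colnames(m)[which.max(mins)]
}

#' Default pseudocount for zero replacement
#'
#' Half the smallest nonzero relative abundance in the table; 0 when the
#' table has no zeros.
#'
#' @param table Relative-abundance tibble.
#' @return A nonnegative scalar.
#' @export
default_pseudocount <- function(table) {
  m <- abundance_matrix(table)
  if (!any(m == 0)) return(0)
  min(m[m > 0]) / 2
}

#' Additive log-ratio (ALR) transform
#'
#' Maps each composition row to `log((x_j + pc) / (x_ref + pc))` for every
#' feature `j` other than the reference, taking the simplex to unconstrained
#' real space. The reference column is dropped from the output.
#'
#' @param table Relative-abundance tibble (rows sum to 1).
#' @param reference Reference feature identifier; defaults to
#'   [default_alr_reference()].
#' @param pseudocount Nonnegative pseudocount; must be positive when the
#'   table contains zeros. Defaults to [default_pseudocount()].
#' @return A tibble `sample_id` + log-ratio columns, with attributes
#'   `reference` and `pseudocount`.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = "s1", a = 0.2, b = 0.3, c = 0.5)
#' alr_transform(tbl, reference = "c")
alr_transform <- function(table, reference = NULL, pseudocount = NULL) {
  validate_abundance(table, "relative")
  m <- abundance_matrix(table)
  reference <- reference %||% default_alr_reference(table)
  if (!reference %in% colnames(m)) {
    abort(sprintf("reference feature '%s' not present in table", reference),
          class = "scfamap_key_error")
  }
  pseudocount <- pseudocount %||% default_pseudocount(table)
  if (pseudocount < 0) {
    abort("pseudocount must be nonnegative", class = "scfamap_config_error")
  }
  if (pseudocount == 0 && any(m == 0)) {
    abort("table contains zeros; a positive pseudocount is required",
          class = "scfamap_domain_error")
  }
  num <- m[, setdiff(colnames(m), reference), drop = FALSE] + pseudocount
  den <- m[, reference] + pseudocount
  lr <- log(sweep(num, 1, den, "/"))
  out <- as_abundance_tibble(lr)
  attr(out, "reference") <- reference
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Invert an ALR transform back to the simplex
#'
#' Appends a zero log-ratio for the reference and applies the softmax,
#' recovering the (pseudocounted, re-closed) composition.
#'
#' @param alr ALR tibble as returned by [alr_transform()].
#' @param reference Reference feature id; taken from the `reference`
#'   attribute when omitted.
#' @return A relative-abundance tibble including the reference column.
#' @export
alr_inverse <- function(alr, reference = NULL) {
  reference <- reference %||% attr(alr, "reference")
  if (is.null(reference)) {
    abort("reference feature unknown; supply `reference`",
          class = "scfamap_key_error")
  }
  m <- abundance_matrix(alr)
  full <- cbind(m, 0)
  colnames(full) <- c(colnames(m), reference)
  e <- exp(full - apply(full, 1, max))
  as_abundance_tibble(sweep(e, 1, rowSums(e), "/"))
}

#' Filter to high-abundant, prevalent features
#'
#' Keeps a feature iff some clinical group contains at least
#' `min_prevalent_samples` samples in which its relative abundance is at
#' least `abundance_min` (default: 0.1% in >= 2 specimens within >= 1
#' group). Features failing the abundance bar everywhere are coded
#' `low_abundance`; features abundant somewhere but never in enough samples
#' of one group are coded `low_prevalence`.
#'
#' @param table Relative-abundance tibble.
#' @param meta Metadata tibble aligned to `table` with a `group` column.
#' @param abundance_min Minimum relative abundance (fraction), default 0.001.
#' @param min_prevalent_samples Minimum number of qualifying samples within a
#'   single group, default 2.
#' @return A list with `table` (filtered tibble) and `report` (tibble of
#'   `feature_id`, `kept`, `reason`).
#' @export
filter_high_abundant <- function(table, meta, abundance_min = 0.001,
                                 min_prevalent_samples = 2) {
  validate_abundance(table, "relative")
  if (!"group" %in% names(meta) || all(is.na(meta$group))) {
    abort("metadata must define a 'group' column", class = "scfamap_config_error")
  }
  if (!identical(as.character(table$sample_id), as.character(meta$sample_id))) {
    abort("table and metadata are not sample-aligned; run align_samples() first",
          class = "scfamap_alignment_error")
  }
  m <- abundance_matrix(table)
  grp <- as.factor(meta$group)
  hits <- m >= abundance_min
  per_group_hits <- rowsum(hits + 0, grp)  # groups x features
  kept <- apply(per_group_hits >= min_prevalent_samples, 2, any)
  reason <- ifelse(kept, NA_character_,
                   ifelse(colSums(hits) == 0, "low_abundance", "low_prevalence"))
  report <- tibble(feature_id = colnames(m), kept = unname(kept),
                   reason = unname(reason))
  list(table = as_abundance_tibble(m[, kept, drop = FALSE]), report = report)
}

#' Screen features for fold differences between group means
#'
#' Computes, for each feature and each ordered pair of clinical groups, the
#' fold ratio of group mean relative abundances
#' `(mean_A + pc) / (mean_B + pc)` and reports pairs at or above
#' `fold_min` (default 3, the usual differential-abundance screen).
#'
#' @param table Relative-abundance tibble.
#' @param meta Aligned metadata with `group`.
#' @param fold_min Minimum fold ratio to emit, default 3.
#' @param pseudocount Added to both means before the ratio; default 0.
#' @param mean_fun `"arithmetic"` (default) or `"geometric"` group means.
#' @return A tibble `feature_id`, `group_a`, `group_b`, `mean_a`, `mean_b`,
#'   `fold`, sorted by descending fold.
#' @export
fold_change_screen <- function(table, meta, fold_min = 3, pseudocount = 0,
                               mean_fun = c("arithmetic", "geometric")) {
  mean_fun <- match.arg(mean_fun)
  validate_abundance(table, "relative")
  grp <- droplevels(as.factor(meta$group))
  if (nlevels(grp) < 2) {
    abort("fold_change_screen needs at least two groups",
          class = "scfamap_config_error")
  }
  m <- abundance_matrix(table)
  gmeans <- if (mean_fun == "arithmetic") {
    rowsum(m, grp) / as.vector(table(grp))
  } else {
    exp(rowsum(log(m + pseudocount), grp) / as.vector(table(grp))) - pseudocount
  }
  pairs <- expand.grid(group_a = levels(grp), group_b = levels(grp),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$group_a != pairs$group_b, , drop = FALSE]
  out <- purrr::pmap(pairs, function(group_a, group_b) {
    ma <- unname(gmeans[group_a, ])
    mb <- unname(gmeans[group_b, ])
    tibble(feature_id = colnames(m), group_a = group_a, group_b = group_b,
           mean_a = ma, mean_b = mb,
           fold = (ma + pseudocount) / (mb + pseudocount))
  }) |> bind_rows()
  out |>
    filter(.data$fold >= fold_min) |>
    arrange(desc(.data$fold))
}
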