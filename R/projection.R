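#' Rank taxa by biplot projection onto an SCFA arrow
#'
#' In the plane of the first two constrained axes of a (p)CCA biplot, each
#' taxon's species-score vector `v` is projected onto the unit direction
#' `u` of the chosen SCFA arrow. The angle to the axis LINE,
#' `theta = arccos(|<v,u>| / ||v||)`, treats positive and negative
#' directions alike; a taxon is retained iff `theta <= cone_deg/2` and
#' `|<v,u>| >= score_min`. The signed projection `<v,u>` is the reported
#' score: its magnitude ranks the strength of the taxon-SCFA association,
#' its sign the direction.
#'
#' With a single constrained axis the cone degenerates: the angle is 0 for
#' every taxon and only the score threshold applies.
#'
#' @param ord A `pcca` fit.
#' @param scfa_id Name of the constraint (biplot arrow) to project onto.
#' @param cone_deg Total aperture of the retention cone in degrees
#'   (default 60, i.e. within 30 degrees of the axis line).
#' @param score_min Minimum absolute projection score (default 0.5).
#' @param plane_axes Pair of constrained-axis indices defining the biplot
#'   plane (default first two).
#' @return A tibble `feature_id`, `projection_score`, `angle_deg`,
#'   `retained`, sorted among retained by descending `|score|` (ties broken
#'   by feature id), with attributes `scfa_id`, `cone_deg`, `score_min`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = c(HV = 12, `IBS-D` = 12),
#'                                         p_taxa = 30), seed = 3)
#' fit <- pcca(cohort$table, cohort$meta,
#'             constraints = c("acetate", "butyrate", "propionate"),
#'             conditions = "transit_days")
#' project_taxa(fit, "acetate")
project_taxa <- function(ord, scfa_id, cone_deg = 60, score_min = 0.5,
                         plane_axes = c(1, 2)) {
  stopifnot(inherits(ord, "pcca"))
  if (!scfa_id %in% rownames(ord$biplot_scores)) {
    abort(sprintf("'%s' is not a constraint of this ordination", scfa_id),
          class = "scfamap_key_error")
  }
  n_axes <- ncol(ord$species_scores)
  plane_axes <- plane_axes[plane_axes <= n_axes]
  if (length(plane_axes) == 0) {
    abort("no constrained axes available", class = "scfamap_design_error")
  }
  arrow <- ord$biplot_scores[scfa_id, plane_axes]
  len <- sqrt(sum(arrow^2))
  if (len < 1e-12) {
    abort(sprintf("biplot arrow for '%s' has zero length", scfa_id),
          class = "scfamap_degenerate_error")
  }
  u <- arrow / len
  V <- ord$species_scores[, plane_axes, drop = FALSE]
  score <- drop(V %*% u)
  vnorm <- sqrt(rowSums(V^2))
  if (length(plane_axes) == 1L) {
    angle <- ifelse(vnorm > 0, 0, NA_real_)
  } else {
    cosang <- ifelse(vnorm > 0, pmin(abs(score) / vnorm, 1), NA_real_)
    angle <- acos(cosang) * 180 / pi
  }
  retained <- !is.na(angle) & angle <= cone_deg / 2 & abs(score) >= score_min
  out <- tibble(feature_id = rownames(V),
                projection_score = unname(score),
                angle_deg = unname(angle),
                retained = unname(retained)) |>
    arrange(desc(.data$retained), desc(abs(.data$projection_score)),
            .data$feature_id)
  attr(out, "scfa_id") <- scfa_id
  attr(out, "cone_deg") <- cone_deg
  attr(out, "score_min") <- score_min
  attr(out, "plane_axes") <- plane_axes
  out
}

#' Per-group microbe-SCFA projection rankings
#'
#' Runs the full within-group pipeline — abundance/prevalence filter,
#' transit-conditioned pCCA, projection ranking for every SCFA constraint —
#' independently within each clinical group and for the overall cohort.
#'
#' @param table Relative-abundance tibble.
#' @param meta Aligned metadata with `group` and the constraint/condition
#'   columns.
#' @param constraints Character vector of SCFA columns in `meta`.
#' @param conditions Conditioning columns (default `"transit_days"`).
#' @param cone_deg,score_min Retention rules passed to [project_taxa()].
#' @param abundance_min,min_prevalent_samples Filter thresholds passed to
#'   [filter_high_abundant()].
#' @param min_group_n Minimum group size; smaller groups are skipped with a
#'   warning (default 4).
#' @param include_overall Also analyse the pooled cohort under the label
#'   `"overall"` (default `TRUE`).
#' @return A tibble with columns `group_id`, `scfa_id`, `feature_id`,
#'   `projection_score`, `angle_deg`, `retained` plus a `counts` attribute
#'   tibble (`group_id`, `scfa_id`, `n_retained`, `n_features`, `n_samples`).
#' @export
rank_by_group <- function(table, meta, constraints,
                          conditions = "transit_days",
                          cone_deg = 60, score_min = 0.5,
                          abundance_min = 0.001, min_prevalent_samples = 2,
                          min_group_n = 4, include_overall = TRUE) {
  stopifnot(identical(as.character(table$sample_id),
                      as.character(meta$sample_id)))
  groups <- levels(droplevels(as.factor(meta$group)))
  units <- c(if (include_overall) "overall", groups)

  one_unit <- function(gid) {
    idx <- if (gid == "overall") rep(TRUE, nrow(meta)) else meta$group == gid
    need <- c(constraints, conditions)
    idx <- idx & complete.cases(meta[need])
    if (sum(idx) < min_group_n) {
      warn(sprintf("group '%s' has fewer than %d usable samples; skipped",
                   gid, min_group_n))
      return(NULL)
    }
    tab_g <- table[idx, , drop = FALSE]
    meta_g <- meta[idx, , drop = FALSE]
    # re-close after subsetting so the filter sees within-group compositions
    tab_g <- relative_abundance(tab_g)
    filt <- filter_high_abundant(tab_g, meta_g, abundance_min,
                                 min_prevalent_samples)
    fit <- tryCatch(
      pcca(filt$table, meta_g, constraints = constraints,
           conditions = conditions),
      error = function(e) {
        warn(sprintf("group '%s': ordination failed (%s); skipped",
                     gid, conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) return(NULL)
    purrr::map(constraints, function(s) {
      pr <- project_taxa(fit, s, cone_deg = cone_deg, score_min = score_min)
      mutate(pr, group_id = gid, scfa_id = s, .before = 1)
    }) |> bind_rows()
  }

  res <- purrr::map(units, one_unit) |> bind_rows()
  counts <- res |>
    group_by(.data$group_id, .data$scfa_id) |>
    summarise(n_retained = sum(.data$retained), n_features = n(),
              .groups = "drop")
  attr(res, "counts") <- counts
  res
}

#' Plot a projection ranking
#'
#' Diverging bar chart of retained taxa per SCFA, signed by association
#' direction.
#'
#' @param ranking Output of [rank_by_group()] (or [project_taxa()] with
#'   `group_id`/`scfa_id` columns added).
#' @param top_n Show at most this many taxa per panel.
#' @return A ggplot object.
#' @export
plot_projection_ranking <- function(ranking, top_n = 20) {
  df <- ranking |>
    filter(.data$retained) |>
    group_by(dplyr::across(any_of(c("group_id", "scfa_id")))) |>
    dplyr::slice_max(abs(.data$projection_score), n = top_n) |>
    ungroup() |>
    mutate(direction = ifelse(.data$projection_score >= 0,
                              "positive", "negative"))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$projection_score,
    y = stats::reorder(.data$feature_id, abs(.data$projection_score)),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "firebrick",
                                          negative = "purple4")) +
    ggplot2::labs(x = "projection score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (all(c("group_id", "scfa_id") %in% names(df))) {
    p <- p + ggplot2::facet_grid(group_id ~ scfa_id, scales = "free_y")
  }
  p
}
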