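#' Read a sample-by-feature abundance table
#'
#' Reads a delimited abundance table with one header row of feature
#' identifiers and a first column of sample identifiers, validates it, and
#' returns a tibble in the package's canonical layout (`sample_id` first,
#' numeric feature columns after).
#'
#' @param path Path to a TSV (or CSV, with `delim = ","`) file.
#' @param kind Either `"counts"` or `"relative"`. Relative tables must have
#'   rows summing to 1 within `1e-9` (after optional renormalisation).
#' @param delim Field delimiter; tab by default.
#' @param auto_transpose If `TRUE` and the table has more rows than columns
#'   by a wide margin (features as rows, the other common shipping layout),
#'   transpose so samples are rows. Off by default.
#' @param renormalize If `TRUE`, re-close each row to sum to 1 and treat the
#'   result as relative abundances (e.g. after restricting a profile to the
#'   species level).
#' @return A tibble with column `sample_id` followed by feature columns.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tt1\tt2", "s1\t6\t4", "s2\t2\t8"), tf)
#' read_abundance_table(tf, kind = "counts")
read_abundance_table <- function(path, kind = c("counts", "relative"),
                                 delim = "\t", auto_transpose = FALSE,
                                 renormalize = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "scfamap_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(sprintf("empty or header-only abundance table: %s", path),
          class = "scfamap_format_error")
  }
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  non_num <- names(raw)[-1][!vapply(raw[-1], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(sprintf("non-numeric abundance column(s): %s",
                  paste(head(non_num, 5), collapse = ", ")),
          class = "scfamap_format_error")
  }
  m <- abundance_matrix(raw)
  if (anyNA(m) || any(m < 0)) {
    bad <- which(is.na(m) | m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("invalid abundance at sample '%s', feature '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "scfamap_format_error")
  }
  if (auto_transpose && nrow(m) > ncol(m)) {
    m <- t(m)
    names(dimnames(m)) <- NULL
  }
  if (renormalize) {
    m <- close_rows(m)
    kind <- "relative"
  }
  out <- as_abundance_tibble(m)
  validate_abundance(out, kind)
  out
}

#' Convert a counts table to relative abundances
#'
#' Row-normalises a counts table so each sample's abundances sum to 1.
#'
#' @param table Abundance tibble (`sample_id` + numeric feature columns).
#' @return A relative-abundance tibble.
#' @export
relative_abundance <- function(table) {
  m <- close_rows(abundance_matrix(table))
  as_abundance_tibble(m)
}

#' Read a cohort metadata table
#'
#' Reads per-sample clinical metadata: group label, covariates, SCFA
#' concentrations, colonic transit time and stool bile-acid traits. Empty
#' cells and the string `"NA"` are read as missing; missing traits are kept
#' here and dropped per-endpoint downstream, never imputed.
#'
#' @param path Path to a TSV file with a `sample_id` column and a `group`
#'   column; any further columns are carried along as traits/covariates.
#' @param delim Field delimiter.
#' @return A tibble with `sample_id`, `group` (factor) and trait columns.
#' @export
read_metadata <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "scfamap_io_error")
  }
  meta <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            na = c("", "NA"), progress = FALSE,
                            show_col_types = FALSE)
  names(meta)[1] <- "sample_id"
  meta$sample_id <- as.character(meta$sample_id)
  check_no_duplicates(meta$sample_id, "sample")
  if ("group" %in% names(meta)) meta$group <- factor(meta$group)
  meta
}

#' Read gut-metabolic-module (GMM) definitions
#'
#' Reads a TSV with columns `module_id`, `description`, `ko_ids` where
#' `ko_ids` is a comma-separated list of KEGG orthogroup identifiers.
#'
#' @param path Path to the definition TSV.
#' @param delim Field delimiter.
#' @return A tibble with one row per module and a list-column `ko_ids`.
#' @export
read_gmm_definitions <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  need <- c("module_id", "description", "ko_ids")
  if (!all(need %in% names(raw))) {
    abort(sprintf("GMM definition file must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "scfamap_format_error")
  }
  check_no_duplicates(raw$module_id, "module")
  out <- raw |>
    mutate(ko_ids = purrr::map(.data$ko_ids, function(x) {
      if (is.na(x)) return(character(0))
      kos <- unique(trimws(strsplit(as.character(x), ",")[[1]]))
      kos[nzchar(kos)]
    }))
  bad <- out$module_id[purrr::map_int(out$ko_ids, length) == 0]
  if (length(bad) > 0) {
    abort(sprintf("module(s) with empty KO set: %s", paste(bad, collapse = ", ")),
          class = "scfamap_format_error")
  }
  out
}

#' Align an abundance table with cohort metadata
#'
#' Restricts both tables to their shared samples, in the same order
#' (abundance-table order). Samples missing any of `require_traits` are
#' dropped with an informative message, mirroring per-endpoint exclusion of
#' missing values.
#'
#' @param table Abundance tibble.
#' @param meta Metadata tibble.
#' @param require_traits Character vector of metadata columns that must be
#'   non-missing; samples failing this are dropped.
#' @return A list with elements `table` and `meta`, row-aligned.
#' @export
align_samples <- function(table, meta, require_traits = character()) {
  shared <- intersect(table$sample_id, meta$sample_id)
  if (length(shared) == 0L) {
    abort("no shared samples between abundance table and metadata",
          class = "scfamap_alignment_error")
  }
  keep <- table$sample_id[table$sample_id %in% shared]
  meta2 <- meta[match(keep, meta$sample_id), , drop = FALSE]
  if (length(require_traits) > 0) {
    missing_cols <- setdiff(require_traits, names(meta2))
    if (length(missing_cols) > 0) {
      abort(sprintf("required trait column(s) absent from metadata: %s",
                    paste(missing_cols, collapse = ", ")),
            class = "scfamap_alignment_error")
    }
    ok <- complete.cases(meta2[require_traits])
    n_drop <- sum(!ok)
    if (n_drop > 0) {
      inform(sprintf("align_samples: dropped %d sample(s) missing %s",
                     n_drop, paste(require_traits, collapse = "/")))
    }
    keep <- keep[ok]
    meta2 <- meta2[ok, , drop = FALSE]
  }
  if (length(keep) == 0L) {
    abort("no samples remain after dropping missing traits",
          class = "scfamap_alignment_error")
  }
  list(table = table[match(keep, table$sample_id), , drop = FALSE],
       meta = meta2)
}

#' Write pipeline result tables to a directory
#'
#' Exports each result in a named list as a flat TSV and returns a manifest.
#' Data frames are written as-is; fitted ordination objects, consensus
#' networks and rankings are first flattened with their `tidy()` methods.
#'
#' @param results Named list of results (tibbles/data frames or objects with
#'   a `tidy()` method).
#' @param out_dir Output directory, created if needed.
#' @return A manifest tibble with columns `name`, `file`, `n_rows`.
#' @export
write_result_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir),
          class = "scfamap_io_error")
  }
  rows <- purrr::imap(results, function(res, name) {
    df <- if (is.data.frame(res)) res else generics::tidy(res)
    file <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, file, progress = FALSE)
    tibble(name = name, file = file, n_rows = nrow(df))
  })
  bind_rows(rows)
}
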