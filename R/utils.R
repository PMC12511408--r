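#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select filter arrange left_join bind_rows bind_cols
#'   group_by summarise ungroup across all_of any_of desc n rename relocate
#'   pull distinct
#' @importFrom stats lm pnorm pt qnorm rnorm runif rlnorm sd var cor coef
#'   kruskal.test p.adjust setNames complete.cases dist
#' @importFrom utils head
#' @importFrom Rcpp evalCpp
#' @useDynLib scfamap, .registration = TRUE
NULL

# Convert a sample-by-feature tibble (first column = sample identifiers) to a
# numeric matrix with sample ids as rownames.
abundance_matrix <- function(tbl, id_col = "sample_id") {
  stopifnot(is.data.frame(tbl))
  if (!id_col %in% names(tbl)) {
    abort(sprintf("column '%s' not found in abundance table", id_col),
          class = "scfamap_format_error")
  }
  ids <- as.character(tbl[[id_col]])
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (!is.numeric(m)) {
    abort("abundance table contains non-numeric feature columns",
          class = "scfamap_format_error")
  }
  rownames(m) <- ids
  m
}

as_abundance_tibble <- function(m, id_col = "sample_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(!!id_col := rownames(m)) |> dplyr::bind_cols(out)
  out
}

check_no_duplicates <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    abort(sprintf("duplicate %s identifier(s): %s", what,
                  paste(head(dup, 5), collapse = ", ")),
          class = "scfamap_format_error")
  }
  invisible(x)
}

# Validate an abundance tibble; kind is "counts" or "relative".
validate_abundance <- function(tbl, kind = c("counts", "relative"),
                               id_col = "sample_id", tol = 1e-9) {
  kind <- match.arg(kind)
  m <- abundance_matrix(tbl, id_col)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    abort("abundance table is empty", class = "scfamap_format_error")
  }
  check_no_duplicates(rownames(m), "sample")
  check_no_duplicates(colnames(m), "feature")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at sample '%s', feature '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "scfamap_format_error")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value at sample '%s', feature '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "scfamap_format_error")
  }
  if (kind == "relative") {
    rs <- rowSums(m)
    if (any(abs(rs - 1) > tol)) {
      bad <- rownames(m)[which.max(abs(rs - 1))]
      abort(sprintf("relative abundances must sum to 1 per sample; sample '%s' sums to %.6g",
                    bad, rs[which.max(abs(rs - 1))]),
            class = "scfamap_format_error")
    }
  }
  invisible(tbl)
}

# Row-closure to relative abundances.
close_rows <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("sample '%s' has zero total abundance and cannot be closed",
                  rownames(m)[which(rs <= 0)[1]]),
          class = "scfamap_domain_error")
  }
  sweep(m, 1, rs, "/")
}

feature_ids <- function(tbl, id_col = "sample_id") setdiff(names(tbl), id_col)

# Deterministic per-stage seed fan-out from one global seed.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1013L) %% .Machine$integer.max
}
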