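#' Construct a feature table
#'
#' A feature table holds an LC-MS aligned peak matrix: one row per chemical
#' feature (identified by its mass-to-charge ratio and retention time) and one
#' column per sample (culture replicate or extraction blank), with nonnegative
#' peak areas.
#'
#' @param abundance numeric matrix, features x samples, nonnegative. Row and
#'   column names are used as feature and sample identifiers when present.
#' @param mz numeric vector of feature m/z values (Da), one per row.
#' @param rt numeric vector of feature retention times (minutes), one per row.
#' @param feature_id optional character vector of feature identifiers;
#'   defaults to rownames of `abundance` or `F1..Fn`.
#' @return an object of class `feature_table`: a list with elements
#'   `features` (data.frame: feature_id, mz, rt) and `abundance` (matrix).
#' @export
feature_table <- function(abundance, mz, rt, feature_id = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  n <- nrow(abundance)
  if (length(mz) != n || length(rt) != n)
    abort("mz and rt must have one value per feature row", "bad-argument")
  if (any(abundance < 0, na.rm = TRUE))
    abort("abundances must be nonnegative", "bad-argument")
  abundance[is.na(abundance)] <- 0
  feature_id <- feature_id %||% rownames(abundance) %||% paste0("F", seq_len(n))
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    abort("feature identifiers must be unique", "malformed-table")
  if (anyDuplicated(paste(mz, rt)))
    abort("duplicate (m/z, retention time) pairs", "malformed-table")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("S", seq_len(ncol(abundance)))
  rownames(abundance) <- feature_id
  structure(
    list(features = data.frame(feature_id = feature_id, mz = as.numeric(mz),
                               rt = as.numeric(rt), stringsAsFactors = FALSE),
         abundance = abundance),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  m/z range %.4f-%.4f, RT range %.2f-%.2f\n",
              min(x$features$mz), max(x$features$mz),
              min(x$features$rt), max(x$features$rt)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

# check every abundance column has exactly one metadata row
check_metadata <- function(table, metadata) {
  if (!all(c("sample_id", "isolate_id", "is_blank") %in% names(metadata)))
    abort("metadata needs sample_id, isolate_id and is_blank columns", "bad-metadata")
  if (anyDuplicated(metadata$sample_id))
    abort("duplicate sample_id rows in metadata", "bad-metadata")
  missing <- setdiff(colnames(table$abundance), metadata$sample_id)
  if (length(missing))
    abort(paste0("samples absent from metadata: ", paste(missing, collapse = ", ")),
          "bad-metadata")
  metadata[match(colnames(table$abundance), metadata$sample_id), , drop = FALSE]
}

#' Construct an incidence matrix
#'
#' An incidence matrix records binary presence of items (features or
#' scaffolds) across sampling units (isolates), together with the summary
#' statistics used by incidence-based richness estimators: the number of
#' units `T`, per-item incidence frequencies `Ti`, the unique/duplicate
#' counts `Q1`/`Q2` (items seen in exactly one / exactly two units), and the
#' observed richness `S_obs`.
#'
#' @param mat logical or 0/1 numeric matrix, items x units.
#' @param groups optional vector of group labels (e.g. clade or chemical
#'   cluster), one per unit.
#' @param drop_empty drop all-zero item rows (default TRUE); the number
#'   dropped is recorded in attribute `n_dropped`.
#' @return an object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(mat, groups = NULL, drop_empty = TRUE) {
  mat <- as.matrix(mat)
  mat <- (mat != 0) * 1L
  if (is.null(rownames(mat))) rownames(mat) <- paste0("F", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("I", seq_len(ncol(mat)))
  if (!is.null(groups)) {
    if (length(groups) != ncol(mat))
      abort("one group label per unit required", "bad-argument")
    groups <- stats::setNames(as.character(groups), colnames(mat))
  }
  n_dropped <- 0L
  if (drop_empty) {
    keep <- rowSums(mat) > 0
    n_dropped <- sum(!keep)
    mat <- mat[keep, , drop = FALSE]
  }
  Ti <- rowSums(mat)
  out <- structure(
    list(incidence = mat, groups = groups, T = ncol(mat), Ti = Ti,
         Q1 = sum(Ti == 1), Q2 = sum(Ti == 2), S_obs = nrow(mat)),
    class = "incidence_matrix")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d items x %d units (Q1=%d, Q2=%d)\n",
              x$S_obs, x$T, x$Q1, x$Q2))
  if (!is.null(x$groups))
    cat("  groups:", paste(names(table(x$groups)), table(x$groups),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# subset an incidence matrix by unit (isolate) names or indices,
# recomputing all summary statistics
subset_units <- function(x, units) {
  incidence_matrix(x$incidence[, units, drop = FALSE],
                   groups = if (is.null(x$groups)) NULL else x$groups[units],
                   drop_empty = TRUE)
}
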