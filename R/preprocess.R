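#' Read an aligned feature table exported from MZmine
#'
#' Parses the aligned-export CSV dialect used by MZmine ("row ID",
#' "row m/z", "row retention time", then one "<sample> Peak area" column per
#' sample). Missing or empty peak areas are read as zero.
#'
#' @param path path to the CSV file.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  area_cols <- grep(" Peak area$", names(df), value = TRUE)
  if (!length(area_cols))
    abort("no '<sample> Peak area' columns found", "malformed-table")
  need <- c("row m/z", "row retention time")
  if (!all(need %in% names(df)))
    abort("missing 'row m/z' / 'row retention time' columns", "malformed-table")
  if (anyDuplicated(paste(df[["row m/z"]], df[["row retention time"]])))
    abort("duplicate (m/z, retention time) rows", "malformed-table")
  ab <- sapply(area_cols, function(cn) {
    v <- df[[cn]]
    if (is.character(v)) {
      v[v == ""] <- "0"
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) abort(sprintf("non-numeric peak area in column '%s'", cn),
                           "parse-error")
      v <- vn
    }
    v[is.na(v)] <- 0
    v
  })
  ab <- matrix(ab, nrow = nrow(df),
               dimnames = list(NULL, sub(" Peak area$", "", area_cols)))
  fid <- if ("row ID" %in% names(df)) as.character(df[["row ID"]]) else NULL
  feature_table(ab, mz = df[["row m/z"]], rt = df[["row retention time"]],
                feature_id = fid)
}

#' Write a feature table in the MZmine aligned-export dialect
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(check.names = FALSE,
                   `row ID` = table$features$feature_id,
                   `row m/z` = table$features$mz,
                   `row retention time` = table$features$rt)
  ab <- as.data.frame(table$abundance)
  names(ab) <- paste(colnames(table$abundance), "Peak area")
  utils::write.csv(cbind(df, ab), path, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated metadata with columns `sample_id`, `isolate_id`, `clade`,
#' `replicate`, `is_blank` and optional `lon`/`lat`. Blank samples carry no
#' clade (empty / NA).
#'
#' @param path TSV path.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"is_blank" %in% names(md))
    abort("metadata needs an is_blank column", "bad-metadata")
  md$is_blank <- as.logical(md$is_blank)
  if ("clade" %in% names(md)) md$clade[md$clade == ""] <- NA_character_
  md
}

#' @rdname read_metadata
#' @param metadata data.frame of sample metadata.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove features detected in extraction blanks
#'
#' Every feature with a nonzero peak area in any blank sample is removed from
#' the table entirely, and the blank columns are dropped. This strict rule
#' treats any blank detection as contamination or medium background. An
#' optional fold-change rescue keeps a feature whose maximum culture
#' abundance exceeds `fold` times its maximum blank abundance.
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata (see [read_metadata()]).
#' @param mode `"strict"` (default): remove on any blank detection;
#'   `"fold"`: keep features with max(culture)/max(blank) >= `fold`.
#' @param fold fold-change threshold used when `mode = "fold"`.
#' @return filtered [feature_table()] without blank columns; attributes
#'   `removed_features` (character vector) record what was dropped.
#' @export
blank_filter <- function(table, metadata, mode = c("strict", "fold"), fold = 3) {
  mode <- match.arg(mode)
  md <- check_metadata(table, metadata)
  blanks <- md$sample_id[md$is_blank]
  if (!length(blanks)) {
    warning("no blank samples present; table returned unchanged")
    return(table)
  }
  ab <- table$abundance
  blank_max <- apply(ab[, blanks, drop = FALSE], 1, max)
  culture_cols <- setdiff(colnames(ab), blanks)
  drop <- if (mode == "strict") blank_max > 0
          else {
            cmax <- apply(ab[, culture_cols, drop = FALSE], 1, max)
            blank_max > 0 & cmax < fold * blank_max
          }
  out <- feature_table(ab[!drop, culture_cols, drop = FALSE],
                       mz = table$features$mz[!drop],
                       rt = table$features$rt[!drop],
                       feature_id = table$features$feature_id[!drop])
  attr(out, "removed_features") <- table$features$feature_id[drop]
  out
}

#' Normalize each sample to its total ion current
#'
#' Divides each sample column by its total abundance so that every column
#' sums to one; corrects for injection-to-injection intensity differences.
#'
#' @param table a [feature_table()].
#' @return normalized [feature_table()].
#' @export
tic_normalize <- function(table) {
  tot <- colSums(table$abundance)
  if (any(tot <= 0))
    abort(paste0("all-zero sample column(s): ",
                 paste(colnames(table$abundance)[tot <= 0], collapse = ", ")),
          "empty-sample")
  feature_table(sweep(table$abundance, 2, tot, "/"),
                mz = table$features$mz, rt = table$features$rt,
                feature_id = table$features$feature_id)
}

#' Merge replicate cultures into one column per isolate
#'
#' @param table a [feature_table()] (normally TIC-normalized).
#' @param metadata sample metadata mapping each culture to its isolate.
#' @param mode `"mean"`: average replicate abundances (preserves quantitative
#'   Bray-Curtis structure); `"union"`: per-feature maximum (presence if
#'   detected in any replicate).
#' @return [feature_table()] with one column per isolate.
#' @export
merge_replicates <- function(table, metadata, mode = c("mean", "union")) {
  mode <- match.arg(mode)
  md <- check_metadata(table, metadata)
  if (any(md$is_blank))
    abort("blank columns present; run blank_filter() first", "bad-metadata")
  iso <- unique(md$isolate_id)
  ab <- table$abundance
  merged <- vapply(iso, function(i) {
    cols <- md$sample_id[md$isolate_id == i]
    sub <- ab[, cols, drop = FALSE]
    if (mode == "mean") rowMeans(sub) else apply(sub, 1, max)
  }, numeric(nrow(ab)))
  merged <- matrix(merged, nrow = nrow(ab), dimnames = list(rownames(ab), iso))
  feature_table(merged, mz = table$features$mz, rt = table$features$rt,
                feature_id = table$features$feature_id)
}

#' Binarize a feature table into an incidence matrix
#'
#' @param table a [feature_table()] with one column per isolate.
#' @param threshold presence threshold: present iff abundance > threshold
#'   (default 0, i.e. any detected peak counts).
#' @param groups optional group label per isolate (clade or cluster).
#' @return an [incidence_matrix()]; all-zero feature rows are dropped and
#'   counted in attribute `n_dropped`.
#' @export
binarize <- function(table, threshold = 0, groups = NULL) {
  if (threshold < 0) abort("threshold must be >= 0", "bad-argument")
  incidence_matrix(table$abundance > threshold, groups = groups)
}

#' Run the standard preprocessing pipeline
#'
#' Blank filter, TIC normalization, replicate merging and binarization, in
#' that fixed order (normalization is a per-injection property, so it
#' precedes merging; columns are re-normalized after a mean merge so they
#' still sum to one).
#'
#' @inheritParams blank_filter
#' @inheritParams merge_replicates
#' @inheritParams binarize
#' @param group_by metadata column used as isolate group label ("clade").
#' @return list with elements `normalized` (feature_table, per isolate) and
#'   `incidence` (incidence_matrix).
#' @export
preprocess <- function(table, metadata, mode = "mean", threshold = 0,
                       blank_mode = "strict", fold = 3, group_by = "clade") {
  filt <- if (any(metadata$is_blank))
    blank_filter(table, metadata, mode = blank_mode, fold = fold) else table
  norm <- tic_normalize(filt)
  merged <- merge_replicates(norm, metadata, mode = mode)
  if (mode == "mean") merged <- tic_normalize(merged)
  groups <- NULL
  if (!is.null(group_by) && group_by %in% names(metadata)) {
    md <- metadata[!metadata$is_blank, ]
    groups <- md[[group_by]][match(colnames(merged$abundance), md$isolate_id)]
  }
  list(normalized = merged,
       incidence = binarize(merged, threshold = threshold, groups = groups))
}
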