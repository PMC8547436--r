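#' Partition items by the exact set of groups containing them
#'
#' Venn-style partition: each item (feature or scaffold) is assigned to the
#' exact subset of groups in which it occurs, where group-level presence is
#' the union over the group's isolates (one detection suffices). The
#' all-groups subset is the core metabolome; single-group subsets are the
#' items unique to that group.
#'
#' @param incidence an [incidence_matrix()] with group labels (>= 2 groups).
#' @return list of class `venn_partition`: `counts` (data.frame: subset,
#'   n_groups, count, percent), `total`, `core`, `unique` (named vector per
#'   group).
#' @export
venn_partition <- function(incidence) {
  if (is.null(incidence$groups)) abort("group labels required", "bad-argument")
  gl <- sort(unique(incidence$groups))
  if (length(gl) < 2) abort("need at least two groups", "bad-argument")
  mat <- incidence$incidence
  gp <- vapply(gl, function(g)
    rowSums(mat[, names(incidence$groups)[incidence$groups == g], drop = FALSE]) > 0,
    logical(nrow(mat)))
  none <- rowSums(gp) == 0
  if (any(none)) {
    warning(sprintf("%d items present in no group; excluded", sum(none)))
    gp <- gp[!none, , drop = FALSE]
  }
  pattern <- apply(gp, 1, function(r) paste(gl[r], collapse = "&"))
  counts <- table(pattern)
  n_groups <- lengths(strsplit(names(counts), "&", fixed = TRUE))
  total <- nrow(gp)
  df <- data.frame(subset = names(counts), n_groups = n_groups,
                   count = as.integer(counts),
                   percent = as_percent(as.integer(counts), total),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(df$n_groups, df$subset), ]
  core_label <- paste(gl, collapse = "&")
  uniq <- vapply(gl, function(g) {
    i <- match(g, df$subset); if (is.na(i)) 0L else df$count[i]
  }, integer(1))
  structure(list(counts = df, total = total,
                 core = if (core_label %in% df$subset)
                   df$count[df$subset == core_label] else 0L,
                 unique = uniq),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d items; core (all groups): %d (%.1f%%)\n",
              x$total, x$core, as_percent(x$core, x$total)))
  print(utils::head(x$counts[order(-x$counts$count), ], 10), row.names = FALSE)
  invisible(x)
}

#' Format a count as a one-decimal percentage
#'
#' `100 * count / total`, rounded half away from zero to one decimal — the
#' convention used in published tables (e.g. 539 of 1,661 prints as 32.5,
#' not 32.4).
#'
#' @param count numeric vector, `0 <= count <= total`.
#' @param total positive total.
#' @return numeric vector of percentages at one-decimal resolution.
#' @export
as_percent <- function(count, total) {
  if (any(total <= 0)) abort("total must be > 0", "bad-argument")
  if (any(count < 0 | count > total)) abort("count must lie in [0, total]", "bad-argument")
  round_half_up(100 * count / total, 1)
}

#' Ordered group-wise accumulation of coverage
#'
#' Adds groups one at a time in a stated order and reports the percentage
#' of the grand-total item pool newly covered by each group. Because
#' rounding each increment to one decimal can leave the cumulative total at
#' 99.9/100.1, the final increment absorbs the rounding residue so the
#' cumulative coverage prints as exactly 100.0; raw unrounded values are
#' returned alongside.
#'
#' @param incidence an [incidence_matrix()] with group labels.
#' @param order a permutation of the group labels, or `"largest-first"` /
#'   `"smallest-first"` (by number of isolates).
#' @return data.frame of class `coverage_report`: `group`, `n_isolates`,
#'   `new_items`, `increment_raw`, `increment` (percent), `cumulative`.
#' @export
ordered_accumulation <- function(incidence, order = "largest-first") {
  if (is.null(incidence$groups)) abort("group labels required", "bad-argument")
  sizes <- table(incidence$groups)
  if (length(order) == 1 && order %in% c("largest-first", "smallest-first")) {
    order <- names(sort(sizes, decreasing = order == "largest-first"))
  }
  if (!setequal(order, names(sizes)) || anyDuplicated(order))
    abort("order must be a permutation of the group labels", "bad-argument")
  mat <- incidence$incidence
  total <- nrow(mat)
  covered <- logical(total)
  new_items <- integer(length(order))
  for (i in seq_along(order)) {
    g <- order[i]
    pres <- rowSums(mat[, names(incidence$groups)[incidence$groups == g],
                        drop = FALSE]) > 0
    new_items[i] <- sum(pres & !covered)
    covered <- covered | pres
  }
  raw <- 100 * new_items / total
  inc <- as_percent(new_items, total)
  inc[length(inc)] <- round_half_up(100 - sum(inc[-length(inc)]), 1)
  structure(data.frame(group = order, n_isolates = as.integer(sizes[order]),
                       new_items = new_items, increment_raw = raw,
                       increment = inc, cumulative = cumsum(inc),
                       stringsAsFactors = FALSE),
            class = c("coverage_report", "data.frame"))
}

#' Per-group geographic range summary
#'
#' Longitude/latitude bounding box, isolate count and longitudinal span per
#' group, flagging groups whose span falls below a fraction of the overall
#' span (range-restricted groups).
#'
#' @param metadata data.frame with `isolate_id`, `lon`, `lat` (one row per
#'   sample; blanks and repeated isolates are handled).
#' @param labels named vector of group labels per isolate.
#' @param restricted_fraction flag groups whose longitudinal span is below
#'   this fraction of the overall span (default 0.5).
#' @return data.frame: group, n, lon_min/lon_max/lat_min/lat_max, lon_span,
#'   restricted.
#' @export
geographic_summary <- function(metadata, labels, restricted_fraction = 0.5) {
  md <- metadata[!metadata$is_blank & !duplicated(metadata$isolate_id), ]
  md <- md[!is.na(md$lon) & !is.na(md$lat), ]
  if (!nrow(md)) abort("no coordinates present", "bad-argument")
  md$group <- labels[md$isolate_id]
  skip <- is.na(md$group)
  if (any(skip)) {
    warning(sprintf("%d isolates without group label skipped", sum(skip)))
    md <- md[!skip, ]
  }
  overall_span <- diff(range(md$lon))
  out <- do.call(rbind, lapply(split(md, md$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               lon_min = min(d$lon), lon_max = max(d$lon),
               lat_min = min(d$lat), lat_max = max(d$lat),
               lon_span = diff(range(d$lon)), stringsAsFactors = FALSE)
  }))
  out$restricted <- out$lon_span < restricted_fraction * overall_span
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulation (or file input), preprocessing, chemistry-based partitioning,
#' diversity and coverage analysis, molecular networking, and reporting, in
#' one call. Every stage failure aborts with a stage-named error. The
#' returned bundle (and the JSON summary written to `outdir`) carries the
#' machine-readable results: per-group richness, coverage targets, Venn
#' partitions for features and scaffolds, ordered accumulation, PERMANOVA,
#' and all parameters and seeds used.
#'
#' @param config list (or YAML file path) with optional elements:
#'   `simulate` (a [generator_config()] or TRUE for defaults), or `features`
#'   / `metadata` / `mgf` file paths; `seed`; `coverage_fractions`;
#'   `endpoint`; `k_range`; `n_perm`; network parameters `min_cosine`,
#'   `min_matched`, `top_k`, `frag_tol`.
#' @param outdir optional output directory for the CSV/TSV views and the
#'   `summary.json` file.
#' @return list of class `chemcov_report` with all stage results.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("reading YAML configs requires the yaml package", "bad-argument")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "stage-failure"))
  }

  dat <- stage("input", {
    if (!is.null(config$features)) {
      list(feature_table = read_feature_table(config$features),
           metadata = read_metadata(config$metadata),
           spectra = if (!is.null(config$mgf)) read_mgf(config$mgf) else NULL,
           ground_truth = NULL)
    } else {
      gc <- config$simulate
      if (is.null(gc) || isTRUE(gc)) gc <- generator_config(seed = seed)
      generate_dataset(gc)
    }
  })

  prep <- stage("preprocess",
                preprocess(dat$feature_table, dat$metadata,
                           threshold = config$threshold %||% 0))

  part <- stage("partition", {
    d <- bray_curtis_dist(prep$normalized)
    cl <- cluster_isolates(d, k_range = config$k_range %||% 2:10)
    pn_clade <- if (!is.null(prep$incidence$groups))
      permanova(d, prep$incidence$groups, n_perm = config$n_perm %||% 999,
                seed = seed) else NULL
    pn_cluster <- permanova(d, cl$labels, n_perm = config$n_perm %||% 999,
                            seed = seed)
    list(dist = d, pcoa = pcoa(d), clusters = cl,
         permanova_clade = pn_clade, permanova_cluster = pn_cluster)
  })

  div <- stage("diversity", {
    inc <- prep$incidence
    rich <- alpha_richness(inc)
    list(richness = rich,
         comparison = if (!is.null(inc$groups))
           compare_richness(rich, inc$groups) else NULL,
         curve = accumulation_curve(inc, endpoint = config$endpoint %||% 500),
         coverage = coverage_targets(
           inc, config$coverage_fractions %||% c(0.5, 0.75, 0.9, 0.95, 0.99)),
         end_slope = end_slope(inc))
  })

  net <- if (!is.null(dat$spectra)) stage("network", {
    nw <- build_network(dat$spectra,
                        min_cosine = config$min_cosine %||% 0.7,
                        min_matched = config$min_matched %||% 6,
                        top_k = config$top_k %||% 10,
                        frag_tol = config$frag_tol %||% 0.02)
    list(network = nw,
         scaffold_incidence = scaffold_incidence(nw, prep$incidence),
         nonsingleton_incidence = scaffold_incidence(nw, prep$incidence,
                                                     drop_singletons = TRUE))
  }) else NULL

  rep_out <- stage("report", {
    out <- list(feature_venn = venn_partition(prep$incidence),
                feature_order = ordered_accumulation(prep$incidence, "largest-first"))
    if (!is.null(net)) {
      out$scaffold_venn <- venn_partition(net$scaffold_incidence)
      out$scaffold_order <- ordered_accumulation(net$scaffold_incidence,
                                                 "largest-first")
    }
    if (!is.null(dat$metadata$lon)) {
      labs <- stats::setNames(part$clusters$labels,
                              colnames(prep$normalized$abundance))
      out$geography <- geographic_summary(dat$metadata, labs)
    }
    out
  })

  summary <- list(
    seed = seed,
    n_isolates = prep$incidence$T,
    n_features = prep$incidence$S_obs,
    n_scaffolds = if (!is.null(net)) net$scaffold_incidence$S_obs else NULL,
    n_singleton_scaffolds = if (!is.null(net))
      attr(net$scaffold_incidence, "n_singletons") else NULL,
    selected_k = part$clusters$k,
    permanova = list(
      cluster = list(pseudo_F = part$permanova_cluster$pseudo_F,
                     p_value = part$permanova_cluster$p_value),
      clade = if (!is.null(part$permanova_clade))
        list(pseudo_F = part$permanova_clade$pseudo_F,
             p_value = part$permanova_clade$p_value) else NULL),
    richness = list(
      per_group = if (!is.null(div$comparison)) div$comparison$summary else NULL,
      anova_F = if (!is.null(div$comparison)) div$comparison$anova_F else NULL,
      anova_p = if (!is.null(div$comparison)) div$comparison$anova_p else NULL),
    coverage_targets = div$coverage,
    end_slope = div$end_slope,
    feature_venn = rep_out$feature_venn$counts,
    feature_core_percent = as_percent(rep_out$feature_venn$core,
                                      rep_out$feature_venn$total),
    scaffold_venn = if (!is.null(rep_out$scaffold_venn))
      rep_out$scaffold_venn$counts else NULL,
    ordered_accumulation = list(
      features = rep_out$feature_order,
      scaffolds = rep_out$scaffold_order),
    parameters = list(threshold = config$threshold %||% 0,
                      endpoint = config$endpoint %||% 500,
                      k_range = range(config$k_range %||% 2:10),
                      n_perm = config$n_perm %||% 999,
                      min_cosine = config$min_cosine %||% 0.7,
                      min_matched = config$min_matched %||% 6,
                      top_k = config$top_k %||% 10,
                      frag_tol = config$frag_tol %||% 0.02))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.matrix(part$dist), file.path(outdir, "distance_matrix.csv"))
    utils::write.csv(part$pcoa$coordinates, file.path(outdir, "pcoa_coordinates.csv"))
    utils::write.table(data.frame(isolate = names(part$clusters$labels),
                                  cluster = part$clusters$labels),
                       file.path(outdir, "cluster_labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(div$curve, file.path(outdir, "accumulation_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(div$coverage, file.path(outdir, "coverage_targets.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }

  structure(list(data = dat, preprocessed = prep, partition = part,
                 diversity = div, network = net, report = rep_out,
                 summary = summary),
            class = "chemcov_report")
}

#' @export
print.chemcov_report <- function(x, ...) {
  s <- x$summary
  cat("<chemcov_report>\n")
  cat(sprintf("  %d isolates, %d features", s$n_isolates, s$n_features))
  if (!is.null(s$n_scaffolds)) cat(sprintf(", %d scaffolds", s$n_scaffolds))
  cat("\n")
  cat(sprintf("  chemical clusters: k = %d; PERMANOVA p = %.4g\n",
              s$selected_k, s$permanova$cluster$p_value))
  cat(sprintf("  core features: %.1f%% of total\n", s$feature_core_percent))
  cat("  coverage targets:\n")
  print(s$coverage_targets, row.names = FALSE)
  invisible(x)
}
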