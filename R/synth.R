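#' Configuration for the synthetic isolate-collection generator
#'
#' Builds and validates the parameter set for [generate_dataset()]. The
#' defaults emulate a clade-structured fungal isolate collection: 198
#' isolates in 5 unevenly sized genetic clades (one dominant clade of 111),
#' a small core metabolome shared by all clades, large clade-specific
#' feature pools, features shared by pairs of clades, isolate-singleton
#' features making up 18% of the final feature set, duplicate cultures per
#' isolate, extraction blanks carrying medium-background features, and
#' scaffold-structured MS/MS spectra. Two deliberate mismatches between
#' genetics and chemistry are built in: one clade hides two distinct
#' chemotypes (so the true number of chemical clusters is `n_clades + 1`),
#' and a fraction of isolates in designated other clades is reassigned the
#' chemotype of one donor cluster ("embedded" cluster members).
#'
#' @param n_clades number of genetic clades.
#' @param clade_sizes isolates per clade (length `n_clades`).
#' @param clade_names labels for the clades.
#' @param n_core_features size of the core pool present across all clades.
#' @param n_clade_features clade-specific pool size per clade.
#' @param n_pairwise_shared_features features shared by random clade pairs.
#' @param singleton_fraction target fraction of final features present in
#'   exactly one isolate (injected post hoc so it is recoverable).
#' @param p_detect_core,p_detect_clade per-isolate Bernoulli detection
#'   probabilities for core and pool features, in (0, 1].
#' @param hidden_split_clade index of the clade hiding two chemotypes.
#' @param split_overlap fraction of the split clade's pool shared by both of
#'   its chemotypes (controls how chemically distinct they are).
#' @param embedded_cluster_rate per-isolate probability, within
#'   `embedded_into_clades`, of being reassigned the donor chemotype.
#' @param embedded_donor_cluster chemical cluster donated to embedded
#'   isolates (default: the split clade's first chemotype).
#' @param embedded_into_clades clade indices eligible for embedding.
#' @param n_replicates_per_isolate duplicate cultures per isolate.
#' @param n_blanks,n_blank_features extraction blanks and the background
#'   features present in every blank (and a random subset of cultures).
#' @param p_blank_in_culture probability a blank feature also shows up in a
#'   given culture.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma log-scale mean /
#'   sd of per-feature characteristic peak areas.
#' @param isolate_sigma,replicate_sigma log-scale sd of isolate-level and
#'   replicate-level abundance variation around the feature mean.
#' @param n_scaffolds number of multi-member scaffold templates over which
#'   pool features are distributed (injected singletons get their own).
#' @param peaks_per_scaffold_range min/max fragment peaks per template.
#' @param max_shifted_peaks at most this many template peaks are shifted by
#'   the member's precursor offset.
#' @param fragment_noise_peaks low-intensity random peaks added per spectrum.
#' @param min_matched_peaks guaranteed number of alignable peaks between two
#'   members of the same scaffold; requires
#'   `min(peaks_per_scaffold_range) - 2 * max_shifted_peaks >= min_matched_peaks`.
#' @param cluster_geo_boxes list of `c(lon_min, lon_max, lat_min, lat_max)`
#'   per chemical cluster; isolates are placed uniformly inside their
#'   cluster's box (one cluster is range-restricted by default).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_clades = 5,
                             clade_sizes = c(111, 30, 25, 18, 14),
                             clade_names = c("U", "V", "W", "X", "Y"),
                             n_core_features = 30,
                             n_clade_features = c(150, 120, 80, 70, 100),
                             n_pairwise_shared_features = 60,
                             singleton_fraction = 0.18,
                             p_detect_core = 0.95,
                             p_detect_clade = 0.85,
                             hidden_split_clade = 2,
                             split_overlap = 0.05,
                             embedded_cluster_rate = 0.05,
                             embedded_donor_cluster = NULL,
                             embedded_into_clades = c(1, 4),
                             n_replicates_per_isolate = 2,
                             n_blanks = 6,
                             n_blank_features = 15,
                             p_blank_in_culture = 0.3,
                             abundance_lognormal_mu = 13,
                             abundance_lognormal_sigma = 1.5,
                             isolate_sigma = 0.4,
                             replicate_sigma = 0.2,
                             n_scaffolds = 180,
                             peaks_per_scaffold_range = c(12, 18),
                             max_shifted_peaks = 3,
                             fragment_noise_peaks = 2,
                             min_matched_peaks = 6,
                             cluster_geo_boxes = NULL,
                             seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$clade_sizes) != n_clades || length(cfg$n_clade_features) != n_clades)
    abort("clade_sizes and n_clade_features must have length n_clades",
          "infeasible-config")
  if (any(cfg$clade_sizes < 1)) abort("every clade needs >= 1 isolate", "infeasible-config")
  for (p in c("p_detect_core", "p_detect_clade"))
    if (cfg[[p]] <= 0 || cfg[[p]] > 1)
      abort(paste(p, "must be in (0, 1]"), "infeasible-config")
  if (singleton_fraction < 0 || singleton_fraction >= 1)
    abort("singleton_fraction must be in [0, 1)", "infeasible-config")
  if (hidden_split_clade < 1 || hidden_split_clade > n_clades)
    abort("hidden_split_clade out of range", "infeasible-config")
  if (any(embedded_into_clades < 1 | embedded_into_clades > n_clades))
    abort("embedded_into_clades out of range", "infeasible-config")
  if (peaks_per_scaffold_range[1] - 2 * max_shifted_peaks < min_matched_peaks)
    abort("peaks per scaffold too few to guarantee min_matched_peaks", "infeasible-config")
  cfg$embedded_donor_cluster <- embedded_donor_cluster %||% hidden_split_clade
  n_clusters <- n_clades + 1
  if (is.null(cluster_geo_boxes)) {
    full <- c(-125, -70, 25, 49)
    cfg$cluster_geo_boxes <- rep(list(full), n_clusters)
    cfg$cluster_geo_boxes[[min(5, n_clusters)]] <- c(-125, -110, 30, 49)
  }
  if (length(cfg$cluster_geo_boxes) != n_clusters)
    abort("need one geo box per chemical cluster", "infeasible-config")
  structure(cfg, class = "generator_config")
}

# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic isolate collection with ground truth
#'
#' Simulates the full data bundle analyzed by the pipeline: an aligned
#' feature table (one column per replicate culture and per blank, raw peak
#' areas), sample metadata with clade labels and geography, MS/MS spectra
#' for every non-blank feature, and the generator's bookkeeping
#' (per-feature category and scaffold, per-isolate true chemotype) for
#' recovery tests.
#'
#' Each isolate detects the core pool and its chemotype's pools by
#' independent Bernoulli draws; abundances are log-normal around per-feature
#' characteristic levels with isolate- and replicate-level variation;
#' singleton features (present in exactly one isolate) are injected until
#' their realized fraction matches `singleton_fraction` to within one
#' feature; blank-background features appear in every blank and a random
#' subset of cultures.
#'
#' @param config a [generator_config()].
#' @return list with elements `feature_table` ([feature_table()]),
#'   `metadata` (data.frame), `spectra` (`spectrum_set`), `ground_truth`
#'   (list: `features`, `isolates`, `scaffold_templates`, `config`).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_iso <- sum(config$clade_sizes)
    iso_id <- sprintf("ISO%03d", seq_len(n_iso))
    clade_idx <- rep(seq_len(config$n_clades), config$clade_sizes)
    clade <- config$clade_names[clade_idx]
    K <- config$n_clades + 1          # true number of chemotypes

    # chemotype assignment: clade index, except the hidden split clade whose
    # isolates alternate between chemotypes (s, K); embedded isolates in the
    # designated clades are swapped to the donor chemotype
    s <- config$hidden_split_clade
    cluster <- clade_idx
    in_split <- which(clade_idx == s)
    cluster[in_split[seq_along(in_split) %% 2 == 0]] <- K
    eligible <- which(clade_idx %in% config$embedded_into_clades & clade_idx != s)
    swapped <- eligible[stats::runif(length(eligible)) < config$embedded_cluster_rate]
    cluster[swapped] <- config$embedded_donor_cluster

    # feature pools --------------------------------------------------------
    cat_core <- rep("core", config$n_core_features)
    cat_clade <- character(0); pool_owner <- list()
    # chemotype-level ownership of clade pools; the split clade's pool is
    # divided into two chemotype-private halves plus a shared slice
    owner_sets <- list()
    for (i in seq_len(config$n_clades)) {
      ni <- config$n_clade_features[i]
      if (i == s) {
        n_sh <- round(config$split_overlap * ni)
        n_a <- floor((ni - n_sh) / 2); n_b <- ni - n_sh - n_a
        owner_sets <- c(owner_sets, rep(list(s), n_a), rep(list(K), n_b),
                        rep(list(c(s, K)), n_sh))
      } else {
        owner_sets <- c(owner_sets, rep(list(i), ni))
      }
      cat_clade <- c(cat_clade,
                     rep(paste0("clade_specific:", config$clade_names[i]), ni))
    }
    n_pool <- length(cat_clade)
    # pairwise-shared pools: random unordered clade pairs
    prs <- if (config$n_pairwise_shared_features > 0)
      t(replicate(config$n_pairwise_shared_features,
                  sort(sample.int(config$n_clades, 2))))
    else matrix(integer(0), 0, 2)
    cat_pair <- paste0("pairwise_shared:", config$clade_names[prs[, 1]], "-",
                       config$clade_names[prs[, 2]])

    categories <- c(cat_core, cat_clade, cat_pair)
    n_feat0 <- length(categories)

    # chemotype home clade: which clade's pairwise pools a chemotype expresses
    home_clade <- c(seq_len(config$n_clades), s)

    # incidence simulation (isolate level) ---------------------------------
    inc <- matrix(0L, n_feat0, n_iso)
    core_rows <- seq_len(config$n_core_features)
    inc[core_rows, ] <- (stats::runif(length(core_rows) * n_iso) <
                           config$p_detect_core) * 1L
    for (f in seq_len(n_pool)) {
      row <- config$n_core_features + f
      own <- owner_sets[[f]]
      cols <- which(cluster %in% own)
      inc[row, cols] <- (stats::runif(length(cols)) < config$p_detect_clade) * 1L
    }
    for (f in seq_len(config$n_pairwise_shared_features)) {
      row <- config$n_core_features + n_pool + f
      cols <- which(home_clade[cluster] %in% prs[f, ])
      inc[row, cols] <- (stats::runif(length(cols)) < config$p_detect_clade) * 1L
    }

    # singleton injection to hit the configured fraction --------------------
    Ti <- rowSums(inc)
    S0 <- sum(Ti >= 1); a0 <- sum(Ti == 1)
    f_target <- config$singleton_fraction
    n_add <- round((f_target * S0 - a0) / (1 - f_target))
    if (n_add < 0)
      abort("singleton_fraction below the rate arising from detection noise",
            "infeasible-config")
    if (n_add > 0) {
      add <- matrix(0L, n_add, n_iso)
      add[cbind(seq_len(n_add), sample.int(n_iso, n_add, replace = TRUE))] <- 1L
      inc <- rbind(inc, add)
      categories <- c(categories, rep("singleton", n_add))
    }
    n_feat <- nrow(inc)

    # blank-background features ---------------------------------------------
    nb <- config$n_blank_features
    if (config$n_blanks > 0 && nb > 0) {
      blank_in_culture <- matrix(
        (stats::runif(nb * n_iso) < config$p_blank_in_culture) * 1L, nb, n_iso)
      inc <- rbind(inc, blank_in_culture)
      categories <- c(categories, rep("blank_artifact", nb))
    } else nb <- 0
    feature_id <- sprintf("FT%05d", seq_len(nrow(inc)))

    # scaffold assignment ----------------------------------------------------
    scaffold <- rep(NA_integer_, nrow(inc))
    pool_idx <- which(!categories %in% c("singleton", "blank_artifact"))
    scaffold[pool_idx] <- sample.int(config$n_scaffolds, length(pool_idx),
                                     replace = TRUE)
    singl_idx <- which(categories == "singleton")
    scaffold[singl_idx] <- config$n_scaffolds + seq_along(singl_idx)
    n_scaff_total <- config$n_scaffolds + length(singl_idx)

    # scaffold templates and feature m/z -------------------------------------
    lo <- config$peaks_per_scaffold_range[1]; hi <- config$peaks_per_scaffold_range[2]
    templates <- lapply(seq_len(n_scaff_total), function(sid) {
      base_mz <- stats::runif(1, 250, 850)
      k <- sample(lo:hi, 1)
      pk <- cbind(mz = sort(stats::runif(k, 50, base_mz - 30)),
                  intensity = stats::runif(k, 0.2, 1))
      list(scaffold_id = sid, base_mz = base_mz, peaks = pk)
    })
    mz <- numeric(nrow(inc)); rt <- stats::runif(nrow(inc), 0.5, 12)
    has_sc <- !is.na(scaffold)
    base <- vapply(scaffold[has_sc], function(sid) templates[[sid]]$base_mz, numeric(1))
    mz[has_sc] <- base + stats::runif(sum(has_sc), -25, 25)
    mz[!has_sc] <- stats::runif(sum(!has_sc), 150, 1000)

    # abundances --------------------------------------------------------------
    R <- config$n_replicates_per_isolate
    culture_id <- as.vector(t(outer(iso_id, seq_len(R),
                                    function(i, r) paste0(i, "_r", r))))
    culture_iso <- rep(iso_id, each = R)
    blank_id <- if (config$n_blanks > 0) paste0("BLANK_", seq_len(config$n_blanks))
                else character(0)
    feat_mu <- stats::rnorm(nrow(inc), config$abundance_lognormal_mu,
                            config$abundance_lognormal_sigma)
    ab <- matrix(0, nrow(inc), length(culture_id) + length(blank_id),
                 dimnames = list(feature_id, c(culture_id, blank_id)))
    pres <- which(inc == 1L, arr.ind = TRUE)
    iso_level <- feat_mu[pres[, 1]] + stats::rnorm(nrow(pres), 0, config$isolate_sigma)
    for (r in seq_len(R)) {
      cols <- (pres[, 2] - 1L) * R + r
      ab[cbind(pres[, 1], cols)] <-
        exp(iso_level + stats::rnorm(nrow(pres), 0, config$replicate_sigma))
    }
    if (config$n_blanks > 0 && nb > 0) {
      brows <- which(categories == "blank_artifact")
      for (b in seq_len(config$n_blanks))
        ab[brows, length(culture_id) + b] <-
          exp(stats::rnorm(nb, config$abundance_lognormal_mu - 2, 0.5))
    }

    # geography: uniform inside the isolate's chemotype bounding box ----------
    boxes <- config$cluster_geo_boxes
    lon <- lat <- numeric(n_iso)
    for (i in seq_len(n_iso)) {
      bx <- boxes[[cluster[i]]]
      lon[i] <- stats::runif(1, bx[1], bx[2]); lat[i] <- stats::runif(1, bx[3], bx[4])
    }

    metadata <- data.frame(
      sample_id = c(culture_id, blank_id),
      isolate_id = c(culture_iso, rep(NA_character_, length(blank_id))),
      clade = c(clade[match(culture_iso, iso_id)], rep(NA_character_, length(blank_id))),
      replicate = c(rep(seq_len(R), times = n_iso), rep(NA_integer_, length(blank_id))),
      is_blank = c(rep(FALSE, length(culture_id)), rep(TRUE, length(blank_id))),
      lon = c(lon[match(culture_iso, iso_id)], rep(NA_real_, length(blank_id))),
      lat = c(lat[match(culture_iso, iso_id)], rep(NA_real_, length(blank_id))),
      stringsAsFactors = FALSE)

    ground_truth <- list(
      features = data.frame(feature_id = feature_id, category = categories,
                            scaffold_id = scaffold, stringsAsFactors = FALSE),
      isolates = data.frame(isolate_id = iso_id, clade = clade,
                            true_cluster = cluster, lon = lon, lat = lat,
                            stringsAsFactors = FALSE),
      scaffold_templates = templates,
      config = config)

    ft <- feature_table(ab, mz = mz, rt = rt, feature_id = feature_id)
    ground_truth$features$mz <- mz
    spectra <- generate_spectra(ground_truth, config)
    list(feature_table = ft, metadata = metadata, spectra = spectra,
         ground_truth = ground_truth)
  })
}

#' Generate scaffold-structured MS/MS spectra
#'
#' Every non-blank feature receives its scaffold's template fragment
#' spectrum with the member's precursor offset (feature m/z minus the
#' scaffold base m/z) applied to a small random subset of peaks, plus a few
#' low-intensity noise peaks. Because at most `max_shifted_peaks` peaks are
#' shifted per member, two members of the same scaffold are guaranteed at
#' least `min_matched_peaks` alignable peaks under shift-aware (modified
#' cosine) matching; members of different scaffolds share no template peaks.
#'
#' @param ground_truth the `ground_truth` element of [generate_dataset()]
#'   output (scaffold templates must be assigned).
#' @param config the [generator_config()] used.
#' @return list of class `spectrum_set`; each element has `feature_id`,
#'   `precursor_mz`, and a two-column `peaks` matrix (mz, intensity) sorted
#'   by m/z.
#' @export
generate_spectra <- function(ground_truth, config) {
  feats <- ground_truth$features
  templates <- ground_truth$scaffold_templates
  if (is.null(templates)) abort("scaffold templates not assigned", "infeasible-config")
  idx <- which(!is.na(feats$scaffold_id))
  out <- lapply(idx, function(i) {
    tpl <- templates[[feats$scaffold_id[i]]]
    pk <- tpl$peaks
    delta <- feats$mz[i] - tpl$base_mz
    n_shift <- sample(0:config$max_shifted_peaks, 1)
    if (n_shift > 0) {
      sh <- sample.int(nrow(pk), n_shift)
      pk[sh, 1] <- pk[sh, 1] + delta
    }
    if (config$fragment_noise_peaks > 0) {
      noise <- cbind(stats::runif(config$fragment_noise_peaks, 50, feats$mz[i] - 10),
                     stats::runif(config$fragment_noise_peaks, 0.01, 0.05))
      pk <- rbind(pk, noise)
    }
    pk <- pk[pk[, 1] > 0, , drop = FALSE]
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    colnames(pk) <- c("mz", "intensity")
    list(feature_id = feats$feature_id[i], precursor_mz = feats$mz[i], peaks = pk)
  })
  names(out) <- feats$feature_id[idx]
  class(out) <- "spectrum_set"
  out
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra\n", length(x)))
  invisible(x)
}

#' @export
`[.spectrum_set` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "spectrum_set"
  out
}

#' Write the synthetic bundle to disk
#'
#' Writes the feature table (MZmine aligned-export CSV), metadata TSV,
#' spectra MGF, and ground-truth TSVs into a directory.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(dataset$feature_table, file.path(dir, "features.csv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_mgf(dataset$spectra, file.path(dir, "spectra.mgf"))
  utils::write.table(dataset$ground_truth$features,
                     file.path(dir, "ground_truth_features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$ground_truth$isolates,
                     file.path(dir, "ground_truth_isolates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
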