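test_that("generator configuration validates its invariants", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(clade_sizes = c(10, 10)), class = "chemcov_infeasible-config")
  expect_error(generator_config(p_detect_core = 0), class = "chemcov_infeasible-config")
  expect_error(generator_config(singleton_fraction = 1), class = "chemcov_infeasible-config")
  expect_error(generator_config(clade_sizes = c(111, 30, 25, 18, 0)),
               class = "chemcov_infeasible-config")
  expect_error(generator_config(peaks_per_scaffold_range = c(6, 10),
                                max_shifted_peaks = 3, min_matched_peaks = 6),
               class = "chemcov_infeasible-config")
})

test_that("a fixed seed yields identical datasets and leaves the RNG alone", {
  cfg <- small_config(seed = 7)
  set.seed(99); before <- runif(1)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$feature_table$abundance, d2$feature_table$abundance)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$ground_truth$features, d2$ground_truth$features)
  expect_identical(d1$spectra, d2$spectra)
  set.seed(99); expect_identical(runif(1), before)
})

test_that("degenerate parameters give a deterministic block structure", {
  cfg <- small_config(singleton_fraction = 0, n_blanks = 0, n_blank_features = 0,
                      p_detect_core = 1, p_detect_clade = 1,
                      embedded_cluster_rate = 0)
  d <- generate_dataset(cfg)
  inc <- preprocess(d$feature_table, d$metadata)$incidence
  # every feature present in at least two isolates (no singletons possible)
  expect_true(all(inc$Ti >= 2))
  expect_equal(inc$Q1, 0)
  # core features are present in every isolate
  gt <- d$ground_truth$features
  core <- gt$feature_id[gt$category == "core"]
  expect_true(all(inc$incidence[core, ] == 1))
})

test_that("realized singleton fraction hits the configured target", {
  d <- generate_dataset(generator_config(seed = 7))
  inc <- preprocess(d$feature_table, d$metadata)$incidence
  expect_equal(inc$Q1 / inc$S_obs, 0.18, tolerance = 0.01)
})

test_that("ground-truth bookkeeping is complete and consistent", {
  d <- generate_dataset(small_config())
  gt <- d$ground_truth
  expect_equal(nrow(gt$features), nrow(d$feature_table$abundance))
  # every feature has exactly one category
  expect_true(all(gt$features$category %in%
    c("core", "singleton", "blank_artifact",
      grep("^(clade_specific|pairwise_shared):", unique(gt$features$category),
           value = TRUE))))
  # every non-blank feature maps to exactly one scaffold
  nonblank <- gt$features$category != "blank_artifact"
  expect_true(all(!is.na(gt$features$scaffold_id[nonblank])))
  expect_true(all(is.na(gt$features$scaffold_id[!nonblank])))
  # spectra exist exactly for scaffold-assigned features
  expect_setequal(names(d$spectra), gt$features$feature_id[nonblank])
  # chemotype labels: split clade hosts two clusters, one cluster is embedded
  iso <- gt$isolates
  split_clades <- unique(iso$clade[iso$true_cluster == 4])  # K = n_clades + 1
  expect_equal(split_clades, "B")
  expect_gte(length(unique(iso$true_cluster[iso$clade == "B"])), 2)
})

test_that("replicate columns and blanks are laid out as configured", {
  cfg <- small_config()
  d <- generate_dataset(cfg)
  md <- d$metadata
  expect_equal(sum(!md$is_blank), sum(cfg$clade_sizes) * cfg$n_replicates_per_isolate)
  expect_equal(sum(md$is_blank), cfg$n_blanks)
  expect_equal(as.integer(table(md$isolate_id[!md$is_blank])),
               rep(cfg$n_replicates_per_isolate, sum(cfg$clade_sizes)))
  expect_true(all(is.na(md$clade[md$is_blank])))
})

test_that("isolates are placed inside their chemotype's bounding box", {
  cfg <- small_config()
  d <- generate_dataset(cfg)
  iso <- d$ground_truth$isolates
  for (cl in unique(iso$true_cluster)) {
    bx <- cfg$cluster_geo_boxes[[cl]]
    sub <- iso[iso$true_cluster == cl, ]
    expect_true(all(sub$lon >= bx[1] & sub$lon <= bx[2]))
    expect_true(all(sub$lat >= bx[3] & sub$lat <= bx[4]))
  }
})

test_that("same-scaffold spectra stay alignable, cross-scaffold spectra do not", {
  d <- generate_dataset(small_config(seed = 2))
  gt <- d$ground_truth$features
  cfg <- d$ground_truth$config
  sc_groups <- split(gt$feature_id[!is.na(gt$scaffold_id)],
                     gt$scaffold_id[!is.na(gt$scaffold_id)])
  multi <- sc_groups[lengths(sc_groups) >= 2][1:5]
  for (grp in multi) {
    res <- modified_cosine(d$spectra[[grp[1]]], d$spectra[[grp[2]]])
    expect_gte(unname(res["n_matched"]), cfg$min_matched_peaks)
    expect_gte(unname(res["score"]), 0.7)
  }
  # two features from different scaffolds share essentially nothing
  ids <- vapply(sc_groups[lengths(sc_groups) >= 1][1:10], `[`, character(1), 1)
  res <- modified_cosine(d$spectra[[ids[1]]], d$spectra[[ids[2]]])
  expect_lt(unname(res["score"]), 0.3)
})

test_that("the whole bundle round-trips through its writers and readers", {
  d <- generate_dataset(small_config())
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  ft <- read_feature_table(file.path(dir, "features.csv"))
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  sp <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_equal(ft$abundance, d$feature_table$abundance, tolerance = 1e-9)
  expect_equal(md$sample_id, d$metadata$sample_id)
  expect_equal(length(sp), length(d$spectra))
  gtf <- read.delim(file.path(dir, "ground_truth_features.tsv"))
  expect_equal(gtf$category, d$ground_truth$features$category)
})

test_that("infeasible singleton targets are rejected", {
  # one isolate per clade: every detected feature risks being a singleton,
  # so a zero singleton target cannot be met
  cfg <- generator_config(n_clades = 2, clade_sizes = c(1, 1),
                          clade_names = c("A", "B"),
                          n_core_features = 5, n_clade_features = c(10, 10),
                          n_pairwise_shared_features = 0,
                          singleton_fraction = 0, hidden_split_clade = 1,
                          embedded_into_clades = 1,
                          n_blanks = 0, n_blank_features = 0,
                          n_scaffolds = 10, seed = 1)
  expect_error(generate_dataset(cfg), class = "chemcov_infeasible-config")
})
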