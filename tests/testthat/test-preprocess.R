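make_toy_table <- function() {
  ab <- matrix(c(2, 3, 5,    # s1
                 0, 1, 4,    # s2
                 6, 0, 0),   # blank1: feature 1 contaminated
               nrow = 3,
               dimnames = list(NULL, c("s1", "s2", "blank1")))
  feature_table(ab, mz = c(100.1, 200.2, 300.3), rt = c(1, 2, 3))
}

toy_metadata <- data.frame(
  sample_id = c("s1", "s2", "blank1"),
  isolate_id = c("isoA", "isoA", NA),
  clade = c("U", "U", NA),
  replicate = c(1L, 2L, NA),
  is_blank = c(FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

test_that("feature table round-trips through the MZmine CSV dialect", {
  tab <- make_toy_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  header <- readLines(path, n = 1)
  expect_match(header, "row m/z")
  expect_match(header, "s1 Peak area")
  back <- read_feature_table(path)
  expect_equal(back$abundance, tab$abundance)
  expect_equal(back$features, tab$features)

  # synthetic bundle round-trip
  d <- generate_dataset(small_config())
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(d$feature_table, p2)
  back2 <- read_feature_table(p2)
  expect_equal(back2$abundance, d$feature_table$abundance, tolerance = 1e-9)
})

test_that("malformed tables are rejected with typed errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row ID,row m/z,row retention time,s1 Peak area",
               "1,100.5,1.2,50", "2,100.5,1.2,60"), path)
  expect_error(read_feature_table(path), class = "chemcov_malformed-table")
  writeLines(c("row ID,row m/z,row retention time,s1 Peak area",
               "1,100.5,1.2,oops"), path)
  expect_error(read_feature_table(path), class = "chemcov_parse-error")
  # sample column missing from metadata is caught downstream
  tab <- make_toy_table()
  md <- toy_metadata[1:2, ]
  expect_error(blank_filter(tab, md), class = "chemcov_bad-metadata")
})

test_that("blank filter removes any feature detected in a blank", {
  tab <- make_toy_table()
  out <- blank_filter(tab, toy_metadata)
  expect_equal(rownames(out$abundance), c("F2", "F3"))
  expect_equal(colnames(out$abundance), c("s1", "s2"))
  expect_equal(attr(out, "removed_features"), "F1")
  # idempotence: filtering again (no blanks left) warns and returns identity
  md2 <- toy_metadata[toy_metadata$sample_id %in% c("s1", "s2"), ]
  expect_warning(again <- blank_filter(out, md2), "no blank")
  expect_equal(again$abundance, out$abundance)
  # fold-change rescue keeps strongly culture-enriched features
  ab <- matrix(c(50, 3, 5,   0, 1, 4,   1, 0, 0), nrow = 3,
               dimnames = list(NULL, c("s1", "s2", "blank1")))
  tab2 <- feature_table(ab, mz = c(100.1, 200.2, 300.3), rt = 1:3)
  rescued <- blank_filter(tab2, toy_metadata, mode = "fold", fold = 3)
  expect_true("F1" %in% rownames(rescued$abundance))   # 50 >= 3 * 1
  strict <- blank_filter(tab2, toy_metadata, mode = "strict")
  expect_false("F1" %in% rownames(strict$abundance))
})

test_that("blank filter removes exactly the ground-truth blank artifacts", {
  d <- generate_dataset(small_config())
  filt <- blank_filter(d$feature_table, d$metadata)
  gt <- d$ground_truth$features
  expect_setequal(attr(filt, "removed_features"),
                  gt$feature_id[gt$category == "blank_artifact"])
})

test_that("TIC normalization makes every column sum to one and is idempotent", {
  tab <- feature_table(matrix(c(2, 3, 5), 3, 1, dimnames = list(NULL, "s1")),
                       mz = 1:3, rt = 1:3)
  norm <- tic_normalize(tab)
  expect_equal(unname(norm$abundance[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(tic_normalize(norm)$abundance, norm$abundance)
  set.seed(1)
  big <- feature_table(matrix(rexp(200), 20, 10), mz = 1:20, rt = 1:20)
  expect_equal(unname(colSums(tic_normalize(big)$abundance)), rep(1, 10),
               tolerance = 1e-12)
  zero <- feature_table(matrix(0, 2, 1), mz = 1:2, rt = 1:2)
  expect_error(tic_normalize(zero), class = "chemcov_empty-sample")
})

test_that("replicate merging averages or takes maxima per isolate", {
  ab <- matrix(c(0.2, 0, 0.4, 0.1), 2, 2,
               dimnames = list(NULL, c("s1", "s2")))
  tab <- feature_table(ab, mz = 1:2, rt = 1:2)
  md <- toy_metadata[1:2, ]
  m_mean <- merge_replicates(tab, md, "mean")
  expect_equal(unname(m_mean$abundance[, "isoA"]), c(0.3, 0.05))
  m_union <- merge_replicates(tab, md, "union")
  expect_equal(unname(m_union$abundance[, "isoA"]), c(0.4, 0.1))
  # identical replicates are unchanged under either mode
  same <- feature_table(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                               dimnames = list(NULL, c("s1", "s2"))),
                        mz = 1:2, rt = 1:2)
  expect_equal(unname(merge_replicates(same, md, "mean")$abundance[, 1]), c(0.5, 0.5))
  expect_equal(unname(merge_replicates(same, md, "union")$abundance[, 1]), c(0.5, 0.5))
})

test_that("binarization applies thresholds and is monotone in threshold", {
  tab <- feature_table(matrix(c(0, 1e-9, 0.3, 0.6), 4, 1,
                              dimnames = list(NULL, "i1")),
                       mz = 1:4, rt = 1:4)
  inc0 <- binarize(tab, 0)
  expect_equal(unname(inc0$incidence[, 1]), c(1, 1, 1))   # zero row dropped
  expect_equal(attr(inc0, "n_dropped"), 1L)
  inc5 <- binarize(tab, 0.5)
  expect_equal(rownames(inc5$incidence), "F4")
  # presence set shrinks as the threshold rises
  set.seed(8)
  big <- feature_table(matrix(runif(100), 20, 5), mz = 1:20, rt = 1:20)
  for (pair in list(c(0.2, 0.5), c(0.1, 0.9))) {
    lo <- binarize(big, pair[1]); hi <- binarize(big, pair[2])
    common <- intersect(rownames(lo$incidence), rownames(hi$incidence))
    expect_true(all(lo$incidence[common, ] >= hi$incidence[common, ]))
  }
})

test_that("full preprocessing recovers ground-truth feature counts", {
  d <- generate_dataset(small_config())
  pp <- preprocess(d$feature_table, d$metadata)
  gt <- d$ground_truth$features
  realized <- table(factor(gt$category != "blank_artifact", c(FALSE, TRUE)))
  # S_obs equals the number of non-blank features actually detected somewhere
  expect_equal(pp$incidence$S_obs, sum(gt$category != "blank_artifact"))
  # columns sum to one after mean merge + renormalization
  expect_equal(unname(colSums(pp$normalized$abundance)),
               rep(1, ncol(pp$normalized$abundance)), tolerance = 1e-12)
  # groups carried through
  expect_equal(sort(unique(pp$incidence$groups)), c("A", "B", "C"))
})

test_that("metadata TSV round-trips", {
  d <- generate_dataset(small_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(d$metadata, path)
  back <- read_metadata(path)
  expect_equal(back$sample_id, d$metadata$sample_id)
  expect_equal(back$is_blank, d$metadata$is_blank)
  expect_equal(back$lon, d$metadata$lon, tolerance = 1e-9)
})
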