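# shared fixtures, all built in code

# 4-isolate, 5-feature toy with incidence frequencies (1, 2, 4, 2, 1):
# Q1 = 2, Q2 = 2, S_obs = 5; E[S(2)] = 5 - 8/6 by exhaustive enumeration
toy_incidence <- function(groups = NULL) {
  m <- rbind(f1 = c(1, 0, 0, 0),
             f2 = c(1, 1, 0, 0),
             f3 = c(1, 1, 1, 1),
             f4 = c(0, 0, 1, 1),
             f5 = c(0, 0, 0, 1))
  colnames(m) <- paste0("iso", 1:4)
  incidence_matrix(m, groups = groups)
}

# random 0/1 matrix with no empty rows, for property tests
random_incidence <- function(S, T, p = 0.4) {
  m <- matrix(rbinom(S * T, 1, p), S, T)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(T, sum(empty), replace = TRUE))] <- 1L
  incidence_matrix(m)
}

# brute-force rarefaction oracle: average distinct-feature count over every
# size-t subset of isolates (feasible for T <= 8)
exhaustive_rarefaction <- function(inc, t) {
  mat <- inc$incidence
  subsets <- utils::combn(inc$T, t)
  mean(apply(subsets, 2, function(cols)
    sum(rowSums(mat[, cols, drop = FALSE]) > 0)))
}

spec_spectrum <- function(mz, intensity, precursor, id = "S") {
  pk <- cbind(mz = mz, intensity = intensity)
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  list(feature_id = id, precursor_mz = precursor, peaks = pk)
}

# scaled-down generator configuration for fast unit tests
small_config <- function(seed = 11, ...) {
  args <- list(n_clades = 3, clade_sizes = c(20, 12, 8),
               clade_names = c("A", "B", "C"),
               n_core_features = 10,
               n_clade_features = c(40, 30, 25),
               n_pairwise_shared_features = 10,
               hidden_split_clade = 2, embedded_into_clades = c(1, 3),
               n_blanks = 2, n_blank_features = 5,
               n_scaffolds = 30,
               seed = seed)
  do.call(generator_config, utils::modifyList(args, list(...)))
}
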