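#' Observed chemical richness per isolate
#'
#' Number of items (features or scaffolds) detected in each isolate, i.e.
#' the column sums of the incidence matrix.
#'
#' @param incidence an [incidence_matrix()].
#' @return named integer vector of per-isolate richness.
#' @export
alpha_richness <- function(incidence) {
  colSums(incidence$incidence)
}

#' Compare richness across groups (ANOVA + Tukey HSD)
#'
#' One-way ANOVA of per-isolate richness by group, followed by all pairwise
#' Tukey honestly-significant-difference comparisons. Unequal group sizes
#' use Tukey-Kramer standard errors `sqrt((MSW/2) (1/n_i + 1/n_j))`; each
#' pair's studentized-range statistic `q = |diff| / se` is referred to the
#' studentized range distribution with `k` groups and the residual degrees
#' of freedom.
#'
#' @param richness numeric vector of per-isolate richness.
#' @param groups group label per isolate (>= 2 groups of >= 2 members).
#' @return list of class `richness_summary`: `summary` (per-group n, median,
#'   quartiles), `anova_F`, `anova_p`, `df`, `tukey` (data.frame: pair,
#'   diff, q, p_adj).
#' @export
compare_richness <- function(richness, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least two groups", "bad-argument")
  if (any(table(groups) < 2)) abort("every group needs >= 2 members", "bad-argument")
  if (all(tapply(richness, groups, stats::var) == 0))
    abort("zero within-group variance everywhere", "degenerate-anova")
  fit <- stats::aov(richness ~ groups)
  tab <- stats::anova(fit)
  msw <- tab["Residuals", "Mean Sq"]
  Fv <- tab["groups", "F value"]
  pv <- tab["groups", "Pr(>F)"]
  th <- stats::TukeyHSD(fit)$groups
  ns <- table(groups)
  means <- tapply(richness, groups, mean)
  pairs <- strsplit(rownames(th), "-", fixed = TRUE)
  q <- vapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    se <- sqrt((msw / 2) * (1 / ns[[a]] + 1 / ns[[b]]))
    abs(means[[a]] - means[[b]]) / se
  }, numeric(1))
  qs <- tapply(richness, groups, function(v)
    stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
  summ <- data.frame(group = levels(groups), n = as.integer(ns),
                     q1 = vapply(qs, `[`, numeric(1), 1),
                     median = vapply(qs, `[`, numeric(1), 2),
                     q3 = vapply(qs, `[`, numeric(1), 3),
                     row.names = NULL)
  structure(list(summary = summ, anova_F = Fv, anova_p = pv,
                 df = unname(tab$Df),
                 tukey = data.frame(pair = rownames(th), diff = th[, "diff"],
                                    q = q, p_adj = th[, "p adj"],
                                    row.names = NULL)),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$anova_F, x$anova_p))
  print(x$summary)
  invisible(x)
}

#' Balanced subsampling of isolates within groups
#'
#' Draws exactly `n` isolates without replacement from every group with at
#' least `n` members; smaller groups are kept whole (with a warning), which
#' mirrors subsampling only the larger clades to equalize sample sizes.
#'
#' @param incidence an [incidence_matrix()] with group labels.
#' @param n target number of isolates per group.
#' @param seed optional integer seed; caller's RNG state is preserved.
#' @return a new [incidence_matrix()] restricted to the sampled isolates.
#' @export
balanced_subsample <- function(incidence, n, seed = NULL) {
  n <- stopifnot_scalar_count(n, "n")
  if (n < 1) abort("n must be >= 1", "bad-argument")
  if (is.null(incidence$groups)) abort("incidence matrix has no group labels", "bad-argument")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  keep <- unlist(lapply(split(names(incidence$groups), incidence$groups), function(ids) {
    if (length(ids) <= n) {
      if (length(ids) < n)
        warning(sprintf("group with %d isolates kept whole (n = %d)", length(ids), n))
      ids
    } else sample(ids, n)
  }), use.names = FALSE)
  subset_units(incidence, keep[order(match(keep, colnames(incidence$incidence)))])
}

#' Exact sample-based rarefaction
#'
#' Expected number of distinct items among a random subset of `t` isolates:
#' `E[S(t)] = S_obs - sum_i C(T - T_i, t) / C(T, t)`, the exact
#' hypergeometric expectation over all size-`t` subsets (no resampling
#' noise). Binomial coefficients are evaluated in log space so `T` in the
#' hundreds is safe.
#'
#' @param incidence an [incidence_matrix()].
#' @param t integer vector of subset sizes, each in `1..T`.
#' @return numeric vector `E[S(t)]`.
#' @export
analytic_rarefaction <- function(incidence, t) {
  T <- incidence$T
  if (any(t < 1 | t > T)) abort("t must lie in 1..T", "bad-argument")
  Ti <- incidence$Ti
  vapply(as.integer(t), function(tt)
    incidence$S_obs - sum(lchoose_ratio(T - Ti, tt, T)), numeric(1))
}

#' Collector's and permutation-averaged accumulation curves
#'
#' In `order` mode, returns the cumulative count of distinct items along a
#' specific isolate ordering (a collector's curve: order-dependent, raw data
#' as entered). In `n_perm` mode, returns the mean curve over `n_perm`
#' seeded random orderings, which converges to the exact rarefaction curve.
#'
#' @param incidence an [incidence_matrix()].
#' @param order a permutation of isolate names or indices (collector mode).
#' @param n_perm number of random orderings to average (permutation mode).
#' @param seed optional integer seed for permutation mode.
#' @return data.frame of class `accumulation_curve`: `t`, `expected_richness`,
#'   `method` (`"collector"` or `"permutation_mean"`).
#' @export
collector_curve <- function(incidence, order = NULL, n_perm = NULL, seed = NULL) {
  mat <- incidence$incidence
  T <- incidence$T
  one_curve <- function(idx) {
    first <- max.col(mat[, idx, drop = FALSE], ties.method = "first")
    cumsum(tabulate(first, nbins = T))
  }
  if (!is.null(order)) {
    if (is.character(order)) order <- match(order, colnames(mat))
    if (anyNA(order) || !setequal(order, seq_len(T)))
      abort("order must be a permutation of the isolates", "bad-argument")
    curve <- one_curve(order)
    method <- "collector"
  } else {
    if (is.null(n_perm) || n_perm < 1)
      abort("give either `order` or `n_perm >= 1`", "bad-argument")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    acc <- numeric(T)
    for (i in seq_len(n_perm)) acc <- acc + one_curve(sample.int(T))
    curve <- acc / n_perm
    method <- "permutation_mean"
  }
  structure(data.frame(t = seq_len(T), expected_richness = curve, method = method),
            class = c("accumulation_curve", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' Chao2 estimate of unseen incidence-based richness
#'
#' `Q0_hat = ((T-1)/T) Q1^2 / (2 Q2)` when duplicates exist, falling back to
#' the bias-corrected form `((T-1)/T) Q1 (Q1-1) / 2` when `Q2 = 0`.
#'
#' @param Q1 number of items seen in exactly one isolate ("uniques").
#' @param Q2 number of items seen in exactly two isolates ("duplicates").
#' @param T number of isolates (>= 2).
#' @return estimated number of unseen items.
#' @export
chao2_unseen <- function(Q1, Q2, T) {
  if (T < 2) abort("T must be >= 2", "bad-argument")
  if (Q1 < 0 || Q2 < 0) abort("Q1 and Q2 must be >= 0", "bad-argument")
  if (Q2 > 0) ((T - 1) / T) * Q1^2 / (2 * Q2)
  else ((T - 1) / T) * Q1 * (Q1 - 1) / 2
}

#' Extrapolated richness beyond the observed sample
#'
#' Expected richness after `t_star` additional isolates:
#' `S(T + t*) = S_obs + Q0_hat [1 - (1 - Q1 / (Q1 + T Q0_hat))^t*]`,
#' approaching the Chao2 asymptote `S_obs + Q0_hat` as `t*` grows; returns
#' `S_obs` exactly when nothing unseen is estimated.
#'
#' @param incidence an [incidence_matrix()].
#' @param t_star nonnegative integer vector of additional isolates.
#' @return numeric vector of extrapolated richness values.
#' @export
extrapolate_richness <- function(incidence, t_star) {
  if (any(t_star < 0)) abort("t_star must be >= 0", "bad-argument")
  Q1 <- incidence$Q1
  q0 <- chao2_unseen(Q1, incidence$Q2, incidence$T)
  if (q0 == 0) return(rep(incidence$S_obs, length(t_star)))
  incidence$S_obs + q0 * (1 - (1 - Q1 / (Q1 + incidence$T * q0))^t_star)
}

#' Combined interpolated + extrapolated accumulation curve
#'
#' Exact rarefaction for `t = 1..T` and Chao2-based extrapolation out to
#' `endpoint` isolates.
#'
#' @param incidence an [incidence_matrix()].
#' @param endpoint total number of isolates at the end of the extrapolated
#'   segment (default 500); values `<= T` give the interpolated curve only.
#' @return data.frame of class `accumulation_curve`: `t`,
#'   `expected_richness`, `method` (`"interpolated"`/`"extrapolated"`).
#' @export
accumulation_curve <- function(incidence, endpoint = 500) {
  T <- incidence$T
  interp <- data.frame(t = seq_len(T),
                       expected_richness = analytic_rarefaction(incidence, seq_len(T)),
                       method = "interpolated")
  out <- interp
  if (endpoint > T) {
    ts <- seq.int(T + 1, endpoint)
    out <- rbind(interp, data.frame(
      t = ts, expected_richness = extrapolate_richness(incidence, ts - T),
      method = "extrapolated"))
  }
  structure(out, class = c("accumulation_curve", "data.frame"))
}

#' Solve for isolate counts reaching target coverage fractions
#'
#' For each target fraction `p`, the smallest number of isolates `t` whose
#' expected rarefied richness reaches `p * S_obs` — coverage measured
#' against the observed total of the dataset (or group), not the estimated
#' asymptote.
#'
#' @param incidence an [incidence_matrix()].
#' @param fractions numeric vector of target fractions in `(0, 1]`.
#' @return data.frame: `fraction`, `n_isolates`, `expected_richness`.
#' @export
coverage_targets <- function(incidence, fractions = c(0.5, 0.75, 0.9, 0.95, 0.99)) {
  if (any(fractions <= 0 | fractions > 1))
    abort("fractions must lie in (0, 1]", "bad-argument")
  curve <- analytic_rarefaction(incidence, seq_len(incidence$T))
  tol <- 1e-9 * incidence$S_obs
  n <- vapply(fractions, function(p) {
    which(curve >= p * incidence$S_obs - tol)[1]
  }, integer(1))
  data.frame(fraction = fractions, n_isolates = n,
             expected_richness = curve[n])
}

#' Saturation slope at the end of the interpolated curve
#'
#' `E[S(T)] - E[S(T-1)]`, the expected gain from the final isolate, which
#' reduces exactly to `Q1 / T` (the per-isolate rate of still-unique items).
#' A slope near zero indicates the group's chemistry is close to saturation.
#'
#' @param incidence an [incidence_matrix()] with `T >= 2`.
#' @return the end slope (numeric scalar).
#' @export
end_slope <- function(incidence) {
  if (incidence$T < 2) abort("need T >= 2", "bad-argument")
  diff(analytic_rarefaction(incidence, c(incidence$T - 1, incidence$T)))
}

#' Per-group accumulation curves
#'
#' @param incidence an [incidence_matrix()] with group labels; each group's
#'   curve is computed on the sub-matrix of its isolates (items absent from
#'   the group are dropped).
#' @param endpoint extrapolation endpoint passed to [accumulation_curve()].
#' @return data.frame with an extra `group` column ("all" plus one per group).
#' @export
group_accumulation <- function(incidence, endpoint = 500) {
  res <- cbind(group = "all", accumulation_curve(incidence, endpoint))
  if (!is.null(incidence$groups)) {
    for (g in sort(unique(incidence$groups))) {
      sub <- subset_units(incidence, names(incidence$groups)[incidence$groups == g])
      res <- rbind(res, cbind(group = g, accumulation_curve(sub, endpoint)))
    }
  }
  res
}
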