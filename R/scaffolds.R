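#' Read / write MS/MS spectra in MGF format
#'
#' Minimal Mascot Generic Format dialect used by feature-based molecular
#' networking exports: one `BEGIN IONS`/`END IONS` block per spectrum with
#' `FEATURE_ID=` and `PEPMASS=` headers followed by `m/z intensity` peak
#' lines. Peaks are sorted by m/z on read.
#'
#' @param path MGF file path.
#' @return a `spectrum_set` (possibly empty).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    abort("unbalanced BEGIN IONS / END IONS blocks", "malformed-mgf")
  out <- vector("list", length(starts))
  ids <- character(length(starts))
  for (b in seq_along(starts)) {
    blk <- lines[(starts[b] + 1):(ends[b] - 1)]
    hdr <- grep("=", blk, fixed = TRUE, value = TRUE)
    kv <- strsplit(hdr, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    if (!"PEPMASS" %in% keys)
      abort(sprintf("spectrum block %d has no PEPMASS", b), "malformed-mgf")
    prec <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    fid <- if ("FEATURE_ID" %in% keys) trimws(vals[match("FEATURE_ID", keys)])
           else paste0("spectrum_", b)
    pk_lines <- blk[!grepl("=", blk, fixed = TRUE) & nzchar(trimws(blk))]
    pk <- if (length(pk_lines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
      m[order(m[, 1]), , drop = FALSE]
    } else matrix(numeric(0), 0, 2)
    colnames(pk) <- c("mz", "intensity")
    out[[b]] <- list(feature_id = fid, precursor_mz = prec, peaks = pk)
    ids[b] <- fid
  }
  names(out) <- ids
  class(out) <- "spectrum_set"
  out
}

#' @rdname read_mgf
#' @param spectra a `spectrum_set`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("FEATURE_ID=", sp$feature_id),
                 paste0("PEPMASS=", sprintf("%.10g", sp$precursor_mz)),
                 sprintf("%.10g %.10g", sp$peaks[, 1], sp$peaks[, 2]),
                 "END IONS", ""), con)
  }
  invisible(path)
}

# precompute normalized weight vector for a spectrum
.spec_weights <- function(intensity, weighting) {
  w <- if (weighting == "sqrt") sqrt(intensity) else intensity
  w / sqrt(sum(w^2))
}

# core scorer on prepared (mz, weight, precursor) triples
.mcosine <- function(mza, wa, pa, mzb, wb, pb, frag_tol) {
  delta <- pa - pb
  dm <- outer(mza, mzb, "-")
  cand <- abs(dm) <= frag_tol | abs(dm - delta) <= frag_tol
  if (!any(cand)) return(c(0, 0))
  ij <- which(cand, arr.ind = TRUE)
  prod <- wa[ij[, 1]] * wb[ij[, 2]]
  ord <- order(prod, decreasing = TRUE)
  used_a <- logical(length(mza)); used_b <- logical(length(mzb))
  score <- 0; n <- 0L
  for (k in ord) {
    i <- ij[k, 1]; j <- ij[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      score <- score + prod[k]; n <- n + 1L
    }
  }
  c(min(score, 1), n)
}

#' Modified cosine similarity between two spectra
#'
#' Shift-aware spectral similarity used by molecular networking: fragment
#' peaks may match either directly (`|mz_a - mz_b| <= frag_tol`) or offset
#' by the precursor mass difference (`|mz_a - mz_b - (prec_a - prec_b)| <=
#' frag_tol`), so structural analogs differing by one modification still
#' align. Peak intensities are square-root transformed (or used raw) and
#' normalized per spectrum to unit length; candidate pairs are assigned
#' greedily one-to-one in descending intensity-product order. The score is
#' the sum of matched products, in `[0, 1]`.
#'
#' @param a,b spectra (lists with `precursor_mz` and a `peaks` matrix).
#' @param frag_tol fragment m/z tolerance in Da (default 0.02).
#' @param weighting `"sqrt"` (default) or `"raw"` intensity weighting.
#' @return named numeric vector `c(score, n_matched)`.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02, weighting = c("sqrt", "raw")) {
  weighting <- match.arg(weighting)
  if (frag_tol <= 0) abort("frag_tol must be > 0", "bad-argument")
  if (!nrow(a$peaks) || !nrow(b$peaks)) abort("empty spectrum", "bad-argument")
  res <- .mcosine(a$peaks[, 1], .spec_weights(a$peaks[, 2], weighting), a$precursor_mz,
                  b$peaks[, 1], .spec_weights(b$peaks[, 2], weighting), b$precursor_mz,
                  frag_tol)
  c(score = res[1], n_matched = res[2])
}

#' Build a molecular network from spectra
#'
#' Scores every spectrum pair by [modified_cosine()], keeps an edge when the
#' score reaches `min_cosine`, at least `min_matched` peak pairs align, and
#' each endpoint ranks the other within its `top_k` highest-scoring
#' partners (mutual top-K). Connected components of the resulting graph are
#' the scaffolds (molecular families); spectra with no qualifying edge form
#' singleton scaffolds.
#'
#' @param spectra a `spectrum_set`.
#' @param min_cosine minimum modified-cosine score (default 0.7).
#' @param min_matched minimum number of matched peaks (default 6).
#' @param top_k mutual rank cutoff (default 10).
#' @param frag_tol fragment tolerance in Da (default 0.02).
#' @param weighting intensity weighting, `"sqrt"` or `"raw"`.
#' @return list of class `molecular_network`: `nodes`, `edges` (data.frame:
#'   from, to, cosine, n_matched), `components` (named integer membership),
#'   `params`.
#' @export
build_network <- function(spectra, min_cosine = 0.7, min_matched = 6,
                          top_k = 10, frag_tol = 0.02,
                          weighting = c("sqrt", "raw")) {
  weighting <- match.arg(weighting)
  if (min_cosine <= 0 || min_matched < 1 || top_k < 1 || frag_tol <= 0)
    abort("network parameters must be positive", "bad-argument")
  n <- length(spectra)
  ids <- vapply(spectra, `[[`, character(1), "feature_id")
  mzs <- lapply(spectra, function(s) s$peaks[, 1])
  ws <- lapply(spectra, function(s) .spec_weights(s$peaks[, 2], weighting))
  precs <- vapply(spectra, `[[`, numeric(1), "precursor_mz")

  from <- to <- integer(0); sc <- nm <- numeric(0)
  if (n > 1) {
    buf_f <- buf_t <- integer(5000); buf_s <- buf_m <- numeric(5000); cnt <- 0L
    grow <- function() {
      buf_f <<- c(buf_f, integer(length(buf_f)))
      buf_t <<- c(buf_t, integer(length(buf_t)))
      buf_s <<- c(buf_s, numeric(length(buf_s)))
      buf_m <<- c(buf_m, numeric(length(buf_m)))
    }
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        r <- .mcosine(mzs[[i]], ws[[i]], precs[i], mzs[[j]], ws[[j]], precs[j],
                      frag_tol)
        if (r[1] >= min_cosine && r[2] >= min_matched) {
          cnt <- cnt + 1L
          if (cnt > length(buf_f)) grow()
          buf_f[cnt] <- i; buf_t[cnt] <- j; buf_s[cnt] <- r[1]; buf_m[cnt] <- r[2]
        }
      }
    }
    if (cnt > 0) {
      from <- buf_f[seq_len(cnt)]; to <- buf_t[seq_len(cnt)]
      sc <- buf_s[seq_len(cnt)]; nm <- buf_m[seq_len(cnt)]
      # mutual top-K filter: an edge survives iff it ranks within the top_k
      # strongest edges at both endpoints
      keep <- rep(TRUE, cnt)
      for (v in unique(c(from, to))) {
        inc_idx <- which(from == v | to == v)
        if (length(inc_idx) > top_k) {
          drop_idx <- inc_idx[order(sc[inc_idx], decreasing = TRUE)][-seq_len(top_k)]
          keep[drop_idx] <- FALSE
        }
      }
      from <- from[keep]; to <- to[keep]; sc <- sc[keep]; nm <- nm[keep]
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  names(comp) <- ids
  structure(list(
    nodes = ids,
    edges = data.frame(from = ids[from], to = ids[to], cosine = sc,
                       n_matched = nm, stringsAsFactors = FALSE),
    components = comp,
    params = list(min_cosine = min_cosine, min_matched = min_matched,
                  top_k = top_k, frag_tol = frag_tol, weighting = weighting)),
    class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  sizes <- table(x$components)
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d scaffolds (%d singletons)\n",
              length(x$nodes), nrow(x$edges), length(sizes), sum(sizes == 1)))
  invisible(x)
}

#' Scaffold assignment from a molecular network
#'
#' @param network a `molecular_network`.
#' @return data.frame: `feature_id`, `scaffold_id` (component label),
#'   `singleton` (component of size one).
#' @export
scaffold_assignment <- function(network) {
  sizes <- table(network$components)
  data.frame(feature_id = names(network$components),
             scaffold_id = as.integer(network$components),
             singleton = sizes[as.character(network$components)] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Project scaffold presence onto isolates
#'
#' A scaffold is present in an isolate when at least one of its member
#' features is present. Features in the incidence matrix without a network
#' node become singleton scaffolds of their own (orphans, with a warning).
#'
#' @param assignment data.frame from [scaffold_assignment()] (or a
#'   `molecular_network`).
#' @param feature_incidence a feature-level [incidence_matrix()].
#' @param drop_singletons remove scaffolds consisting of a single feature;
#'   the number removed is recorded in attribute `n_singletons_dropped`.
#' @return scaffold-level [incidence_matrix()] (rows named `SC<id>`).
#' @export
scaffold_incidence <- function(assignment, feature_incidence,
                               drop_singletons = FALSE) {
  if (inherits(assignment, "molecular_network"))
    assignment <- scaffold_assignment(assignment)
  mat <- feature_incidence$incidence
  idx <- match(rownames(mat), assignment$feature_id)
  scid <- assignment$scaffold_id[idx]
  if (anyNA(scid)) {
    warning(sprintf("%d features missing from the network; kept as singleton scaffolds",
                    sum(is.na(scid))))
    scid[is.na(scid)] <- max(assignment$scaffold_id, 0) + seq_len(sum(is.na(scid)))
  }
  agg <- rowsum((mat > 0) * 1L, group = scid)
  sc_mat <- (agg > 0) * 1L
  rownames(sc_mat) <- paste0("SC", rownames(agg))
  member_count <- as.vector(table(scid)[rownames(agg)])
  n_singl <- sum(member_count == 1)
  if (drop_singletons)
    sc_mat <- sc_mat[member_count > 1, , drop = FALSE]
  out <- incidence_matrix(sc_mat, groups = feature_incidence$groups)
  attr(out, "n_singletons_dropped") <- if (drop_singletons) n_singl else 0L
  attr(out, "n_singletons") <- n_singl
  out
}
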