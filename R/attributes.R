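BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_rows <- function(rows) {
  # rows: named character vector of (possibly gapped) sequences
  m <- t(vapply(strsplit(rows, "", fixed = TRUE), identity,
                character(nchar(rows[[1]]))))
  codes <- matrix(0L, nrow(m), ncol(m), dimnames = list(names(rows), NULL))
  for (b in names(BASE_CODE)) codes[m == b] <- BASE_CODE[[b]]
  codes
}

profile_from_codes <- function(codes) {
  # 5 x L counts (A,C,G,T,gap) from an integer-coded alignment matrix
  L <- ncol(codes)
  p <- matrix(0, 5, L)
  for (b in 1:4) p[b, ] <- colSums(codes == b)
  p[5, ] <- colSums(codes == 0L)
  p
}

#' Multiple sequence alignment of an intron set
#'
#' The builtin backend is a deterministic progressive aligner: a 3-mer
#' frequency distance matrix feeds an average-linkage guide clustering, and
#' profiles are merged by global (Needleman-Wunsch) profile alignment with
#' match +1, mismatch -1 and a linear gap penalty of -2 per site.  Gaps are
#' only ever inserted, so de-gapping any row recovers its input sequence
#' exactly.  The external backend shells out to an aligner such as
#' `mafft` and falls back to the builtin one (with a warning) when the
#' executable is unavailable.
#'
#' @param seqs Named character vector of at least 2 sequences.
#' @param method `"builtin"` or `"external"`.
#' @param external_cmd Executable name for the external backend.
#' @param match,mismatch,gap Builtin scoring parameters.
#' @return An `intron_msa`: list with `rows` (named gapped strings, input
#'   order) and `n_cols`.
#' @export
align_sequences <- function(seqs, method = c("builtin", "external"),
                            external_cmd = "mafft",
                            match = 1, mismatch = -1, gap = -2) {
  method <- match.arg(method)
  if (length(seqs) < 1L || is.null(names(seqs))) {
    stop("need a named character vector of sequences", call. = FALSE)
  }
  if (method == "external") {
    if (nzchar(Sys.which(external_cmd))) {
      return(align_external(seqs, external_cmd))
    }
    warning("external aligner '", external_cmd,
            "' not found; falling back to builtin progressive aligner")
  }
  align_builtin(seqs, match, mismatch, gap)
}

align_builtin <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  n <- length(seqs)
  if (n == 1L) return(new_msa(seqs))
  codes <- lapply(seqs, function(s) unname(BASE_CODE[as_base_vector(s)]))

  # guide clustering on 3-mer frequency distances
  kmer <- function(v) {
    if (length(v) < 3L) return(rep(0, 64))
    idx <- (v[1:(length(v) - 2)] - 1L) * 16L + (v[2:(length(v) - 1)] - 1L) * 4L + v[3:length(v)]
    tabulate(idx, 64) / (length(v) - 2L)
  }
  km <- t(vapply(codes, kmer, numeric(64)))
  hc <- stats::hclust(stats::dist(km), method = "average")

  # each cluster holds an integer-coded alignment matrix
  aln <- lapply(codes, function(v) matrix(v, nrow = 1))
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(id) if (id < 0) aln[[-id]] else merged[[id]]
    a <- pick(hc$merge[step, 1]); b <- pick(hc$merge[step, 2])
    path <- align_profiles_cpp(profile_from_codes(a), profile_from_codes(b),
                               match, mismatch, gap)
    L <- ncol(path)
    expand <- function(m, idx) {
      out <- matrix(0L, nrow(m), L)
      nz <- idx > 0L
      out[, nz] <- m[, idx[nz], drop = FALSE]
      rownames(out) <- rownames(m)
      out
    }
    rownames(a) <- rownames(a) %||% names(seqs)[-hc$merge[step, 1]]
    rownames(b) <- rownames(b) %||% names(seqs)[-hc$merge[step, 2]]
    merged[[step]] <- rbind(expand(a, path[1, ]), expand(b, path[2, ]))
  }
  final <- merged[[n - 1L]]
  final <- final[match(names(seqs), rownames(final)), , drop = FALSE]
  chars <- matrix("-", nrow(final), ncol(final))
  for (b in names(BASE_CODE)) chars[final == BASE_CODE[[b]]] <- b
  rows <- setNames(apply(chars, 1, paste0, collapse = ""), names(seqs))
  new_msa(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

align_external <- function(seqs, cmd) {
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(seqs, fin)
  args <- if (grepl("mafft", cmd)) c("--auto", "--quiet", fin) else fin
  res <- suppressWarnings(system2(cmd, args, stdout = fout, stderr = FALSE))
  if (res != 0L) stop("external aligner failed with status ", res, call. = FALSE)
  rows <- toupper(read_fasta(fout))
  new_msa(rows[names(seqs)])
}

new_msa <- function(rows) {
  nc <- unique(nchar(rows))
  stopifnot(length(nc) == 1L)
  structure(list(rows = rows, n_cols = nc), class = "intron_msa")
}

#' @export
print.intron_msa <- function(x, ...) {
  cat("<intron_msa> ", length(x$rows), " rows x ", x$n_cols, " columns\n", sep = "")
  invisible(x)
}

# --- Kimura two-parameter machinery ------------------------------------------

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 & w2 > 0
  d <- d_s <- d_v <- r <- rep(NA_real_, length(P))
  d[defined] <- -0.5 * log(w1[defined] * sqrt(w2[defined]))
  d_s[defined] <- -0.5 * log(w1[defined]) + 0.25 * log(w2[defined])
  d_v[defined] <- -0.5 * log(w2[defined])
  r[defined] <- d_s[defined] / d_v[defined]
  list(d = d, d_s = d_s, d_v = d_v, R = r, defined = defined)
}

#' Pairwise Kimura two-parameter statistics of two alignment rows
#'
#' Over the sites where both rows are ungapped, computes the transition
#' difference proportion `P`, the transversion proportion `Q`, the K2P
#' distance `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))` and the transition/
#' transversion ratio estimate `R_pair = d_s / d_v` with
#' `d_s = -1/2 ln(1-2P-Q) + 1/4 ln(1-2Q)` and `d_v = -1/2 ln(1-2Q)`.
#' The distance is undefined (NA, `defined = FALSE`) when the logs are
#' non-positive (saturated pair) or no sites are comparable.
#'
#' @param row_a,row_b Equal-length gapped sequence strings.
#' @return One-row tibble: `P`, `Q`, `n_sites`, `n_transitions`,
#'   `n_transversions`, `d`, `d_s`, `d_v`, `R_pair`, `defined`.
#' @export
pair_stats <- function(row_a, row_b) {
  stopifnot(nchar(row_a) == nchar(row_b))
  codes <- encode_rows(setNames(c(row_a, row_b), c("a", "b")))
  cnt <- pair_counts_cpp(codes)
  ns <- cnt[1, 3]; ts <- cnt[1, 4]; tv <- cnt[1, 5]
  P <- if (ns > 0) ts / ns else NA_real_
  Q <- if (ns > 0) tv / ns else NA_real_
  k <- if (ns > 0) k2p_from_pq(P, Q) else
    list(d = NA_real_, d_s = NA_real_, d_v = NA_real_, R = NA_real_, defined = FALSE)
  tibble::tibble(
    P = P, Q = Q, n_sites = as.integer(ns),
    n_transitions = as.integer(ts), n_transversions = as.integer(tv),
    d = k$d, d_s = k$d_s, d_v = k$d_v, R_pair = k$R, defined = isTRUE(k$defined)
  )
}

msa_pair_table <- function(msa, invariant_sites = FALSE) {
  codes <- encode_rows(msa$rows)
  cnt <- pair_counts_cpp(codes)
  ns <- cnt[, 3]
  if (invariant_sites) {
    # crude +I correction: discount the estimated invariant fraction of
    # comparable sites before converting counts to proportions
    full <- colSums(codes > 0L) >= 2L
    const <- full & apply(codes, 2, function(col) {
      v <- col[col > 0L]; length(unique(v)) == 1L
    })
    p_inv <- if (any(full)) sum(const) / sum(full) else 0
    ns_eff <- pmax(ns - round(p_inv * ns), cnt[, 4] + cnt[, 5])
  } else {
    ns_eff <- ns
  }
  P <- ifelse(ns_eff > 0, cnt[, 4] / ns_eff, NA_real_)
  Q <- ifelse(ns_eff > 0, cnt[, 5] / ns_eff, NA_real_)
  k <- k2p_from_pq(P, Q)
  nm <- names(msa$rows)
  tibble::tibble(
    id_a = nm[cnt[, 1]], id_b = nm[cnt[, 2]],
    n_sites = as.integer(ns), n_transitions = as.integer(cnt[, 4]),
    n_transversions = as.integer(cnt[, 5]),
    P = P, Q = Q, d = k$d, R_pair = k$R,
    defined = k$defined & !is.na(P)
  )
}

#' Overall mean distance and pooled transition/transversion ratio
#'
#' `Dbar` is the arithmetic mean of the K2P distance over all unordered row
#' pairs with a defined distance; saturated pairs are excluded and counted.
#' `R_K2I` pools the transition/transversion site counts over all pairs and
#' applies the K2P ratio formula to the pooled proportions (pooling is more
#' stable than averaging per-pair ratios when transversion distances are
#' near zero).
#'
#' @param msa An `intron_msa`.
#' @param invariant_sites Apply a simple invariant-sites discount before
#'   computing proportions.
#' @return List with `Dbar`, `R_K2I`, `n_pairs`, `n_excluded`, and the
#'   per-pair tibble `pairs`.
#' @export
overall_stats <- function(msa, invariant_sites = FALSE) {
  if (length(msa$rows) < 2L) stop("need at least 2 rows", call. = FALSE)
  pairs <- msa_pair_table(msa, invariant_sites)
  ok <- pairs$defined
  if (!any(ok)) stop("all pairwise distances are undefined (saturated alignment)", call. = FALSE)
  tot <- sum(pairs$n_sites)
  Ppool <- sum(pairs$n_transitions) / tot
  Qpool <- sum(pairs$n_transversions) / tot
  kp <- k2p_from_pq(Ppool, Qpool)
  list(
    Dbar = mean(pairs$d[ok]),
    R_K2I = kp$R,
    n_pairs = nrow(pairs),
    n_excluded = sum(!ok),
    pairs = pairs
  )
}

#' Bootstrap standard error of the overall mean distance
#'
#' Resamples alignment columns with replacement `reps` times, recomputes
#' `Dbar` on each replicate, and returns the sample standard deviation
#' across replicates.
#'
#' @inheritParams overall_stats
#' @param reps Bootstrap replicates (default 500).
#' @param seed Optional seed for the resampling.
#' @return The bootstrap standard error (numeric scalar).
#' @export
sed_bootstrap <- function(msa, reps = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
  L <- msa$n_cols
  if (L < 2L) {
    warning("degenerate single-column alignment; SE is 0")
    return(0)
  }
  codes <- encode_rows(msa$rows)
  ind <- pair_column_indicators_cpp(codes)
  np <- nrow(ind) / 3L
  cmp <- ind[seq_len(np), , drop = FALSE]
  ts <- ind[np + seq_len(np), , drop = FALSE]
  tv <- ind[2L * np + seq_len(np), , drop = FALSE]
  dbars <- vapply(seq_len(reps), function(i) {
    w <- tabulate(sample.int(L, L, replace = TRUE), L)
    n <- as.numeric(cmp %*% w)
    P <- ifelse(n > 0, as.numeric(ts %*% w) / n, NA_real_)
    Q <- ifelse(n > 0, as.numeric(tv %*% w) / n, NA_real_)
    d <- k2p_from_pq(P, Q)$d
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }, numeric(1))
  stats::sd(dbars, na.rm = TRUE)
}

# --- tree inference and the topology score -----------------------------------

#' Infer a tree from sequences or an alignment by neighbor-joining
#'
#' Computes the K2P distance matrix (pairwise deletion), imputes undefined
#' (saturated) distances as twice the maximum defined distance, runs
#' neighbor-joining, and clamps negative branch lengths to zero.  Input
#' order does not matter: rows are sorted by label before inference.
#'
#' @param x Named character vector of sequences, or an `intron_msa`.
#' @param ... Passed to [align_sequences()] when `x` is raw sequences.
#' @return A `guide_tree` (no backbone labels).
#' @export
infer_tree <- function(x, ...) {
  msa <- if (inherits(x, "intron_msa")) x else align_sequences(x, ...)
  if (length(msa$rows) < 4L) stop("need at least 4 sequences", call. = FALSE)
  pairs <- msa_pair_table(msa)
  nm <- sort(names(msa$rows))
  D <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  dmax <- max(pairs$d[pairs$defined], 0, na.rm = TRUE)
  fill <- ifelse(pairs$defined, pairs$d, 2 * dmax)
  for (i in seq_len(nrow(pairs))) {
    D[pairs$id_a[i], pairs$id_b[i]] <- fill[i]
    D[pairs$id_b[i], pairs$id_a[i]] <- fill[i]
  }
  nj_tree(D)
}

#' Neighbor-joining wrapper on a distance matrix
#' @param D Symmetric distance matrix with labeled rows.
#' @return A `guide_tree`.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 4L) stop("need at least 4 taxa for tree inference", call. = FALSE)
  ord <- sort(rownames(D))
  ph <- ape::nj(stats::as.dist(D[ord, ord]))
  ph$edge.length <- pmax(ph$edge.length, 0)
  new_guide_tree(ph)
}

#' Topology score of a test tree against a reference tree
#'
#' Both trees are ladderized (see [ladder_layout()]).  Each test leaf is
#' compared with its matched reference leaf: 1 point if the branch forms
#' agree and 1 point if the relative locations agree (the leaf directly
#' above the test leaf, mapped through the matching, equals the leaf
#' directly above the reference leaf; `TOP` only matches `TOP`).  The score
#' therefore lies in `[0, 2N]`, and any tree scored against itself yields
#' `2N`.
#'
#' @param test_tree,ref_tree `guide_tree`s (or `ladder_layout`s).
#' @param match Named character vector mapping test leaf labels to reference
#'   leaf labels; defaults to the identity on shared labels.  Must be a
#'   bijection.
#' @return Integer score with attribute `"breakdown"` (per-leaf tibble).
#' @export
#' @examples
#' tr <- fixture_tree(seed = 1)
#' topology_score(tr, tr)
topology_score <- function(test_tree, ref_tree, match = NULL) {
  lt <- if (inherits(test_tree, "ladder_layout")) test_tree else ladder_layout(test_tree)
  lr <- if (inherits(ref_tree, "ladder_layout")) ref_tree else ladder_layout(ref_tree)
  if (is.null(match)) {
    if (!setequal(lt$leaf, lr$leaf)) {
      stop("leaf label sets differ; supply an explicit match", call. = FALSE)
    }
    match <- setNames(lt$leaf, lt$leaf)
  }
  if (anyDuplicated(match) || anyDuplicated(names(match)) ||
      !setequal(names(match), lt$leaf) || !setequal(match, lr$leaf)) {
    stop("match must be a bijection between test and reference leaves", call. = FALSE)
  }
  map_above <- function(a) ifelse(a == "TOP", "TOP", unname(match[a]))
  ref_i <- match(unname(match[lt$leaf]), lr$leaf)
  form_pt <- as.integer(lt$form == lr$form[ref_i])
  loc_pt <- as.integer(map_above(lt$above) == lr$above[ref_i])
  breakdown <- tibble::tibble(
    leaf = lt$leaf, ref_leaf = lr$leaf[ref_i],
    form_test = lt$form, form_ref = lr$form[ref_i], form_point = form_pt,
    above_test = lt$above, above_ref = lr$above[ref_i], location_point = loc_pt
  )
  structure(sum(form_pt) + sum(loc_pt), breakdown = breakdown)
}

#' Compute the five attributes of a sequence set
#'
#' Composes the full evaluation pipeline: alignment (`L_MSA` = column
#' count), pooled K2P transition/transversion ratio (`R_K2I`), overall mean
#' distance (`Dbar`), its bootstrap standard error (`SEDbar`), and the
#' topology score (`TS_ML`) of the neighbor-joining tree of the set against
#' the reference tree.
#'
#' @param seqs Named character vector of sequences; names must match the
#'   reference tree's leaf labels.
#' @param ref_tree Reference `guide_tree`.
#' @param bootstrap_reps Bootstrap replicates for `SEDbar`.
#' @param aligner `"builtin"` or `"external"`.
#' @param seed Optional seed (bootstrap resampling).
#' @param invariant_sites Passed to [overall_stats()].
#' @return One-row tibble: `L_MSA`, `R_K2I`, `Dbar`, `SEDbar`, `TS_ML`,
#'   `n_undefined_pairs`.
#' @export
intron_attributes <- function(seqs, ref_tree, bootstrap_reps = 500L,
                              aligner = "builtin", seed = NULL,
                              invariant_sites = FALSE) {
  if (!setequal(names(seqs), ref_tree$phylo$tip.label)) {
    missing <- setdiff(ref_tree$phylo$tip.label, names(seqs))
    extra <- setdiff(names(seqs), ref_tree$phylo$tip.label)
    stop("sequence labels do not match reference tree leaves; missing: ",
         paste(missing, collapse = ","), "; extra: ",
         paste(extra, collapse = ","), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  msa <- align_sequences(seqs, method = aligner)
  ov <- overall_stats(msa, invariant_sites = invariant_sites)
  sed <- sed_bootstrap(msa, reps = bootstrap_reps)
  tr <- infer_tree(msa)
  ts <- topology_score(tr, ref_tree)
  tibble::tibble(
    L_MSA = msa$n_cols, R_K2I = ov$R_K2I, Dbar = ov$Dbar, SEDbar = sed,
    TS_ML = as.integer(ts), n_undefined_pairs = ov$n_excluded
  )
}
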