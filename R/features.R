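#' 2-D histogram of linkage coordinates
#'
#' Bins the `M - 1` linkage coordinates `(a_i, b_i)` of a hierarchy on an
#' `R x R` grid spanning the node-index range `(0, 2M - 1]`, with bin width
#' `eps = (2M - 1) / R` per axis. Intervals are left-open/right-closed:
#' coordinate `a` falls in row `j` (0-based) when `j*eps < a <= (j+1)*eps`.
#' Since node indices lie in `[1, 2M - 2]`, every coordinate falls in
#' exactly one bin. Counts are normalized by `M - 1`, so entries lie in
#' `[0, 1]` and sum to 1; the index condition `b > a` forces the strict
#' lower triangle to zero.
#'
#' Bin assignment is computed in exact integer arithmetic
#' (`ceil(a * R / (2M - 1)) - 1`), so the histogram is independent of
#' floating-point rounding.
#'
#' @param hier An [build_hierarchy()] result.
#' @param R Number of bins per axis (positive integer).
#' @param marginalize_leaves Replace the histogram by its expectation over
#'   uniform relabelings of the leaf indices. Leaf indices reflect the
#'   arbitrary row order of the input; the dendrogram itself does not, so
#'   this marginalization removes pure labelling noise while leaving all
#'   structural (internal-node) coordinates untouched. The result is
#'   additionally invariant under row permutation of the input. Default
#'   `FALSE`: bin the realized coordinates exactly.
#' @return An `R x R` numeric matrix of class `hlr_histogram`, with
#'   attributes `M` and `R`.
#' @examples
#' h <- build_hierarchy(matrix(c(0, 1, 10), ncol = 1), "single")
#' linkage_histogram(h, R = 5)
#' @export
linkage_histogram <- function(hier, R = 40, marginalize_leaves = FALSE) {
  stopifnot(inherits(hier, "hlr_hierarchy"))
  R <- as.integer(R)
  if (is.na(R) || R < 1L) abort("`R` must be a positive integer.")
  M <- hier$M
  q <- 2L * M - 1L
  bin0 <- function(v) {
    # 0-based bin: ceil(v*R / q) - 1, exact for integer v
    p <- as.numeric(v) * R
    (p + q - 1) %/% q - 1
  }
  a <- hier$merges$a
  b <- hier$merges$b
  if (!marginalize_leaves) {
    j <- bin0(a)
    k <- bin0(b)
    # column-major linear index of h[j+1, k+1]
    lin <- as.integer(k * R + j + 1)
    h <- matrix(tabulate(lin, nbins = R * R) / (M - 1L), R, R)
  } else {
    h <- matrix(0, R, R)
    # bin occupancy of the M leaf indices (1-based bins)
    leaf_counts <- tabulate(bin0(seq_len(M)) + 1L, R)
    leaf_prob <- leaf_counts / M
    a_leaf <- a <= M
    b_leaf <- b <= M
    # internal-internal: coordinates are labelling-invariant
    ii <- !a_leaf & !b_leaf
    if (any(ii)) {
      lin <- as.integer(bin0(b[ii]) * R + bin0(a[ii]) + 1)
      h <- h + matrix(tabulate(lin, nbins = R * R), R, R)
    }
    # leaf-internal: the leaf index is uniform on 1..M under relabelling
    li <- a_leaf & !b_leaf
    for (col in bin0(b[li]) + 1L) {
      h[, col] <- h[, col] + leaf_prob
    }
    # leaf-leaf: (min, max) of a uniform distinct pair from 1..M
    n_ll <- sum(a_leaf & b_leaf)
    if (n_ll > 0) {
      npairs <- M * (M - 1) / 2
      pair <- outer(leaf_counts, leaf_counts) # c_j * c_k
      pair[lower.tri(pair)] <- 0
      diag(pair) <- leaf_counts * (leaf_counts - 1) / 2
      h <- h + n_ll * pair / npairs
    }
    h <- h / (M - 1L)
  }
  structure(h, class = c("hlr_histogram", "matrix", "array"),
            M = M, R = R)
}

#' Unroll the upper triangle of a linkage histogram
#'
#' Flattens the diagonal-and-above entries of the `R x R` histogram into a
#' feature vector of length `R(R+1)/2`. The order is row-major over the
#' upper triangle: row `j = 1..R`, then column `k = j..R`; [unroll_index()]
#' documents the mapping and [reroll()] inverts it.
#'
#' @param h An `hlr_histogram` (or any square matrix).
#' @return Numeric vector of length `R(R+1)/2`.
#' @examples
#' length(unroll(matrix(0, 40, 40))) # 820
#' @export
unroll <- function(h) {
  stopifnot(is.matrix(h), nrow(h) == ncol(h))
  # row-major upper triangle of h == column-major lower triangle of t(h)
  t(h)[lower.tri(h, diag = TRUE)]
}

#' Upper-triangle unroll order
#'
#' @param R Bins per axis.
#' @return A tibble with columns `pos` (1-based position in the unrolled
#'   vector), `row` (`j`) and `col` (`k >= j`), both 1-based.
#' @export
unroll_index <- function(R) {
  R <- as.integer(R)
  if (is.na(R) || R < 1L) abort("`R` must be a positive integer.")
  row <- rep(seq_len(R), times = R - seq_len(R) + 1L)
  col <- unlist(lapply(seq_len(R), function(j) j:R))
  tibble(pos = seq_along(row), row = row, col = col)
}

#' Rebuild the histogram matrix from an unrolled feature vector
#'
#' Inverse of [unroll()]: reconstructs the upper triangle (the strict lower
#' triangle is zero by construction).
#'
#' @param f Feature vector of length `R(R+1)/2`.
#' @param R Bins per axis; inferred from `length(f)` when omitted.
#' @return An `R x R` matrix.
#' @export
reroll <- function(f, R = NULL) {
  if (is.null(R)) {
    R <- as.integer((sqrt(8 * length(f) + 1) - 1) / 2)
  }
  if (R * (R + 1) / 2 != length(f)) {
    abort("length(f) is not R(R+1)/2 for any integer R.")
  }
  h <- matrix(0, R, R)
  ht <- t(h)
  ht[lower.tri(ht, diag = TRUE)] <- f
  t(ht)
}

#' Featurize a point set for hierarchical linkage regression
#'
#' Convenience wrapper: builds the hierarchy, bins its linkage coordinates
#' and unrolls the upper triangle. The resulting feature vector depends only
#' on the merge order of the hierarchy, not on the magnitudes of the
#' distances, so it is invariant under translation and positive scaling of
#' the input.
#'
#' @inheritParams build_hierarchy
#' @inheritParams linkage_histogram
#' @param R Bins per axis of the linkage-coordinate histogram.
#' @return Numeric feature vector of length `R(R+1)/2`, entries in `[0, 1]`
#'   summing to 1.
#' @export
featurize <- function(points, R = 40,
                      linkage = c("complete", "single", "ward"),
                      metric = c("euclidean", "manhattan"),
                      standardize = FALSE, marginalize_leaves = FALSE) {
  unroll(linkage_histogram(
    build_hierarchy(points, linkage, metric, standardize = standardize), R,
    marginalize_leaves = marginalize_leaves))
}

#' Distance-only histogram (ablation featurizer)
#'
#' One-dimensional histogram of the `M - 1` merge heights of the same
#' hierarchy, binned uniformly on `(0, max(height)]` and normalized to sum
#' to 1. This baseline carries only distance-magnitude information — no
#' linkage structure — and exists to demonstrate that distance information
#' alone does not generalize across data scales. Zero heights (duplicate
#' points) land in the first bin; if every height is zero the whole mass is
#' in bin 1.
#'
#' @param points Numeric matrix or data frame (rows = samples), or an
#'   `hlr_hierarchy` already built.
#' @param nbins Number of bins (default 200).
#' @inheritParams build_hierarchy
#' @param source `"heights"` bins the `M - 1` merge heights (default);
#'   `"pairwise"` bins all `M(M-1)/2` pairwise point distances instead.
#' @param range_max Upper edge of the binning range. `NULL` (default) uses
#'   the per-instance maximum, which makes the histogram scale-free; a
#'   fixed value keeps absolute magnitudes comparable across instances
#'   (values beyond it are clamped into the last bin). Feature matrices
#'   built for regression fix this at the training corpus maximum so that
#'   the baseline actually carries magnitude information.
#' @return Numeric vector of length `nbins` summing to 1.
#' @export
distance_histogram <- function(points, nbins = 200,
                               linkage = c("complete", "single", "ward"),
                               metric = c("euclidean", "manhattan"),
                               source = c("heights", "pairwise"),
                               standardize = FALSE, range_max = NULL) {
  nbins <- as.integer(nbins)
  if (is.na(nbins) || nbins < 1L) abort("`nbins` must be a positive integer.")
  source <- match.arg(source)
  if (source == "pairwise") {
    params <- linkage_params(linkage, metric)
    X <- as_point_matrix(points)
    if (nrow(X) < 2L) abort("Need at least 2 points.")
    if (standardize) X <- scale(X)
    vals <- as.numeric(dist(X, method = params$metric))
  } else {
    hier <- if (inherits(points, "hlr_hierarchy")) points else
      build_hierarchy(points, linkage, metric, standardize = standardize)
    vals <- hier$merges$height
  }
  hmax <- range_max %||% max(vals)
  counts <- numeric(nbins)
  if (hmax <= 0) {
    counts[1L] <- length(vals)
  } else {
    idx <- pmin(pmax(ceiling(vals / (hmax / nbins)), 1L), nbins)
    tab <- tabulate(idx, nbins)
    counts <- as.numeric(tab)
  }
  counts / length(vals)
}
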