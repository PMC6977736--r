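#' Linkage parameters
#'
#' Bundles the linkage type and distance metric used to build an
#' agglomerative hierarchy. Ward's method is defined on the Euclidean norm
#' only, so requesting `ward` together with the Manhattan metric is an error.
#'
#' @param linkage One of `"complete"`, `"single"`, `"ward"`.
#' @param metric One of `"euclidean"` (L2) or `"manhattan"` (L1). The
#'   aliases `"l2"`/`"l1"` are accepted. Ignored-but-checked for Ward:
#'   anything other than Euclidean is rejected.
#' @return A list of class `hlr_linkage_params` with elements `linkage` and
#'   `metric`.
#' @examples
#' linkage_params("complete", "manhattan")
#' @export
linkage_params <- function(linkage = c("complete", "single", "ward"),
                           metric = c("euclidean", "manhattan")) {
  linkage <- match.arg(linkage)
  metric <- tolower(metric[1])
  metric <- switch(metric,
    l2 = "euclidean", euclidean = "euclidean",
    l1 = "manhattan", manhattan = "manhattan",
    abort(sprintf("Unknown metric '%s'; use 'euclidean'/'l2' or 'manhattan'/'l1'.", metric))
  )
  if (linkage == "ward" && metric != "euclidean") {
    abort("Ward linkage is defined on the Euclidean norm only; metric 'manhattan' is not allowed.")
  }
  structure(list(linkage = linkage, metric = metric),
            class = "hlr_linkage_params")
}

pairwise_norms <- function(A, B, metric) {
  # |A| x |B| matrix of Lk norms between rows of A and rows of B
  n <- nrow(A) + nrow(B)
  d <- as.matrix(dist(rbind(A, B), method = metric))
  d[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B)), drop = FALSE]
}

#' Set-to-set linkage distance
#'
#' Explicit set-to-set distance between two disjoint groups of points:
#' the minimum pairwise norm (single linkage), the maximum pairwise norm
#' (complete linkage), or Ward's variance-increase distance
#' `sqrt(2 * Na * Nb / (Na + Nb)) * ||centroid(A) - centroid(B)||_2`.
#' All three coincide for a pair of singletons.
#'
#' @param A,B Numeric matrices (rows = points) with the same number of
#'   columns; both non-empty.
#' @param linkage,metric Passed to [linkage_params()].
#' @param ward_sqrt Use the square-root (Lance-Williams-consistent) Ward
#'   prefactor (default). `FALSE` drops the square root over
#'   `2*Na*Nb/(Na+Nb)`; both readings agree on singleton merges.
#' @return A single non-negative number.
#' @examples
#' A <- rbind(c(0, 0), c(0, 2)); B <- rbind(c(5, 0), c(5, 2))
#' linkage_distance(A, B, "complete", "manhattan") # 7
#' linkage_distance(A, B, "ward")                  # sqrt(2) * 5
#' @export
linkage_distance <- function(A, B, linkage = c("complete", "single", "ward"),
                             metric = c("euclidean", "manhattan"),
                             ward_sqrt = TRUE) {
  params <- linkage_params(linkage, metric)
  A <- as_point_matrix(A, "A")
  B <- as_point_matrix(B, "B")
  if (nrow(A) < 1L || nrow(B) < 1L) abort("`A` and `B` must be non-empty.")
  if (ncol(A) != ncol(B)) abort("`A` and `B` must have the same dimensionality.")
  switch(params$linkage,
    single = min(pairwise_norms(A, B, params$metric)),
    complete = max(pairwise_norms(A, B, params$metric)),
    ward = {
      pre <- 2 * nrow(A) * nrow(B) / (nrow(A) + nrow(B))
      if (ward_sqrt) pre <- sqrt(pre)
      pre * sqrt(sum((colMeans(A) - colMeans(B))^2))
    }
  )
}

#' Build an agglomerative linkage hierarchy
#'
#' Agglomerates `M` points bottom-up under the chosen linkage and metric,
#' recording for the i-th merge the linkage coordinates `(a_i, b_i)` — the
#' node indices of the two children — and assigning the new node index
#' `M + i`. Leaves carry indices `1..M` in row order; the root is `2M - 1`.
#' Every child pair satisfies `1 <= a < b < 2M - 1` (the root node is never
#' a child).
#'
#' @param points Numeric matrix or data frame, rows = samples. `M >= 2`,
#'   all entries finite.
#' @inheritParams linkage_distance
#' @param standardize Optionally z-score each column before clustering
#'   (default `FALSE`: no implicit scaling is applied).
#' @return An object of class `hlr_hierarchy`: a list with `M`, `n` (input
#'   dimensionality), `merges`
#'   (a tibble with columns `a`, `b`, `node`, `height`, one row per merge,
#'   in construction order), `params`, and the underlying [stats::hclust]
#'   object (`hc`) for dendrogram export.
#' @examples
#' h <- build_hierarchy(matrix(c(0, 1, 10), ncol = 1), "single")
#' h$merges
#' @export
build_hierarchy <- function(points, linkage = c("complete", "single", "ward"),
                            metric = c("euclidean", "manhattan"),
                            standardize = FALSE) {
  params <- linkage_params(linkage, metric)
  X <- as_point_matrix(points)
  M <- nrow(X)
  if (M < 2L) abort("Need at least 2 points to build a hierarchy.")
  if (standardize) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    X <- scale(X, center = TRUE, scale = s)
  }
  method <- switch(params$linkage, single = "single", complete = "complete",
                   ward = "ward.D2")
  hc <- hclust(dist(X, method = params$metric), method = method)
  # hclust merge encoding: negative = leaf, positive = earlier merge row.
  child_index <- function(v) ifelse(v < 0, -v, M + v)
  a <- child_index(hc$merge[, 1L])
  b <- child_index(hc$merge[, 2L])
  merges <- tibble(
    a = as.integer(pmin(a, b)),
    b = as.integer(pmax(a, b)),
    node = M + seq_len(M - 1L),
    height = hc$height
  )
  structure(
    list(M = M, n = ncol(X), merges = merges, params = params,
         standardize = standardize, hc = hc),
    class = "hlr_hierarchy"
  )
}

#' @export
print.hlr_hierarchy <- function(x, ...) {
  cat(sprintf("<hlr_hierarchy> %d leaves, %s linkage, %s metric\n",
              x$M, x$params$linkage, x$params$metric))
  print(x$merges, ...)
  invisible(x)
}

#' Tidy a linkage hierarchy
#'
#' @param x An `hlr_hierarchy`.
#' @param ... Unused.
#' @return The merge table: a tibble with one row per merge and columns
#'   `a`, `b` (child node indices, `a < b`), `node` (index assigned to the
#'   merge, `M + i`) and `height` (merge distance).
#' @method tidy hlr_hierarchy
#' @export
tidy.hlr_hierarchy <- function(x, ...) x$merges

#' Write a hierarchy as a 4-column table
#'
#' @param hier An `hlr_hierarchy`.
#' @param path Output file; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hier, path) {
  stopifnot(inherits(hier, "hlr_hierarchy"))
  readr::write_tsv(hier$merges, path)
  invisible(path)
}

#' Export a hierarchy as a Newick string
#'
#' Converts the dendrogram to Newick for external tree viewers. Leaf labels
#' default to the row index (`1..M`).
#'
#' @param hier An `hlr_hierarchy`.
#' @param path Optional file to write to.
#' @param labels Optional character vector of `M` leaf labels.
#' @return The Newick string, invisibly if `path` is given.
#' @export
as_newick <- function(hier, path = NULL, labels = NULL) {
  stopifnot(inherits(hier, "hlr_hierarchy"))
  hc <- hier$hc
  hc$labels <- labels %||% as.character(seq_len(hier$M))
  phy <- ape::as.phylo(hc)
  out <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a numeric point matrix from a delimited file
#'
#' CSV/TSV reader for feature tables: rows = samples, columns = features.
#' The header row and delimiter are auto-detected unless given, and an
#' optional label column can be split off for evaluation.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect (non-numeric first
#'   line implies a header).
#' @param label_col Optional column name or index holding ground-truth
#'   labels; removed from the matrix and returned as the `labels` attribute.
#' @return A numeric matrix, with attribute `labels` when `label_col` is
#'   given.
#' @export
read_points <- function(path, delim = NULL, header = NA, label_col = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "hlreg_missing_file")
  }
  first <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    fields <- strsplit(first, delim, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- utils::read.table(path, sep = delim, header = header,
                          check.names = FALSE)
  labels <- NULL
  if (!is.null(label_col)) {
    idx <- if (is.character(label_col)) match(label_col, names(df)) else as.integer(label_col)
    if (is.na(idx) || idx < 1L || idx > ncol(df)) {
      abort(sprintf("label_col '%s' not found.", label_col))
    }
    labels <- df[[idx]]
    df <- df[-idx]
  }
  m <- as_point_matrix(df, path)
  if (!is.null(labels)) attr(m, "labels") <- labels
  m
}
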