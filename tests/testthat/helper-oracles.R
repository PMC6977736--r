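# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything from first principles (raw point
# memberships, direct counting) and share no code with the package paths
# they verify.

# Set-to-set distance recomputed from raw memberships.
oracle_set_distance <- function(X, members_a, members_b, linkage, metric) {
  D <- as.matrix(dist(X, method = metric))
  block <- D[members_a, members_b, drop = FALSE]
  if (linkage == "single") return(min(block))
  if (linkage == "complete") return(max(block))
  # ward: sqrt(2 Na Nb / (Na + Nb)) * euclidean centroid distance
  na <- length(members_a); nb <- length(members_b)
  ca <- colMeans(X[members_a, , drop = FALSE])
  cb <- colMeans(X[members_b, , drop = FALSE])
  sqrt(2 * na * nb / (na + nb)) * sqrt(sum((ca - cb)^2))
}

# Greedy agglomeration: at every step scan all active pairs (in lexicographic
# node-id order, strict < so the first minimal pair wins ties) and merge the
# closest. O(M^3)-ish; fine for M <= 12.
oracle_hierarchy <- function(X, linkage, metric) {
  M <- nrow(X)
  members <- lapply(seq_len(M), identity)
  names(members) <- as.character(seq_len(M))
  out <- data.frame(a = integer(0), b = integer(0), node = integer(0),
                    height = numeric(0))
  for (i in seq_len(M - 1L)) {
    ids <- sort(as.integer(names(members)))
    best <- NULL
    for (pi in seq_along(ids)[-length(ids)]) {
      for (qi in (pi + 1L):length(ids)) {
        p <- ids[pi]; q <- ids[qi]
        d <- oracle_set_distance(X, members[[as.character(p)]],
                                 members[[as.character(q)]], linkage, metric)
        if (is.null(best) || d < best$d) best <- list(p = p, q = q, d = d)
      }
    }
    node <- M + i
    out[i, ] <- list(best$p, best$q, node, best$d)
    members[[as.character(node)]] <-
      c(members[[as.character(best$p)]], members[[as.character(best$q)]])
    members[[as.character(best$p)]] <- NULL
    members[[as.character(best$q)]] <- NULL
  }
  out
}

linkage_metric_grid <- data.frame(
  linkage = c("single", "single", "complete", "complete", "ward"),
  metric = c("euclidean", "manhattan", "euclidean", "manhattan", "euclidean"),
  stringsAsFactors = FALSE
)

# Direct single-pass binning oracle for 1-D histograms on (0, max].
oracle_bin_1d <- function(values, nbins) {
  counts <- numeric(nbins)
  top <- max(values)
  if (top <= 0) {
    counts[1] <- length(values)
  } else {
    for (v in values) {
      b <- 1L
      while (b < nbins && v > b * top / nbins) b <- b + 1L
      counts[b] <- counts[b] + 1
    }
  }
  counts / length(values)
}

# Direct-counting metric oracles.
oracle_recall <- function(est, truth, delta) {
  hits <- 0
  for (i in seq_along(est)) if (abs(est[i] - truth[i]) <= delta) hits <- hits + 1
  hits / length(est)
}

oracle_f1_binary <- function(est, truth, delta, y) {
  tp <- fp <- fn <- 0
  for (i in seq_along(est)) {
    is_y <- truth[i] == y
    hit <- abs(est[i] - truth[i]) <= delta
    claimed <- abs(est[i] - y) <= delta
    near <- abs(truth[i] - y) <= delta
    if (is_y && hit) tp <- tp + 1
    if (is_y && !hit) fn <- fn + 1
    if (claimed && !near) fp <- fp + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

oracle_macro_f1 <- function(est, truth, delta, y_max) {
  mean(vapply(seq_len(y_max), function(y) oracle_f1_binary(est, truth, delta, y),
              numeric(1)))
}

# A constant-output model built by hand: all weights zero, output bias = value.
# Exercises the real predict()/rounding path with a known raw inference.
const_model <- function(value, p = 6, R = 3) {
  net <- list(
    W = list(matrix(0, 4, p), matrix(0, 2, 4), matrix(0, 1, 2)),
    b = list(numeric(4), numeric(2), value)
  )
  structure(list(
    net = net,
    config = list(hidden = c(4L, 2L), activation = "relu", beta = 0,
                  solver = "adam", seed = 1L),
    feature_spec = list(featurizer = "linkage", R = as.integer(R),
                        nbins = NULL, linkage = "complete",
                        metric = "euclidean", standardize = FALSE, d_E = 5L),
    curve = NULL,
    fit = list(train_cost = NA_real_, train_mse = NA_real_,
               val_mse = NA_real_)
  ), class = "hlr_model")
}
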