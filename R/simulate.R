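#' Synthetic cluster-generator configuration
#'
#' Describes the random-cluster model used to synthesize training data:
#' each instance holds `k` Gaussian clusters in `d_E` dimensions, the i-th
#' cluster being `z = c_i + v_i` with centroid `c_i` drawn uniformly per
#' dimension on `centroid_interval` and noise `v_i` zero-mean Gaussian with
#' a per-cluster, per-dimension standard deviation drawn uniformly from
#' `sigma_range`. Per-cluster point counts are drawn uniformly from
#' `size_range`. These defaults give a realistic mix of well-separated and
#' overlapping clusters; all values are recorded in output metadata.
#'
#' @param d_E Embedding dimension of the synthetic points. Must be at least
#'   the dimensionality of any dataset the trained model will score.
#' @param k_range Inclusive integer range of cluster counts per instance.
#' @param size_range Inclusive integer range of per-cluster point counts.
#' @param centroid_interval Numeric length-2: uniform bounds of the
#'   per-dimension centroid draw.
#' @param sigma_range Numeric length-2 (positive): uniform bounds of the
#'   per-cluster, per-dimension standard deviation.
#' @param seed Master RNG seed used by [generate_training_set()].
#' @return A list of class `hlr_config`.
#' @export
synthetic_config <- function(d_E = 50, k_range = c(1, 30),
                             size_range = c(50, 1000),
                             centroid_interval = c(0, 10),
                             sigma_range = c(0.25, 1), seed = 1L) {
  k_range <- as.integer(k_range)
  size_range <- as.integer(size_range)
  if (length(k_range) != 2L || k_range[1] < 1L || k_range[1] > k_range[2]) {
    abort("`k_range` must be an increasing integer pair with minimum >= 1.")
  }
  if (length(size_range) != 2L || size_range[1] < 2L ||
      size_range[1] > size_range[2]) {
    abort("`size_range` must be an increasing integer pair with minimum >= 2.")
  }
  if (length(centroid_interval) != 2L ||
      centroid_interval[1] >= centroid_interval[2]) {
    abort("`centroid_interval` must satisfy w1 < w2.")
  }
  if (length(sigma_range) != 2L || sigma_range[1] <= 0 ||
      sigma_range[1] > sigma_range[2]) {
    abort("`sigma_range` must be positive and non-decreasing.")
  }
  d_E <- as.integer(d_E)
  if (is.na(d_E) || d_E < 1L) abort("`d_E` must be a positive integer.")
  structure(list(d_E = d_E, k_range = k_range, size_range = size_range,
                 centroid_interval = centroid_interval,
                 sigma_range = sigma_range, seed = as.integer(seed)),
            class = "hlr_config")
}

# Uniform integer draw on [lo, hi] that is safe when lo == hi
# (sample(x, ...) would treat a scalar x as 1:x).
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Core sampler: draws sizes (via `sizes_draw()`), then cluster centroids,
# spreads and points, all inside one seeded RNG stream; rows shuffled so
# cluster membership never leaks through row order.
sample_instance <- function(sizes_draw, config, seed) {
  d <- config$d_E
  withr::with_seed(seed, {
    sizes <- sizes_draw()
    k <- length(sizes)
    pts <- vector("list", k)
    centroids <- matrix(NA_real_, k, d)
    sigmas <- matrix(NA_real_, k, d)
    for (i in seq_len(k)) {
      centroids[i, ] <- runif(d, config$centroid_interval[1], config$centroid_interval[2])
      sigmas[i, ] <- runif(d, config$sigma_range[1], config$sigma_range[2])
      l <- sizes[i]
      pts[[i]] <- matrix(rnorm(l * d), l, d) *
        matrix(sigmas[i, ], l, d, byrow = TRUE) +
        matrix(centroids[i, ], l, d, byrow = TRUE)
    }
    X <- do.call(rbind, pts)
    member <- rep.int(seq_len(k), sizes)
    ord <- sample.int(nrow(X))
    structure(list(points = X[ord, , drop = FALSE], k = k,
                   sizes = as.integer(sizes), membership = member[ord],
                   centroids = centroids, sigmas = sigmas,
                   seed = as.integer(seed)),
              class = "hlr_instance")
  })
}

#' Generate one synthetic clustering instance
#'
#' @param k Number of clusters (`>= 1`).
#' @param config A [synthetic_config()].
#' @param seed Instance seed.
#' @return An `hlr_instance`: list with `points` (M x d_E matrix, rows
#'   shuffled), `k`, `sizes`, `membership` (true cluster of each row),
#'   `centroids` and `sigmas` (k x d_E draws, for audit) and `seed`.
#' @examples
#' inst <- generate_instance(3, synthetic_config(d_E = 2), seed = 7)
#' inst$k
#' @export
generate_instance <- function(k, config = synthetic_config(), seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be a positive integer.")
  stopifnot(inherits(config, "hlr_config"))
  sample_instance(function() {
    sample_int_range(config$size_range[1], config$size_range[2], k)
  }, config, seed)
}

#' @export
print.hlr_instance <- function(x, ...) {
  cat(sprintf("<hlr_instance> %d clusters, M = %d points, d = %d (seed %d)\n",
              x$k, nrow(x$points), ncol(x$points), x$seed))
  invisible(x)
}

#' Generate a labelled synthetic training set
#'
#' Draws `K` instances with cluster counts uniform on `config$k_range`.
#' Fully reproducible: per-instance seeds are derived from the master seed,
#' so two calls with the same configuration produce bit-identical data.
#'
#' @param K Number of instances.
#' @param config A [synthetic_config()]; its `seed` is the master seed
#'   unless overridden.
#' @param seed Optional master-seed override.
#' @return A tibble of class `hlr_training_set` with columns `id`, `k`
#'   (ground-truth cluster count), `M`, `seed`, `sizes` (list), `points`
#'   (list of matrices); the configuration is kept in the `config`
#'   attribute.
#' @export
generate_training_set <- function(K, config = synthetic_config(), seed = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) abort("`K` must be a positive integer.")
  stopifnot(inherits(config, "hlr_config"))
  master <- as.integer(seed %||% config$seed)
  draws <- withr::with_seed(master, {
    list(ks = sample_int_range(config$k_range[1], config$k_range[2], K),
         seeds = sample.int(.Machine$integer.max - 1L, K))
  })
  instances <- map2(draws$ks, draws$seeds,
                    function(k, s) generate_instance(k, config, seed = s))
  out <- tibble(
    id = seq_len(K),
    k = as.integer(draws$ks),
    M = map_int(instances, ~ nrow(.x$points)),
    seed = as.integer(draws$seeds),
    sizes = map(instances, "sizes"),
    points = map(instances, "points")
  )
  attr(out, "config") <- config
  attr(out, "master_seed") <- master
  class(out) <- c("hlr_training_set", class(out))
  out
}

#' Generate an instance with a fixed total point count
#'
#' Splits exactly `M_total` points into `k` clusters of unequal random
#' sizes (each at least 2). Used as the point-count confounder control:
#' cluster number varies while `M` stays constant.
#'
#' @param M_total Total number of points.
#' @param k Number of clusters; must satisfy `k <= M_total / 2`.
#' @inheritParams generate_instance
#' @return An `hlr_instance` with `sum(sizes) == M_total`.
#' @export
generate_fixed_total <- function(M_total, k, config = synthetic_config(),
                                 seed = 1L) {
  M_total <- as.integer(M_total)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be a positive integer.")
  if (k > M_total / 2) {
    abort(sprintf("Infeasible: %d clusters of >= 2 points cannot sum to %d.",
                  k, M_total))
  }
  sample_instance(function() {
    # Unequal random composition with a detectability floor: every cluster
    # keeps at least a quarter of the equal share (and never fewer than 2
    # points), and the remaining mass is apportioned by a broken-stick
    # (uniform Dirichlet) draw. Near-equal multinomial splits would make
    # every cluster ~ M_total / k; a floorless broken stick routinely
    # produces 2-5-point "clusters" that are not detectable groupings at
    # all, which would make the ground-truth count unidentifiable rather
    # than testing it.
    floor_size <- max(2L, as.integer(M_total %/% (4L * k)))
    spare <- M_total - floor_size * k
    w <- stats::rexp(k)
    raw <- spare * w / sum(w)
    sizes <- floor(raw)
    short <- spare - sum(sizes)
    if (short > 0) {
      top_up <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
      sizes[top_up] <- sizes[top_up] + 1
    }
    floor_size + as.integer(sizes)
  }, config, seed)
}

#' Perturb an instance (scale and jitter)
#'
#' Returns `scale * X` plus Gaussian jitter with per-feature standard
#' deviation `jitter_frac` times the per-feature standard deviation of the
#' scaled data. The ground-truth cluster count is unchanged. With
#' `jitter_frac = 0` and `scale = 1` the instance is returned untouched.
#'
#' @param inst An `hlr_instance`.
#' @param scale Positive multiplier applied to all coordinates.
#' @param jitter_frac Non-negative jitter fraction.
#' @param seed RNG seed for the jitter.
#' @return An `hlr_instance` with perturbed points.
#' @export
perturb_instance <- function(inst, scale = 1, jitter_frac = 0, seed = 1L) {
  stopifnot(inherits(inst, "hlr_instance"))
  if (scale <= 0) abort("`scale` must be positive.")
  if (jitter_frac < 0) abort("`jitter_frac` must be non-negative.")
  X <- inst$points * scale
  if (jitter_frac > 0) {
    sds <- apply(X, 2, sd) * jitter_frac
    X <- X + withr::with_seed(seed, {
      matrix(rnorm(length(X)), nrow(X), ncol(X)) *
        matrix(sds, nrow(X), ncol(X), byrow = TRUE)
    })
  }
  out <- inst
  out$points <- X
  out
}
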