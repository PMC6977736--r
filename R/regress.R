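#' Assemble the feature matrix for a set of instances
#'
#' Featurizes each instance (a point matrix) and stacks the feature vectors
#' as columns of a `p x K` matrix, `p = R(R+1)/2` for the linkage
#' featurizer or `nbins` for the distance-only ablation featurizer.
#' Ground-truth cluster counts are attached as labels when the input
#' carries them.
#'
#' @param x An `hlr_training_set` tibble, a list of point matrices,
#'   `hlr_instance` or prebuilt `hlr_hierarchy` objects, a single matrix,
#'   or a single `hlr_instance`. When hierarchies are supplied their own
#'   linkage parameters govern the featurization (the `linkage`/`metric`
#'   arguments are ignored) and each hierarchy is featurized once, which
#'   avoids re-clustering when both the linkage and the distance featurizer
#'   are wanted for the same instances.
#' @param R Bins per axis of the linkage-coordinate histogram.
#' @param linkage,metric,standardize Passed to [build_hierarchy()].
#' @inheritParams linkage_histogram
#' @param featurizer `"linkage"` (2-D linkage-coordinate histogram, the HLR
#'   feature) or `"distance"` (1-D merge-height histogram baseline).
#' @param nbins Bins for the distance featurizer.
#' @return An object of class `hlr_features`: list with `F` (`p x K`
#'   matrix, columns sum to 1), `labels` (integer vector or `NULL`) and
#'   `spec` (featurization fingerprint, including the maximum input
#'   dimensionality `d_E` seen).
#' @export
build_feature_matrix <- function(x, R = 40,
                                 linkage = c("complete", "single", "ward"),
                                 metric = c("euclidean", "manhattan"),
                                 standardize = FALSE,
                                 featurizer = c("linkage", "distance"),
                                 nbins = 200, marginalize_leaves = FALSE) {
  featurizer <- match.arg(featurizer)
  params <- linkage_params(linkage, metric)
  labels <- NULL
  if (inherits(x, "hlr_training_set")) {
    labels <- x$k
    mats <- x$points
  } else if (inherits(x, "hlr_instance")) {
    labels <- x$k
    mats <- list(x$points)
  } else if (is.matrix(x) || is.data.frame(x)) {
    mats <- list(as_point_matrix(x))
  } else if (is.list(x)) {
    if (length(x) == 0L) abort("`x` is empty.")
    if (all(map_lgl(x, inherits, "hlr_instance"))) {
      labels <- map_int(x, "k")
      mats <- map(x, "points")
    } else if (all(map_lgl(x, inherits, "hlr_hierarchy"))) {
      mats <- NULL
      hiers <- x
    } else {
      mats <- map(x, as_point_matrix)
    }
  } else {
    abort("Unsupported input to `build_feature_matrix()`.")
  }
  if (is.null(mats)) {
    # prebuilt hierarchies: their own linkage parameters govern the spec
    params <- hiers[[1]]$params
    if (!all(map_lgl(hiers, function(h) identical(h$params, params)))) {
      abort("All hierarchies must share the same linkage parameters.")
    }
    standardize <- hiers[[1]]$standardize
    d_E <- max(map_int(hiers, function(h) h$n %||% NA_integer_))
  } else {
    if (any(map_int(mats, nrow) < 2L)) {
      abort("Every instance must have at least 2 points (M >= 2).")
    }
    hiers <- map(mats, function(m) {
      build_hierarchy(m, params$linkage, params$metric,
                      standardize = standardize)
    })
    d_E <- max(map_int(mats, ncol))
  }
  if (featurizer == "distance") {
    # fix the bin range at the corpus-wide maximum height so the baseline
    # keeps absolute magnitude information (the point of the ablation)
    range_max <- max(map_dbl(hiers, function(h) max(h$merges$height)))
    feats <- map(hiers, function(h) {
      distance_histogram(h, nbins = nbins, range_max = range_max)
    })
  } else {
    range_max <- NULL
    feats <- map(hiers, function(h) {
      unroll(linkage_histogram(h, R, marginalize_leaves = marginalize_leaves))
    })
  }
  F <- do.call(cbind, feats)
  spec <- list(featurizer = featurizer,
               R = if (featurizer == "linkage") as.integer(R) else NULL,
               nbins = if (featurizer == "distance") as.integer(nbins) else NULL,
               linkage = params$linkage, metric = params$metric,
               standardize = standardize,
               marginalize_leaves = if (featurizer == "linkage") marginalize_leaves else NULL,
               range_max = range_max,
               d_E = d_E)
  structure(list(F = F, labels = if (!is.null(labels)) as.integer(labels),
                 spec = spec),
            class = "hlr_features")
}

#' @export
print.hlr_features <- function(x, ...) {
  cat(sprintf("<hlr_features> %d features x %d instances (%s featurizer, %s linkage, %s metric)%s\n",
              nrow(x$F), ncol(x$F), x$spec$featurizer, x$spec$linkage,
              x$spec$metric,
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' @method as_tibble hlr_features
#' @export
as_tibble.hlr_features <- function(x, ...) {
  out <- as_tibble(t(x$F), .name_repair = ~ paste0("f", seq_along(.x)))
  if (!is.null(x$labels)) out <- mutate(out, k = x$labels, .before = 1)
  out
}

#' Write / read a feature matrix as CSV with a sidecar spec
#'
#' The CSV holds one row per instance (columns `f1..fp`, plus a leading
#' `k` column when labels are present); the sidecar
#' `<path>.spec.json` records the featurization fingerprint so a reloaded
#' matrix can be matched against a model.
#'
#' @param features An `hlr_features` object.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the restored `hlr_features`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "hlr_features"))
  readr::write_csv(as_tibble(features), path)
  writeLines(jsonlite::toJSON(features$spec, auto_unbox = TRUE, null = "null",
                              digits = NA),
             paste0(path, ".spec.json"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Feature file not found: %s", path), class = "hlreg_missing_file")
  }
  sidecar <- paste0(path, ".spec.json")
  if (!file.exists(sidecar)) {
    abort(sprintf("Sidecar spec not found: %s", sidecar),
          class = "hlreg_missing_file")
  }
  raw <- jsonlite::fromJSON(paste(readLines(sidecar), collapse = "\n"),
                            simplifyVector = FALSE)
  spec <- list(
    featurizer = as.character(unlist(raw$featurizer)),
    R = if (is.null(raw$R)) NULL else as.integer(unlist(raw$R)),
    nbins = if (is.null(raw$nbins)) NULL else as.integer(unlist(raw$nbins)),
    linkage = as.character(unlist(raw$linkage)),
    metric = as.character(unlist(raw$metric)),
    standardize = as.logical(unlist(raw$standardize)),
    marginalize_leaves = if (is.null(raw$marginalize_leaves)) NULL else
      as.logical(unlist(raw$marginalize_leaves)),
    range_max = if (is.null(raw$range_max)) NULL else
      as.numeric(unlist(raw$range_max)),
    d_E = as.integer(unlist(raw$d_E))
  )
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labels <- NULL
  if ("k" %in% names(df)) {
    labels <- as.integer(df$k)
    df$k <- NULL
  }
  structure(list(F = t(as.matrix(df)), labels = labels, spec = spec),
            class = "hlr_features")
}

#' Regularized mean-squared-error cost
#'
#' The training objective: `(1/K) * sum((y - y_hat)^2) + (beta/K) * sum(W^2)`
#' where the penalty runs over all connection weights (biases excluded).
#'
#' @param y Model outputs.
#' @param y_hat Ground-truth values, same length.
#' @param weights A numeric vector/matrix or list of them (the network
#'   weight matrices); `NULL` for no penalty term.
#' @param beta Regularization weight in `[0, 1]`.
#' @return A single number.
#' @examples
#' hlr_cost(2, 3, weights = c(1, 1, 1, 1), beta = 0.5) # 1 + 2 = 3
#' @export
hlr_cost <- function(y, y_hat, weights = NULL, beta = 0) {
  if (length(y) != length(y_hat)) abort("`y` and `y_hat` differ in length.")
  K <- length(y)
  penalty <- if (is.null(weights) || beta == 0) 0 else {
    w <- if (is.list(weights)) unlist(weights) else as.numeric(weights)
    beta / K * sum(w^2)
  }
  mean((y - y_hat)^2) + penalty
}

# ---- network internals -----------------------------------------------------

act_fun <- function(activation) {
  switch(activation,
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) * 1),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a))
  )
}

init_net <- function(p, hidden, activation, seed) {
  dims <- c(p, hidden, 1L)
  withr::with_seed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      fan_in <- dims[l]
      sdv <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
      W[[l]] <- matrix(rnorm(dims[l + 1] * fan_in, sd = sdv), dims[l + 1], fan_in)
      b[[l]] <- numeric(dims[l + 1])
    }
    list(W = W, b = b)
  })
}

net_forward <- function(net, X, act) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- net$W[[l]] %*% A[[l]] + net$b[[l]]
    A[[l + 1]] <- if (l < L) act$f(Z[[l]]) else Z[[l]]  # linear output unit
  }
  list(y = as.numeric(A[[L + 1]]), A = A, Z = Z)
}

# Fixed, data-independent input conditioning applied inside the network.
# Entries of a normalized histogram average 1/p, which leaves first-layer
# preactivations (and hence gradients) vanishingly small under
# fan-in-scaled initialization. "scale" multiplies by the constant p to
# restore unit-scale inputs; "sqrt" additionally takes the square root of
# the scaled counts, an Anscombe-style variance-stabilizing transform that
# equalizes the leverage of rare and common histogram bins.
apply_input_transform <- function(F, transform) {
  switch(transform,
    none = F,
    scale = F * nrow(F),
    sqrt = sqrt(F * nrow(F))
  )
}

# `Ktot` normalizes the data term (batch size), `pen_K` the weight penalty
# (full training-set size, so minibatch steps target the same objective).
net_gradient <- function(net, X, y_hat, beta, act, Ktot, pen_K = Ktot) {
  L <- length(net$W)
  fwd <- net_forward(net, X, act)
  K <- ncol(X)
  delta <- matrix((fwd$y - y_hat) * (2 / Ktot), 1L, K)
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- delta %*% t(fwd$A[[l]]) + (2 * beta / pen_K) * net$W[[l]]
    db[[l]] <- rowSums(delta)
    if (l > 1L) {
      delta <- (t(net$W[[l]]) %*% delta) * act$df(fwd$Z[[l - 1]], fwd$A[[l]])
    }
  }
  list(dW = dW, db = db, y = fwd$y)
}

flatten_net <- function(net) unlist(c(net$W, net$b), use.names = FALSE)

unflatten_net <- function(theta, template) {
  out <- template
  pos <- 0L
  for (l in seq_along(template$W)) {
    n <- length(template$W[[l]])
    out$W[[l]] <- matrix(theta[pos + seq_len(n)], nrow(template$W[[l]]))
    pos <- pos + n
  }
  for (l in seq_along(template$b)) {
    n <- length(template$b[[l]])
    out$b[[l]] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  out
}

net_cost <- function(net, X, y_hat, beta, act) {
  y <- net_forward(net, X, act)$y
  hlr_cost(y, y_hat, weights = net$W, beta = beta)
}

#' Train the hierarchical linkage regressor
#'
#' Fits a small fully-connected feedforward network (two hidden layers by
#' default, single linear output unit) to labelled linkage features by
#' backpropagation, minimizing the regularized mean-squared-error cost of
#' [hlr_cost()]. Two solvers are provided: `"adam"`, an adaptive stochastic
#' minibatch solver with optional early stopping on a held-out validation
#' split, and `"cg"`, deterministic full-batch nonlinear conjugate
#' gradients. Both are reproducible from `seed`.
#'
#' @param features A labelled [build_feature_matrix()] result.
#' @param hidden Hidden layer sizes; one or two positive integers (two is
#'   the reference architecture, one is kept for convergence comparisons).
#' @param activation Hidden activation: `"relu"` or `"sigmoid"`. The output
#'   unit is always linear.
#' @param beta Regularization weight (default 0.2).
#' @param solver `"adam"` or `"cg"`.
#' @param epochs Training epochs (Adam) or maximum iterations (CG).
#' @param batch_size Adam minibatch size.
#' @param learn_rate Adam step size.
#' @param input_transform Fixed conditioning of the feature vector inside
#'   the network: `"sqrt"` (default) rescales the histogram by its length
#'   `p` and takes the square root — a variance-stabilizing transform of
#'   the bin counts; `"scale"` rescales by `p` only; `"none"` feeds raw
#'   features. Stored with the model and applied identically at inference.
#' @param input_noise Standard deviation of zero-mean Gaussian jitter added
#'   to the (rescaled) features of each Adam minibatch, freshly drawn every
#'   step. Emulates the multinomial sampling variability of a histogram
#'   built from finitely many merges and acts as a regularizer; 0 disables.
#'   Ignored by the full-batch CG solver.
#' @param validation_fraction Fraction of instances held out to monitor
#'   generalization and stop Adam early (0 disables early stopping; the CG
#'   solver uses the split only for reporting).
#' @param patience Epochs without validation improvement before Adam stops;
#'   the best-validation weights are restored.
#' @param seed Seed for initialization, the validation split and minibatch
#'   shuffling.
#' @return An object of class `hlr_model` with elements `net` (weights),
#'   `config`, `feature_spec`, `curve` (per-epoch cost tibble) and `fit`
#'   (final training/validation summaries).
#' @export
hlr_train <- function(features, hidden = c(64, 32),
                      activation = c("relu", "sigmoid"), beta = 0.2,
                      solver = c("adam", "cg"), epochs = 300,
                      batch_size = 32, learn_rate = 1e-3,
                      input_transform = c("sqrt", "scale", "none"),
                      input_noise = 0,
                      validation_fraction = 0.1, patience = 25, seed = 1L) {
  stopifnot(inherits(features, "hlr_features"))
  activation <- match.arg(activation)
  solver <- match.arg(solver)
  if (is.null(features$labels)) abort("`features` carries no labels; train on a labelled set.")
  if (!all(is.finite(features$F))) abort("Non-finite feature values.")
  hidden <- as.integer(hidden)
  if (!length(hidden) %in% 1:2 || any(hidden < 1L)) {
    abort("`hidden` must be one or two positive integers.")
  }
  if (beta < 0 || beta > 1) abort("`beta` must lie in [0, 1].")
  input_transform <- match.arg(input_transform)
  X <- apply_input_transform(features$F, input_transform)
  y_hat <- as.numeric(features$labels)
  K <- ncol(X)
  if (K < 2L) abort("Need at least 2 labelled instances.")
  if (length(unique(y_hat)) == 1L) {
    warn("All training labels are identical; the regressor will be degenerate.")
  }
  act <- act_fun(activation)

  # validation split
  n_val <- floor(K * validation_fraction)
  idx_val <- if (n_val >= 1L) {
    withr::with_seed(seed, sample.int(K, n_val))
  } else integer(0)
  idx_tr <- setdiff(seq_len(K), idx_val)
  Xtr <- X[, idx_tr, drop = FALSE]; ytr <- y_hat[idx_tr]
  Xval <- X[, idx_val, drop = FALSE]; yval <- y_hat[idx_val]

  net <- init_net(nrow(X), hidden, activation, seed)
  curve <- NULL

  if (solver == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    theta_m <- flatten_net(net) * 0
    theta_v <- theta_m
    best <- list(val = Inf, net = net, epoch = 0L)
    wait <- 0L
    t_step <- 0L
    Ktr <- ncol(Xtr)
    curve <- vector("list", epochs)
    withr::with_seed(seed + 1L, {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(Ktr)
        starts <- seq(1L, Ktr, by = batch_size)
        for (s in starts) {
          sel <- ord[s:min(s + batch_size - 1L, Ktr)]
          Xb <- Xtr[, sel, drop = FALSE]
          if (input_noise > 0) {
            Xb <- Xb + matrix(rnorm(length(Xb), sd = input_noise),
                              nrow(Xb), ncol(Xb))
          }
          g <- net_gradient(net, Xb, ytr[sel], beta,
                            act, Ktot = length(sel), pen_K = Ktr)
          grad <- unlist(c(g$dW, g$db), use.names = FALSE)
          t_step <- t_step + 1L
          theta <- flatten_net(net)
          theta_m <- b1 * theta_m + (1 - b1) * grad
          theta_v <- b2 * theta_v + (1 - b2) * grad^2
          mhat <- theta_m / (1 - b1^t_step)
          vhat <- theta_v / (1 - b2^t_step)
          theta <- theta - learn_rate * mhat / (sqrt(vhat) + eps)
          net <- unflatten_net(theta, net)
        }
        tr_cost <- net_cost(net, Xtr, ytr, beta, act)
        val_mse <- if (length(idx_val)) {
          hlr_cost(net_forward(net, Xval, act)$y, yval)
        } else NA_real_
        curve[[ep]] <- c(epoch = ep, cost = tr_cost, val_mse = val_mse)
        if (length(idx_val)) {
          if (val_mse < best$val - 1e-9) {
            best <- list(val = val_mse, net = net, epoch = ep)
            wait <- 0L
          } else {
            wait <- wait + 1L
            if (wait >= patience) break
          }
        }
      }
    })
    curve <- as_tibble(do.call(rbind, curve[!map_lgl(curve, is.null)]))
    if (length(idx_val) && is.finite(best$val)) net <- best$net
  } else {
    theta0 <- flatten_net(net)
    template <- net
    fn <- function(th) net_cost(unflatten_net(th, template), Xtr, ytr, beta, act)
    gr <- function(th) {
      g <- net_gradient(unflatten_net(th, template), Xtr, ytr, beta, act,
                        Ktot = ncol(Xtr))
      unlist(c(g$dW, g$db), use.names = FALSE)
    }
    opt <- optim(theta0, fn, gr, method = "CG",
                 control = list(maxit = epochs))
    net <- unflatten_net(opt$par, template)
    curve <- tibble(epoch = NA_integer_, cost = opt$value, val_mse = NA_real_)
  }

  ytr_fit <- net_forward(net, Xtr, act)$y
  fit <- list(
    train_cost = net_cost(net, Xtr, ytr, beta, act),
    train_mse = hlr_cost(ytr_fit, ytr),
    val_mse = if (length(idx_val)) hlr_cost(net_forward(net, Xval, act)$y, yval) else NA_real_,
    n_train = length(idx_tr), n_val = length(idx_val)
  )
  structure(
    list(net = net, input_transform = input_transform,
         config = list(hidden = hidden, activation = activation, beta = beta,
                       solver = solver, epochs = epochs,
                       batch_size = batch_size, learn_rate = learn_rate,
                       input_noise = input_noise,
                       validation_fraction = validation_fraction,
                       patience = patience, seed = as.integer(seed)),
         feature_spec = features$spec,
         curve = curve, fit = fit),
    class = "hlr_model"
  )
}

#' @export
print.hlr_model <- function(x, ...) {
  val_mse <- x$fit$val_mse %||% NA_real_
  cat(sprintf(
    "<hlr_model> FNN %d -> %s -> 1 (%s), solver %s, beta %.2f\n  featurizer: %s (%s linkage, %s metric)\n  train cost %.4f | train MSE %.4f | val MSE %s\n",
    ncol(x$net$W[[1]]),
    paste(x$config$hidden, collapse = " -> "), x$config$activation,
    x$config$solver, x$config$beta,
    x$feature_spec$featurizer, x$feature_spec$linkage, x$feature_spec$metric,
    x$fit$train_cost, x$fit$train_mse,
    if (is.na(val_mse)) "-" else sprintf("%.4f", val_mse)))
  invisible(x)
}

spec_fingerprint <- function(spec) {
  paste(spec$featurizer, spec$R %||% "", spec$nbins %||% "", spec$linkage,
        spec$metric, spec$standardize,
        isTRUE(spec$marginalize_leaves),
        if (is.null(spec$range_max)) "" else sprintf("%.17g", spec$range_max),
        sep = "|")
}

featurize_for_model <- function(model, points) {
  spec <- model$feature_spec
  pts <- as_point_matrix(points)
  if (nrow(pts) < 2L) abort("Need at least 2 rows to infer a cluster count.")
  if (ncol(pts) > spec$d_E) {
    warn(sprintf(
      "Input dimensionality (%d) exceeds the training embedding dimension d_E = %d; estimates may be unreliable. Retrain with d_E >= %d.",
      ncol(pts), spec$d_E, ncol(pts)))
  }
  if (spec$featurizer == "linkage") {
    featurize(pts, R = spec$R, linkage = spec$linkage, metric = spec$metric,
              standardize = spec$standardize,
              marginalize_leaves = isTRUE(spec$marginalize_leaves))
  } else {
    distance_histogram(pts, nbins = spec$nbins, linkage = spec$linkage,
                       metric = spec$metric, standardize = spec$standardize,
                       range_max = spec$range_max)
  }
}

#' Infer cluster number for new data
#'
#' Featurizes the input internally with the model's stored featurization
#' fingerprint and returns the regression output. `type = "raw"` gives the
#' continuous inference; `"rounded"` rounds half-away-from-zero and clamps
#' to at least 1.
#'
#' @param object An `hlr_model`.
#' @param newdata A point matrix / data frame (one instance), a list of
#'   them, an `hlr_instance` / `hlr_training_set`, or an `hlr_features`
#'   object (which must have been produced under the identical featurization
#'   fingerprint, else an error is thrown).
#' @param type `"raw"` or `"rounded"`.
#' @param ... Unused.
#' @return Numeric (raw) or integer (rounded) vector, one value per
#'   instance.
#' @export
predict.hlr_model <- function(object, newdata, type = c("raw", "rounded"),
                              ...) {
  type <- match.arg(type)
  act <- act_fun(object$config$activation)
  if (inherits(newdata, "hlr_features")) {
    if (!identical(spec_fingerprint(newdata$spec),
                   spec_fingerprint(object$feature_spec))) {
      abort(paste0(
        "Feature specification mismatch: these features were produced under '",
        spec_fingerprint(newdata$spec), "' but the model expects '",
        spec_fingerprint(object$feature_spec), "'."),
        class = "hlreg_spec_mismatch")
    }
    F <- newdata$F
  } else {
    mats <- if (inherits(newdata, "hlr_training_set")) newdata$points
      else if (inherits(newdata, "hlr_instance")) list(newdata$points)
      else if (is.list(newdata) && !is.data.frame(newdata)) {
        if (all(map_lgl(newdata, inherits, "hlr_instance"))) map(newdata, "points") else newdata
      }
      else list(newdata)
    F <- do.call(cbind, lapply(mats, function(m) featurize_for_model(object, m)))
  }
  raw <- net_forward(object$net,
                     apply_input_transform(F, object$input_transform %||% "none"),
                     act)$y
  if (type == "raw") raw else as.integer(pmax(1, round_half_away(raw)))
}

#' Train an ensemble of independently initialized regressors
#'
#' Trains `n_models` networks on the same features with different
#' initialization seeds, for [ensemble_median()] inference.
#'
#' @inheritParams hlr_train
#' @param n_models Number of regressors.
#' @param seed Base seed; model i uses `seed + i - 1`.
#' @param ... Passed to [hlr_train()].
#' @return A list of `hlr_model` objects, class `hlr_ensemble`.
#' @export
hlr_train_ensemble <- function(features, n_models = 100, seed = 1L, ...) {
  models <- map(seq_len(n_models),
                function(i) hlr_train(features, seed = seed + i - 1L, ...))
  structure(models, class = "hlr_ensemble")
}

#' Ensemble median-rounded inference
#'
#' Applies each model, rounds each continuous output to the nearest integer
#' (half away from zero), and takes the median of the rounded values; the
#' result is again rounded (an even ensemble can produce a half-integer
#' median) and clamped to at least 1.
#'
#' @param models A list of `hlr_model` objects (e.g. an `hlr_ensemble`).
#' @param newdata As in [predict.hlr_model()].
#' @return Integer vector, one estimate per instance.
#' @examples
#' \dontrun{
#' ensemble_median(models, iris[, 1:4])
#' }
#' @export
ensemble_median <- function(models, newdata) {
  if (inherits(models, "hlr_model")) models <- list(models)
  if (length(models) == 0L) abort("Empty ensemble.")
  rounded <- do.call(rbind, map(models, function(m) {
    round_half_away(predict(m, newdata, type = "raw"))
  }))
  med <- apply(rounded, 2, median)
  as.integer(pmax(1, round_half_away(med)))
}

#' @method tidy hlr_model
#' @export
tidy.hlr_model <- function(x, ...) {
  L <- length(x$net$W)
  layer_name <- function(l) if (l == L) "output" else paste0("hidden", l)
  bind_rows(
    bind_rows(lapply(seq_len(L), function(l) {
      W <- x$net$W[[l]]
      tibble(layer = layer_name(l), parameter = "weight",
             row = rep(seq_len(nrow(W)), ncol(W)),
             col = rep(seq_len(ncol(W)), each = nrow(W)),
             value = as.numeric(W))
    })),
    bind_rows(lapply(seq_len(L), function(l) {
      tibble(layer = layer_name(l), parameter = "bias",
             row = seq_along(x$net$b[[l]]), col = NA_integer_,
             value = x$net$b[[l]])
    }))
  )
}

#' @method glance hlr_model
#' @export
glance.hlr_model <- function(x, ...) {
  tibble(
    n_params = length(flatten_net(x$net)),
    hidden = paste(x$config$hidden, collapse = "x"),
    activation = x$config$activation,
    solver = x$config$solver,
    beta = x$config$beta,
    epochs_run = if (all(is.na(x$curve$epoch))) NA_integer_ else max(x$curve$epoch),
    train_cost = x$fit$train_cost,
    train_mse = x$fit$train_mse,
    val_mse = x$fit$val_mse
  )
}

#' @method autoplot hlr_model
#' @export
autoplot.hlr_model <- function(object, ...) {
  curve <- tidyr::pivot_longer(object$curve, -"epoch",
                               names_to = "series", values_to = "value")
  curve <- filter(curve, is.finite(.data$value), !is.na(.data$epoch))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$epoch, y = .data$value,
                                      colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "cost (log scale)", colour = NULL,
                  title = "Training curve") +
    ggplot2::theme_minimal()
}

# ---- portable model archive ------------------------------------------------

num_to_chr <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly

#' Save / load a trained model as a portable text archive
#'
#' The archive is a single JSON document: structured metadata (featurization
#' fingerprint, training configuration, fit summaries) plus weight blocks
#' serialized at full precision, so that a load/save round trip reproduces
#' predictions bit-exactly.
#'
#' @param model An `hlr_model`.
#' @param path File path (conventionally `.json`).
#' @return `hlr_save()` returns `path` invisibly; `hlr_load()` returns the
#'   restored `hlr_model`.
#' @export
hlr_save <- function(model, path) {
  stopifnot(inherits(model, "hlr_model"))
  doc <- list(
    format = "hlreg-model",
    version = 1L,
    package_version = as.character(utils::packageVersion("hlreg")),
    feature_spec = model$feature_spec,
    input_transform = model$input_transform,
    config = model$config,
    fit = model$fit,
    curve = as.list(model$curve),
    net = list(
      W = map(model$net$W, function(w) list(dim = dim(w), values = num_to_chr(as.numeric(w)))),
      b = map(model$net$b, num_to_chr)
    )
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                              na = "null", digits = NA), path)
  invisible(path)
}

#' @rdname hlr_save
#' @export
hlr_load <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path),
          class = "hlreg_missing_file")
  }
  doc <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = FALSE)
  if (!identical(doc$format, "hlreg-model")) {
    abort("Not an hlreg model archive.")
  }
  scalar <- function(v, as = identity) if (is.null(v)) NULL else as(unlist(v))
  num_or_na <- function(v) {
    if (is.null(v)) return(NA_real_)
    suppressWarnings(as.numeric(unlist(v)))
  }
  W <- map(doc$net$W, function(w) {
    d <- as.integer(unlist(w$dim))
    matrix(as.numeric(unlist(w$values)), d[1], d[2])
  })
  b <- map(doc$net$b, function(v) as.numeric(unlist(v)))
  spec <- list(
    featurizer = scalar(doc$feature_spec$featurizer, as.character),
    R = scalar(doc$feature_spec$R, as.integer),
    nbins = scalar(doc$feature_spec$nbins, as.integer),
    linkage = scalar(doc$feature_spec$linkage, as.character),
    metric = scalar(doc$feature_spec$metric, as.character),
    standardize = scalar(doc$feature_spec$standardize, as.logical),
    marginalize_leaves = scalar(doc$feature_spec$marginalize_leaves, as.logical),
    range_max = scalar(doc$feature_spec$range_max, as.numeric),
    d_E = scalar(doc$feature_spec$d_E, as.integer)
  )
  cfg <- lapply(doc$config, unlist)
  cfg$hidden <- as.integer(cfg$hidden)
  fit <- list(train_cost = num_or_na(doc$fit$train_cost),
              train_mse = num_or_na(doc$fit$train_mse),
              val_mse = num_or_na(doc$fit$val_mse),
              n_train = scalar(doc$fit$n_train, as.integer),
              n_val = scalar(doc$fit$n_val, as.integer))
  curve_col <- function(col) {
    map_dbl(col, function(v) {
      if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
    })
  }
  curve <- tibble(epoch = curve_col(doc$curve$epoch),
                  cost = curve_col(doc$curve$cost),
                  val_mse = curve_col(doc$curve$val_mse))
  structure(
    list(net = list(W = W, b = b),
         input_transform = scalar(doc$input_transform, as.character) %||% "none",
         config = cfg, feature_spec = spec,
         curve = curve, fit = fit),
    class = "hlr_model"
  )
}
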