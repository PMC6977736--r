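check_eval_input <- function(estimates, truths) {
  if (length(estimates) == 0L) abort("Empty input.")
  if (length(estimates) != length(truths)) {
    abort("`estimates` and `truths` differ in length.")
  }
  if (any(truths < 1)) abort("Ground-truth cluster counts must be >= 1.")
  invisible(TRUE)
}

# hit = estimate within delta clusters of the truth
delta_hits <- function(estimates, truths, delta) {
  abs(estimates - truths) <= delta
}

#' Recall at a cluster delta
#'
#' Fraction of instances whose estimate lies within `delta` clusters of the
#' ground truth (TP / (TP + FN)); in the single-cluster-number scenario,
#' where every instance is a positive case, this equals accuracy. Recall is
#' non-decreasing in `delta`.
#'
#' @param estimates Integer vector of cluster-number estimates.
#' @param truths Integer vector of ground-truth cluster counts (`>= 1`).
#' @param delta Non-negative tolerance on the estimate.
#' @return A single number in `[0, 1]`.
#' @examples
#' recall_at_delta(c(15, 14, 10, 16, 20), rep(15, 5), delta = 1) # 0.6
#' @export
recall_at_delta <- function(estimates, truths, delta = 0) {
  check_eval_input(estimates, truths)
  mean(delta_hits(estimates, truths, delta))
}

#' Jaccard index and HLR-normalized Jaccard score
#'
#' The Jaccard index of a method's binary hit vector (hit = estimate within
#' `delta` of truth) against the all-positive indicator set reduces to
#' hits / n; the normalized score divides by the reference (HLR) model's
#' index and so reduces to the ratio of hit counts. A score of 1 means
#' parity with the reference; when the reference has zero hits the
#' normalized score is undefined and returned as `NA` with `undefined =
#' TRUE`.
#'
#' @param estimates Comparator estimates.
#' @param reference_estimates Reference (HLR) estimates on the same
#'   instances.
#' @param truths Shared ground-truth cluster counts.
#' @param delta Cluster-delta tolerance.
#' @return A one-row tibble: `delta`, `j_model`, `j_reference`,
#'   `j_normalized`, `undefined`.
#' @export
jaccard_scores <- function(estimates, reference_estimates, truths, delta = 0) {
  check_eval_input(estimates, truths)
  check_eval_input(reference_estimates, truths)
  n <- length(truths)
  hits_m <- sum(delta_hits(estimates, truths, delta))
  hits_r <- sum(delta_hits(reference_estimates, truths, delta))
  tibble(
    delta = delta,
    j_model = hits_m / n,
    j_reference = hits_r / n,
    j_normalized = if (hits_r == 0) NA_real_ else hits_m / hits_r,
    undefined = hits_r == 0
  )
}

#' Per-cluster-number F1 scores and macro F1
#'
#' For each intrinsic cluster number `y` in `1..y_max`, an instance is a
#' true positive when its truth equals `y` and the estimate lies within
#' `delta` of the truth; a false negative when its truth equals `y` but the
#' estimate misses; and a false positive for `y` when the estimate lies
#' within `delta` of `y` while the truth does not. F1 is the harmonic mean
#' of precision (TP / (TP + FP)) and recall (TP / (TP + FN)), with F1 = 0
#' when precision + recall = 0; the macro F1 is the unweighted mean over
#' `y = 1..y_max`. With `y_max = 1` this reduces exactly to the binary F1.
#'
#' @inheritParams recall_at_delta
#' @param y_max Highest intrinsic cluster number scored; must cover
#'   `max(truths)`.
#' @return A list with `per_cluster` (tibble: `y`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`) and `macro_f1`.
#' @export
f1_scores <- function(estimates, truths, delta = 0, y_max = max(truths)) {
  check_eval_input(estimates, truths)
  if (y_max < max(truths)) {
    abort("`y_max` must be at least max(truths).")
  }
  per <- map(seq_len(y_max), function(y) {
    at_y <- truths == y
    hit <- delta_hits(estimates, truths, delta)
    claimed_y <- abs(estimates - y) <= delta
    truth_near_y <- abs(truths - y) <= delta
    tp <- sum(at_y & hit)
    fn <- sum(at_y & !hit)
    fp <- sum(claimed_y & !truth_near_y)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble(y = y, tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1)
  })
  per <- bind_rows(per)
  list(per_cluster = per, macro_f1 = mean(per$f1))
}

#' Percentile-bootstrap confidence intervals for recall
#'
#' Resamples the evaluation instances with replacement (`n_cases` bootstrap
#' cases of `case_size` samples each), recomputes recall at each delta, and
#' returns the empirical `(1 - level)/2` and `1 - (1 - level)/2` quantiles.
#'
#' @inheritParams recall_at_delta
#' @param deltas Integer vector of deltas to evaluate.
#' @param n_cases Number of bootstrap cases (default 200).
#' @param case_size Samples per case, drawn with replacement (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed; results are seed-reproducible.
#' @return A tibble: `delta`, `recall` (full-sample point estimate),
#'   `lower`, `upper`, `level`.
#' @export
bootstrap_ci <- function(estimates, truths, deltas = 0:5, n_cases = 200,
                         case_size = 200, level = 0.95, seed = 1L) {
  check_eval_input(estimates, truths)
  if (length(estimates) < 2L) abort("Need at least 2 instances to bootstrap.")
  n <- length(estimates)
  reps <- withr::with_seed(seed, {
    map(seq_len(n_cases), function(i) {
      idx <- sample.int(n, case_size, replace = TRUE)
      map_dbl(deltas, function(d) mean(delta_hits(estimates[idx], truths[idx], d)))
    })
  })
  reps <- do.call(rbind, reps)  # n_cases x length(deltas)
  alpha <- (1 - level) / 2
  tibble(
    delta = deltas,
    recall = map_dbl(deltas, function(d) recall_at_delta(estimates, truths, d)),
    lower = apply(reps, 2, quantile, probs = alpha, names = FALSE),
    upper = apply(reps, 2, quantile, probs = 1 - alpha, names = FALSE),
    level = level
  )
}

#' Delta-indexed evaluation report
#'
#' Scores cluster-number estimates over a range of cluster deltas: recall,
#' macro F1, Jaccard index, optionally the reference-normalized Jaccard
#' score, and percentile-bootstrap confidence bounds on recall.
#'
#' @inheritParams recall_at_delta
#' @inheritParams bootstrap_ci
#' @param y_max Highest intrinsic cluster number for the macro F1.
#' @param reference Optional reference (HLR) estimates for the normalized
#'   Jaccard score.
#' @param bootstrap Compute bootstrap CIs on recall (default `TRUE`).
#' @return A tibble of class `hlr_eval`, one row per delta, with columns
#'   `delta`, `n`, `hits`, `recall`, `macro_f1`, `jaccard`,
#'   `j_normalized` (if `reference` given), and `ci_lower`/`ci_upper`/
#'   `ci_level` (if `bootstrap`).
#' @export
hlr_evaluate <- function(estimates, truths, deltas = 0:5,
                         y_max = max(truths), reference = NULL,
                         bootstrap = TRUE, n_cases = 200, case_size = 200,
                         level = 0.95, seed = 1L) {
  check_eval_input(estimates, truths)
  n <- length(estimates)
  out <- bind_rows(map(deltas, function(d) {
    hits <- sum(delta_hits(estimates, truths, d))
    row <- tibble(
      delta = d, n = n, hits = hits,
      recall = hits / n,
      macro_f1 = f1_scores(estimates, truths, d, y_max)$macro_f1,
      jaccard = hits / n
    )
    if (!is.null(reference)) {
      js <- jaccard_scores(estimates, reference, truths, d)
      row$j_normalized <- js$j_normalized
    }
    row
  }))
  if (bootstrap && n >= 2L) {
    ci <- bootstrap_ci(estimates, truths, deltas, n_cases, case_size,
                       level, seed)
    out$ci_lower <- ci$lower
    out$ci_upper <- ci$upper
    out$ci_level <- level
  }
  class(out) <- c("hlr_eval", class(out))
  out
}

#' Write an evaluation report as TSV and/or JSON
#'
#' The TSV is flat (one row per delta x metric); the JSON document keeps
#' the per-delta structure.
#'
#' @param report An [hlr_evaluate()] tibble.
#' @param tsv,json Output paths; either may be `NULL`.
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "hlr_eval"))
  if (!is.null(tsv)) {
    long <- tidyr::pivot_longer(as_tibble(report), -"delta",
                                names_to = "metric", values_to = "value")
    readr::write_tsv(long, tsv)
  }
  if (!is.null(json)) {
    writeLines(jsonlite::toJSON(as_tibble(report), dataframe = "rows",
                                auto_unbox = TRUE, digits = NA, na = "null"),
               json)
  }
  invisible(report)
}

#' @method autoplot hlr_eval
#' @export
autoplot.hlr_eval <- function(object, metric = c("recall", "macro_f1"), ...) {
  metric <- match.arg(metric)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$delta, y = .data[[metric]]))
  if (metric == "recall" && all(c("ci_lower", "ci_upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      alpha = 0.2)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = expression(Delta ~ "(cluster delta)"), y = metric) +
    ggplot2::theme_minimal()
}

#' Prediction-vs-truth diagnostic plot
#'
#' Scatter of raw inferences against ground-truth cluster counts with the
#' identity line and the fitted regression line.
#'
#' @param estimates Numeric (raw) or integer estimates.
#' @param truths Ground-truth cluster counts.
#' @return A ggplot object.
#' @export
plot_recovery <- function(estimates, truths) {
  check_eval_input(estimates, truths)
  df <- tibble(truth = truths, estimate = estimates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "ground-truth cluster count", y = "inferred count") +
    ggplot2::theme_minimal()
}
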