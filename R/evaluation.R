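# Per-class correct-classification rates, totals and averages, and
# percentile-bootstrap confidence intervals.

#' Score classification results against their labels
#'
#' For each divergence kind, computes the per-group correct-classification
#' rate (one group per class x modality), the total number of correctly
#' classified patches, the average success rate (100 x total_correct /
#' total_used), and macro-averaged precision, recall and F1 over the three
#' classes.
#'
#' @param results Data frame from [classify_dataset()] or [fuse_results()],
#'   with a truth column `label`.
#' @param truth Optional explicit truth labels (defaults to
#'   `results$label`); must align row-for-row.
#' @return An `evaluation_report`: list keyed by divergence kind, each with
#'   `rates` (data frame `modality, class, n, correct, rate`),
#'   `total_correct`, `total_used`, `average_success_rate`, `precision`,
#'   `recall`, `f1`.
#' @export
score <- function(results, truth = NULL) {
  truth <- truth %||% results$label
  if (length(truth) != nrow(results) || anyNA(truth))
    stop("truth labels must align with results (one label per row)",
         call. = FALSE)
  rep_for <- function(pred) {
    grp <- interaction(results$modality, truth, drop = TRUE)
    rows <- lapply(levels(grp), function(g) {
      i <- grp == g
      data.frame(modality = results$modality[i][1], class = truth[i][1],
                 n = sum(i), correct = sum(pred[i] == truth[i]),
                 stringsAsFactors = FALSE)
    })
    rates <- do.call(rbind, rows)
    rates$rate <- 100 * rates$correct / rates$n
    prf <- vapply(wd_classes, function(cls) {
      tp <- sum(pred == cls & truth == cls)
      p <- if (sum(pred == cls) > 0) tp / sum(pred == cls) else 0
      r <- if (sum(truth == cls) > 0) tp / sum(truth == cls) else 0
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      c(p, r, f)
    }, numeric(3))
    list(rates = rates,
         total_correct = sum(rates$correct),
         total_used = sum(rates$n),
         average_success_rate = 100 * sum(rates$correct) / sum(rates$n),
         precision = mean(prf[1, ]), recall = mean(prf[2, ]),
         f1 = mean(prf[3, ]))
  }
  out <- lapply(setNames(wd_divergences, wd_divergences), function(k)
    rep_for(results[[paste0("assigned_", k)]]))
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  for (k in names(x)) {
    cat(sprintf("%s: %d/%d correct, average success rate %.2f%% ",
                k, x[[k]]$total_correct, x[[k]]$total_used,
                x[[k]]$average_success_rate))
    cat(sprintf("(macro P %.3f R %.3f F1 %.3f)\n",
                x[[k]]$precision, x[[k]]$recall, x[[k]]$f1))
  }
  invisible(x)
}

#' Aggregate printed per-group rates into totals
#'
#' Reconstructs the total number of correctly classified patches and the
#' average success rate from per-group percentage rates and a common group
#' size. Because published rates are themselves rounded, the implied
#' per-group counts can be fractional; the total is rounded to the nearest
#' integer and the average recomputed from it.
#'
#' @param per_class_rates Percentages in `[0, 100]`, one per group
#'   (typically 6: three classes x two modalities).
#' @param n_per_class Patches per group.
#' @return List with `total_correct` (integer) and `average_rate` (percent,
#'   2 decimals).
#' @export
aggregate_rates <- function(per_class_rates, n_per_class) {
  if (any(per_class_rates < 0 | per_class_rates > 100))
    stop("rates must lie in [0, 100]", call. = FALSE)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  total <- round(sum(per_class_rates * n_per_class / 100))
  n_used <- length(per_class_rates) * n_per_class
  list(total_correct = as.integer(total),
       average_rate = round(100 * total / n_used, 2))
}

# resampled confusion tables -> metric vectors (internal)
boot_metrics_from_codes <- function(joint_codes, idx_mat) {
  apply(idx_mat, 2, function(ii) {
    cm <- matrix(tabulate(joint_codes[ii], nbins = 9L), 3, 3)  # true x pred
    tp <- diag(cm)
    p <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
    r <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
    f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    c(accuracy = 100 * sum(tp) / sum(cm),
      precision = mean(p), recall = mean(r), f1 = mean(f))
  })
}

#' Percentile-bootstrap confidence intervals for classification metrics
#'
#' Resamples the test set with replacement `n_resamples` times, recomputes
#' the metric(s) on each resample, and reports the mean and the
#' `(100-level)/2` and `100-(100-level)/2` empirical percentiles
#' (linear-interpolation percentile definition, `stats::quantile` type 7).
#' Deterministic under a fixed seed.
#'
#' With only `correct` supplied (a logical/0-1 correctness vector), accuracy
#' (%) is bootstrapped. With `predictions` and `truth` supplied, accuracy,
#' macro precision, macro recall and macro F1 are all bootstrapped.
#'
#' @param correct Logical or 0/1 vector: was each test patch classified
#'   correctly?
#' @param predictions,truth Optional label vectors (used instead of
#'   `correct`).
#' @param n_resamples Number of bootstrap resamples (default 10000; < 100
#'   warns, < 2 errors).
#' @param level Confidence level in percent (default 95).
#' @param seed Integer seed for the resampling.
#' @return List per metric with `mean`, `lower`, `upper`, plus
#'   `n_resamples` and `seed`.
#' @export
bootstrap_ci <- function(correct = NULL, predictions = NULL, truth = NULL,
                         n_resamples = 10000, level = 95, seed = 1) {
  if (n_resamples < 2) stop("need at least 2 resamples", call. = FALSE)
  if (n_resamples < 100)
    warning("fewer than 100 resamples gives unstable percentiles",
            call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  alpha <- (100 - level) / 200
  if (is.null(correct)) {
    stopifnot(!is.null(predictions), !is.null(truth),
              length(predictions) == length(truth))
    n <- length(predictions)
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
    joint <- (match(truth, wd_classes) - 1L) * 3L +
      match(predictions, wd_classes)
    m <- boot_metrics_from_codes(joint, idx)
    out <- lapply(rownames(m), function(met) {
      q <- quantile(m[met, ], c(alpha, 1 - alpha), names = FALSE, type = 7)
      list(mean = mean(m[met, ]), lower = q[1], upper = q[2])
    })
    names(out) <- rownames(m)
  } else {
    correct <- as.numeric(correct)
    if (!length(correct)) stop("empty correctness vector", call. = FALSE)
    n <- length(correct)
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
    acc <- 100 * colMeans(matrix(correct[idx], nrow = n))
    q <- quantile(acc, c(alpha, 1 - alpha), names = FALSE, type = 7)
    out <- list(accuracy = list(mean = mean(acc), lower = q[1],
                                upper = q[2]))
  }
  c(out, list(n_resamples = n_resamples, seed = seed))
}
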