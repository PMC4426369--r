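#' Center a per-gene metric at zero
#'
#' Subtracts the global mean over all supplied genes (missing values are
#' ignored for the mean and preserved in the output).
#'
#' @param values Numeric vector with at least one finite value.
#' @return Centered values (mean 0 over the non-missing entries).
#' @export
center_metric <- function(values) {
  if (!any(is.finite(values))) stop("no finite metric values to center")
  values - mean(values, na.rm = TRUE)
}

#' Per-class metric summaries with percentile-bootstrap error bars
#'
#' For each class with at least two genes carrying the metric, reports the
#' class mean and a 95% percentile bootstrap confidence interval from
#' `n_boot` within-class resamples (genes resampled with replacement).
#' The bootstrap mean replicates are retained (attribute `boot`) so that
#' class differences can reuse the same resampling streams. Deterministic
#' given `seed`; classes are processed in sorted order.
#'
#' @param records data.frame with `class_label` and the metric column.
#' @param metric_name Name of the metric column (e.g. `"noise"`).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return A `class_summary` data.frame: `class_label`, `n`, `mean`,
#'   `ci_low`, `ci_high`, `boot_se`, `n_boot`, `seed`; attributes `boot`
#'   (n_boot x classes matrix of replicate means) and `metric`.
#' @export
class_metric_summary <- function(records, metric_name, n_boot = 10000L,
                                 seed = 1L, conf = 0.95) {
  stopifnot("class_label" %in% names(records),
            metric_name %in% names(records), n_boot >= 1L)
  alpha <- (1 - conf) / 2
  set.seed(seed)
  classes <- sort(unique(records$class_label))
  rows <- list()
  boot_mat <- matrix(numeric(), nrow = n_boot, ncol = 0L)
  for (cl in classes) {
    v <- records[[metric_name]][records$class_label == cl]
    v <- v[is.finite(v)]
    if (length(v) < 2L) {
      warning("class '", cl, "' has fewer than 2 genes with '", metric_name,
              "'; omitted")
      next
    }
    resamples <- matrix(sample(v, length(v) * n_boot, replace = TRUE),
                        nrow = length(v))
    boots <- colMeans(resamples)
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                          type = 7)
    rows[[cl]] <- data.frame(class_label = cl, n = length(v),
                             mean = mean(v), ci_low = qs[1], ci_high = qs[2],
                             boot_se = stats::sd(boots),
                             n_boot = n_boot, seed = seed)
    boot_mat <- cbind(boot_mat, boots)
    colnames(boot_mat)[ncol(boot_mat)] <- cl
  }
  if (!length(rows)) stop("no class with >= 2 genes carrying '",
                          metric_name, "'")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, boot = boot_mat, metric = metric_name, conf = conf,
            class = c("class_summary", "data.frame"))
}

#' Bootstrap comparison of a metric between two classes
#'
#' Difference of class means (`class_a - class_b`) with a percentile
#' bootstrap CI of the difference built from the paired resampling streams
#' stored in the summary (replicate `i` of class a is paired with replicate
#' `i` of class b), and a flag for whether the CI excludes zero.
#'
#' @param summaries A `class_summary` from [class_metric_summary()].
#' @param class_a,class_b Class labels to compare.
#' @return List: `metric`, `class_a`, `class_b`, `diff_mean`, `ci_low`,
#'   `ci_high`, `excludes_zero`.
#' @export
compare_classes <- function(summaries, class_a, class_b) {
  stopifnot(inherits(summaries, "class_summary"))
  boot <- attr(summaries, "boot")
  conf <- attr(summaries, "conf")
  for (cl in c(class_a, class_b)) {
    if (!cl %in% colnames(boot)) {
      stop("class '", cl, "' not present in the summary for metric '",
           attr(summaries, "metric"), "'")
    }
  }
  alpha <- (1 - conf) / 2
  diffs <- boot[, class_a] - boot[, class_b]
  qs <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  mean_a <- summaries$mean[summaries$class_label == class_a]
  mean_b <- summaries$mean[summaries$class_label == class_b]
  list(metric = attr(summaries, "metric"),
       class_a = class_a, class_b = class_b,
       diff_mean = mean_a - mean_b,
       ci_low = qs[1], ci_high = qs[2],
       excludes_zero = qs[1] > 0 || qs[2] < 0)
}
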