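#' Bootstrap comparison configuration
#'
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 2, for comparing the
#'   Gaussian-smoothed model against both baselines); the decision
#'   threshold is `alpha / n_comparisons` = 0.025 at the defaults.
#' @param seed Integer master seed for reproducibility.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, alpha = 0.05,
                             n_comparisons = 2L, seed = 1L) {
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (n_comparisons < 1L) stop("`n_comparisons` must be >= 1", call. = FALSE)
  structure(list(n_boot = n_boot, alpha = alpha,
                 n_comparisons = as.integer(n_comparisons),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Stratified bootstrap resample indices
#'
#' Samples with replacement within each true-grade stratum so that every
#' replicate preserves each class count exactly; output length equals input
#' length. Uses the current RNG state (callers seed it).
#'
#' @param y_true Integer vector of true grades; every present class must
#'   have at least one sample.
#' @return Integer index vector into `y_true`, grouped by stratum.
#' @export
stratified_resample_indices <- function(y_true) {
  if (length(y_true) == 0L) stop("empty grade vector", call. = FALSE)
  strata <- split(seq_along(y_true), y_true)
  if (any(lengths(strata) == 0L)) stop("empty stratum", call. = FALSE)
  unlist(lapply(strata, function(idx) {
    if (length(idx) == 1L) rep(idx, 1L)
    else sample(idx, length(idx), replace = TRUE)
  }), use.names = FALSE)
}

# Two-sided percentile bootstrap p with add-one smoothing, capped at 1.
.bootstrap_p <- function(deltas) {
  B <- length(deltas)
  p <- 2 * min(sum(deltas <= 0) + 1L, sum(deltas >= 0) + 1L) / (B + 1L)
  min(p, 1)
}

#' Paired stratified-bootstrap comparison of two models
#'
#' Compares two models' predictions on the same test set. In each of
#' `n_boot` replicates a single stratified index set (class counts
#' preserved exactly) is applied to both score tables — a paired design —
#' and the metric difference `delta = metric(A) - metric(B)` is recorded.
#' The two-sided percentile p-value with add-one smoothing is
#' `p = 2 * min(#{delta <= 0} + 1, #{delta >= 0} + 1) / (n_boot + 1)`,
#' capped at 1; a difference is declared significant when
#' `p < alpha / n_comparisons` (Bonferroni).
#'
#' Each replicate draws from its own pre-spawned seed sub-stream, so the
#' full report is reproducible from the master seed alone.
#'
#' @param tableA,tableB [score_table()]s sharing `ids` and `y_true`.
#' @param metrics Character vector of metric names to compare; any subset
#'   of `c("quad_kappa", "auroc", "precision", "recall", "f1", "mcc")`.
#' @param config A [bootstrap_config()].
#' @return An object of class `comparison_report`: a list with `config`,
#'   and per-metric rows `delta` (full-set A minus B), `delta_boot_mean`,
#'   `delta_boot_lo`/`delta_boot_hi` (2.5/97.5 percentiles), `p_value`,
#'   `significant`.
#' @export
bootstrap_compare <- function(tableA, tableB,
                              metrics = c("quad_kappa", "auroc", "precision",
                                          "recall", "f1", "mcc"),
                              config = bootstrap_config()) {
  stopifnot(inherits(tableA, "score_table"), inherits(tableB, "score_table"))
  if (length(tableA$y_true) != length(tableB$y_true) ||
      any(tableA$y_true != tableB$y_true) ||
      any(as.character(tableA$ids) != as.character(tableB$ids)))
    stop("tables are not paired: ids and true grades must match",
         call. = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)

  full_A <- evaluate_metrics(tableA)[metrics]
  full_B <- evaluate_metrics(tableB)[metrics]

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_boot)

  deltas <- matrix(NA_real_, nrow = config$n_boot, ncol = length(metrics),
                   dimnames = list(NULL, metrics))
  for (b in seq_len(config$n_boot)) {
    set.seed(rep_seeds[b])
    idx <- stratified_resample_indices(tableA$y_true)
    mA <- evaluate_metrics(.subset_table(tableA, idx))[metrics]
    mB <- evaluate_metrics(.subset_table(tableB, idx))[metrics]
    deltas[b, ] <- mA - mB
  }

  threshold <- config$alpha / config$n_comparisons
  rows <- lapply(metrics, function(m) {
    d <- deltas[, m]
    p <- .bootstrap_p(d)
    list(metric = m,
         delta = unname(full_A[m] - full_B[m]),
         delta_boot_mean = mean(d),
         delta_boot_lo = unname(stats::quantile(d, 0.025)),
         delta_boot_hi = unname(stats::quantile(d, 0.975)),
         p_value = p,
         significant = p < threshold)
  })
  names(rows) <- metrics
  structure(list(config = config, threshold = threshold,
                 metrics = rows, deltas = deltas),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$config$n_boot, "stratified replicates,",
      "threshold p <", format(x$threshold), "\n")
  for (r in x$metrics)
    cat(sprintf("  %-10s delta = %+.4f  p = %.4f %s\n", r$metric, r$delta,
                r$p_value, if (r$significant) "(significant)" else ""))
  invisible(x)
}
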