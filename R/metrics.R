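#' Per-sample score table
#'
#' The unit of evaluation: sample identifiers, true grades, a matrix of
#' per-grade scores, and the arg-max predicted grade. Arg-max ties break to
#' the lowest (least severe) grade index, deterministically.
#'
#' @param ids Sample identifiers (character or integer).
#' @param y_true Integer true grades in `0 .. K-1`.
#' @param scores `n x K` numeric matrix of per-grade scores.
#' @param K Number of grades; default inferred from `ncol(scores)`.
#' @return An object of class `score_table`: a list with `ids`, `y_true`,
#'   `scores`, `y_pred`, `K`.
#' @export
score_table <- function(ids, y_true, scores, K = ncol(scores)) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(ids) != n || length(y_true) != n)
    stop("`ids`, `y_true` and `scores` rows must have equal length",
         call. = FALSE)
  y_true <- as.integer(y_true)
  if (n > 0L && (anyNA(y_true) || any(y_true < 0L) || any(y_true >= K)))
    stop("`y_true` must lie in 0 .. K-1", call. = FALSE)
  y_pred <- if (n > 0L) max.col(scores, ties.method = "first") - 1L
            else integer(0)
  structure(list(ids = ids, y_true = y_true, scores = scores,
                 y_pred = y_pred, K = as.integer(K)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table>", length(x$y_true), "samples,", x$K, "grades\n")
  invisible(x)
}

.subset_table <- function(table, idx) {
  score_table(table$ids[idx], table$y_true[idx],
              table$scores[idx, , drop = FALSE], K = table$K)
}

#' Confusion matrix of a score table
#'
#' @param table A [score_table()], or an integer vector of true grades (in
#'   which case `y_pred` and `K` must be given).
#' @param y_pred Predicted grades, when `table` is a plain vector.
#' @param K Number of grades, when `table` is a plain vector.
#' @return `K x K` integer matrix; rows index the true grade, columns the
#'   predicted grade.
#' @export
confusion_matrix <- function(table, y_pred = NULL, K = NULL) {
  if (inherits(table, "score_table")) {
    y_true <- table$y_true; y_pred <- table$y_pred; K <- table$K
  } else {
    y_true <- as.integer(table)
  }
  if (length(y_true) == 0L)
    stop("empty table: confusion matrix undefined", call. = FALSE)
  lv <- seq_len(K) - 1L
  cm <- base::table(factor(y_true, levels = lv),
                    factor(y_pred, levels = lv))
  matrix(as.integer(cm), nrow = K, ncol = K,
         dimnames = list(true = lv, pred = lv))
}

#' Quadratic weight matrix
#'
#' `w_ij = (i - j)^2 / (K - 1)^2`: zero on the diagonal, 1 at the corners.
#'
#' @param K Number of grades.
#' @return `K x K` symmetric numeric matrix.
#' @export
quadratic_weights <- function(K) {
  i <- seq_len(K) - 1L
  outer(i, i, function(a, b) (a - b)^2) / (K - 1)^2
}

#' Quadratic-weighted kappa
#'
#' Chance-corrected agreement penalizing disagreements by the squared grade
#' distance: `kappa = 1 - sum(w * O) / sum(w * E)`, with `O` the observed
#' proportion matrix and `E` the outer product of its marginals. The
#' standard agreement statistic for ordinal grading tasks, where errors by
#' distant grades matter more than neighbor confusions.
#'
#' @param cm A `K x K` confusion matrix of counts (rows = true grades).
#' @return Kappa in `[-1, 1]`, or `NA` with a warning when both marginals
#'   are concentrated in a single identical class, which leaves the
#'   expected disagreement (the denominator) zero.
#' @export
quadratic_weighted_kappa <- function(cm) {
  cm <- as.matrix(cm)
  K <- nrow(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  O <- cm / total
  E <- outer(rowSums(O), colSums(O))
  w <- quadratic_weights(K)
  denom <- sum(w * E)
  if (denom == 0) {
    warning("degenerate marginals: expected weighted disagreement is zero; ",
            "quadratic-weighted kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum(w * O) / denom
}

#' Support-weighted precision, recall and F1
#'
#' Per-class precision, recall and F1 averaged with weights equal to each
#' class's true support (normalized). Classes with no predicted samples
#' contribute a precision of 0 (and analogously for recall/F1 with
#' zero-denominator ratios), with a warning.
#'
#' @param cm `K x K` confusion matrix (rows = true grades).
#' @return Named numeric vector `c(precision, recall, f1)`, each in
#'   `[0, 1]`.
#' @export
weighted_prf <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  support <- rowSums(cm)      # true counts per class
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  if (any(predicted == 0 & support > 0))
    warning("class with zero predicted samples: its precision counts 0",
            call. = FALSE)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / total
  c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Multiclass Matthews correlation coefficient
#'
#' Correlation-style summary of a `K x K` confusion matrix, robust under
#' class imbalance: covariance of truth and prediction over the geometric
#' mean of the marginal variances. Reduces to the familiar binary MCC at
#' `K = 2`. Returns 0 (with a warning) when a marginal variance vanishes,
#' e.g. when all predictions fall in one class.
#'
#' @param cm `K x K` confusion matrix (rows = true grades).
#' @return MCC in `[-1, 1]`.
#' @export
multiclass_mcc <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  if (s <= 0) stop("empty confusion matrix", call. = FALSE)
  c0 <- sum(diag(cm))
  t_k <- rowSums(cm)   # true counts
  p_k <- colSums(cm)   # predicted counts
  num <- c0 * s - sum(p_k * t_k)
  d1 <- s^2 - sum(p_k^2)
  d2 <- s^2 - sum(t_k^2)
  if (d1 <= 0 || d2 <= 0) {
    warning("degenerate marginal: MCC set to 0 by convention", call. = FALSE)
    return(0)
  }
  num / sqrt(d1 * d2)
}

# Rank-based (Mann-Whitney) AUROC of `pos_scores` vs `neg_scores`;
# ties count 0.5.
.rank_auc <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pairwise-averaged multiclass AUROC
#'
#' The multiclass AUROC extension that considers each possible class pair
#' (the Hand-Till construction): for every unordered pair `(i, j)` present
#' in the data, the rank-based AUROC of class `i`'s score among samples
#' truly in `{i, j}` is averaged with its mirror for class `j`, and these
#' pair values are averaged over all present pairs. Ties count 0.5. Only
#' pairs with both classes present contribute; stratified resampling keeps
#' all classes present in the main protocol.
#'
#' @param table A [score_table()].
#' @return AUROC in `[0, 1]`, or `NA` with a warning when fewer than two
#'   classes are present.
#' @export
pairwise_average_auroc <- function(table) {
  stopifnot(inherits(table, "score_table"))
  present <- sort(unique(table$y_true))
  if (length(present) < 2L) {
    warning("fewer than two classes present: AUROC undefined", call. = FALSE)
    return(NA_real_)
  }
  pairs <- utils::combn(present, 2L)
  vals <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    in_i <- table$y_true == i
    in_j <- table$y_true == j
    a_ij <- .rank_auc(table$scores[in_i, i + 1L],
                      table$scores[in_j, i + 1L])
    a_ji <- .rank_auc(table$scores[in_j, j + 1L],
                      table$scores[in_i, j + 1L])
    (a_ij + a_ji) / 2
  })
  mean(vals)
}

#' All evaluation metrics of the grading protocol
#'
#' Computes the six-metric panel used throughout: quadratic-weighted kappa,
#' pairwise-averaged multiclass AUROC, support-weighted precision, recall
#' and F1, and multiclass MCC.
#'
#' @param table A [score_table()].
#' @return Named numeric vector with elements `quad_kappa`, `auroc`,
#'   `precision`, `recall`, `f1`, `mcc`.
#' @export
evaluate_metrics <- function(table) {
  cm <- confusion_matrix(table)
  prf <- suppressWarnings(weighted_prf(cm))
  c(quad_kappa = suppressWarnings(quadratic_weighted_kappa(cm)),
    auroc = suppressWarnings(pairwise_average_auroc(table)),
    precision = unname(prf["precision"]),
    recall = unname(prf["recall"]),
    f1 = unname(prf["f1"]),
    mcc = suppressWarnings(multiclass_mcc(cm)))
}
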