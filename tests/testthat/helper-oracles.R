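# Independent brute-force/definitional implementations used as oracles.
# These deliberately mirror the textbook definitions (explicit loops,
# per-sample arithmetic) rather than the package's vectorized code paths.

# Closed-form decay factor: P(|Z| <= 1.5/sigma) = m  =>  sigma = 1.5 / z
oracle_sigma <- function(neighbor_mass) {
  1.5 / qnorm((1 + neighbor_mass) / 2)
}

# Definitional quadratic-weighted kappa: explicit double loop.
oracle_kappa <- function(cm) {
  K <- nrow(cm)
  n <- sum(cm)
  O <- cm / n
  rmar <- rowSums(O); cmar <- colSums(O)
  num <- 0; den <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w <- (i - j)^2 / (K - 1)^2
    num <- num + w * O[i, j]
    den <- den + w * rmar[i] * cmar[j]
  }
  unname(1 - num / den)
}

# Support-weighted precision/recall/F1 from explicit per-class TP/FP/FN.
oracle_prf <- function(cm) {
  K <- nrow(cm)
  n <- sum(cm)
  prec <- rec <- f1 <- w <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    w[k] <- (tp + fn) / n
  }
  c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

# Multiclass MCC as the Pearson correlation between the one-hot indicator
# expansions of truth and prediction, summed over classes.
oracle_mcc <- function(cm) {
  K <- nrow(cm)
  n <- sum(cm)
  # reconstruct per-sample label pairs from the counts
  yt <- rep(rep(seq_len(K), each = K), times = as.vector(t(cm)))
  yp <- rep(rep(seq_len(K), times = K), times = as.vector(t(cm)))
  X <- outer(yt, seq_len(K), `==`) * 1
  Y <- outer(yp, seq_len(K), `==`) * 1
  cov_xy <- sum(diag(crossprod(scale(X, scale = FALSE),
                               scale(Y, scale = FALSE))))
  cov_xx <- sum(diag(crossprod(scale(X, scale = FALSE))))
  cov_yy <- sum(diag(crossprod(scale(Y, scale = FALSE))))
  if (cov_xx <= 0 || cov_yy <= 0) return(0)
  cov_xy / sqrt(cov_xx * cov_yy)
}

# Binary MCC from the TP/TN/FP/FN arithmetic (class 1 treated as positive).
oracle_mcc_binary <- function(cm) {
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Hand-Till pairwise AUROC by exhaustive cross-class pair counting:
# concordant pairs count 1, ties 0.5.
oracle_auroc <- function(table) {
  present <- sort(unique(table$y_true))
  pair_vals <- c()
  for (a in seq_along(present)) for (b in seq_along(present)) {
    if (b <= a) next
    i <- present[a]; j <- present[b]
    xi <- which(table$y_true == i)
    xj <- which(table$y_true == j)
    auc_dir <- function(col, pos, neg) {
      tot <- 0
      for (p in pos) for (q in neg) {
        sp <- table$scores[p, col]; sq <- table$scores[q, col]
        tot <- tot + (sp > sq) + 0.5 * (sp == sq)
      }
      tot / (length(pos) * length(neg))
    }
    a_ij <- auc_dir(i + 1L, xi, xj)
    a_ji <- auc_dir(j + 1L, xj, xi)
    pair_vals <- c(pair_vals, (a_ij + a_ji) / 2)
  }
  mean(pair_vals)
}

# Random test-case generators -------------------------------------------

random_confusion <- function(K, n) {
  y_true <- sample.int(K, n, replace = TRUE) - 1L
  y_pred <- sample.int(K, n, replace = TRUE) - 1L
  confusion_matrix(y_true, y_pred = y_pred, K = K)
}

random_score_table <- function(K, n, informative = FALSE) {
  y <- sample.int(K, n, replace = TRUE) - 1L
  # ensure at least two classes present
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, K - 1L)
  raw <- matrix(runif(n * K), n, K)
  if (informative) raw <- raw + 2 * outer(y, seq_len(K) - 1L,
                                          function(a, b) a == b)
  # occasional exact ties to exercise the 0.5 convention
  raw <- round(raw, 2)
  score_table(paste0("s", seq_len(n)), y, raw / rowSums(raw), K = K)
}
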