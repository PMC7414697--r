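#' Softmax normalization of score vectors
#'
#' Maps unnormalized scores to probabilities with the exponential
#' normalization map, row-wise for matrices. Numerically stabilized by
#' subtracting the row maximum.
#'
#' @param z Numeric vector of length `K`, or an `n x K` matrix of scores.
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Soft-target cross-entropy
#'
#' `-sum_k q_k log(p_k)` between a predicted probability vector `p` and a
#' (possibly unnormalized) soft label `q`. The loss is linear in `q`, so
#' unnormalized Gaussian-smoothed corner labels are accepted as-is, without
#' rescaling. With a one-hot `q` this reduces to the standard cross-entropy
#' `-log(p_g)`.
#'
#' @param p Numeric probability vector (length `K`). Entries are clamped at
#'   `eps` before taking logs.
#' @param q Numeric soft-label vector of the same length.
#' @param eps Lower clamp for `p`, default `1e-12`.
#' @return Non-negative scalar loss (for normalized `q`).
#' @export
#' @examples
#' soft_cross_entropy(c(0.7, 0.2, 0.1), c(1, 0, 0))  # == -log(0.7)
soft_cross_entropy <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q))
    stop("`p` and `q` must have the same length", call. = FALSE)
  -sum(q * log(pmax(p, eps)))
}

#' Batch soft cross-entropy
#'
#' @param ps `n x K` matrix of predicted probabilities (rows are samples).
#' @param qs `n x K` matrix of soft labels.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @param eps Lower clamp for probabilities.
#' @return Reduced scalar loss.
#' @export
batch_loss <- function(ps, qs, reduction = c("mean", "sum"), eps = 1e-12) {
  reduction <- match.arg(reduction)
  ps <- as.matrix(ps); qs <- as.matrix(qs)
  if (!all(dim(ps) == dim(qs)))
    stop("`ps` and `qs` must have identical dimensions", call. = FALSE)
  if (nrow(ps) == 0L)
    stop("empty batch: the reduced loss is undefined", call. = FALSE)
  per_sample <- -rowSums(qs * log(pmax(ps, eps)))
  switch(reduction, mean = mean(per_sample), sum = sum(per_sample))
}
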