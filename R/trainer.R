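#' Training configuration
#'
#' Optimization conventions for the small classifier harness: plain
#' mini-batch stochastic gradient descent at learning rate 0.001 with batch
#' size 8, early-stopped on the validation loss.
#'
#' @param learning_rate SGD step size (default 0.001).
#' @param batch_size Mini-batch size (default 8).
#' @param max_epochs Upper bound on epochs (default 30).
#' @param patience Epochs without validation improvement tolerated before
#'   stopping (default 5); must not exceed `max_epochs`.
#' @param label_scheme A [smoothing_config()] applied to the *training*
#'   annotations only; validation and test always use hard grades.
#' @param model_kind `"linear"` or `"small_net"`.
#' @param seed Integer seed for batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8L,
                         max_epochs = 30L, patience = 5L,
                         label_scheme = smoothing_config("hard"),
                         model_kind = c("linear", "small_net"),
                         seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (learning_rate <= 0 || batch_size < 1L || max_epochs < 1L)
    stop("rates and sizes must be positive", call. = FALSE)
  if (patience > max_epochs)
    stop("`patience` must not exceed `max_epochs`", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 label_scheme = label_scheme, model_kind = model_kind,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a small parametric scorer
#'
#' `"linear"` is an affine map from features to `K` unnormalized scores
#' (`d*K + K` parameters). `"small_net"` stacks one tanh hidden layer
#' between two affine maps; for image inputs a fixed block-mean pooling
#' stage (from `image_size^2` flattened pixels down to `pool_to^2`) is
#' prepended, so the net sees coarse lesion density rather than raw pixels.
#' Scores are turned into probabilities with [softmax()] at prediction
#' time. Initialization is seeded and deterministic.
#'
#' @param model_kind `"linear"` or `"small_net"`.
#' @param input_dim Number of input features (pixels for images).
#' @param K Number of grades.
#' @param hidden Hidden width for `"small_net"` (default 32).
#' @param image_size Optional image side length; when given, flattened
#'   image inputs are mean-pooled before the affine stack.
#' @param pool_to Pooled side length (default 8).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ord_model`.
#' @export
build_model <- function(model_kind = c("linear", "small_net"),
                        input_dim, K, hidden = 32L,
                        image_size = NULL, pool_to = 8L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (input_dim < 1L) stop("invalid input shape", call. = FALSE)
  set.seed(seed)
  pool <- NULL
  d <- input_dim
  if (!is.null(image_size)) {
    pool <- .pool_matrix(image_size, pool_to)
    d <- ncol(pool)
  }
  sdv <- 0.1 / sqrt(d)
  params <- if (model_kind == "linear") {
    list(W = matrix(stats::rnorm(d * K, sd = sdv), d, K), b = numeric(K))
  } else {
    list(W1 = matrix(stats::rnorm(d * hidden, sd = sdv), d, hidden),
         b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(hidden * K, sd = 0.1 / sqrt(hidden)),
                     hidden, K),
         b2 = numeric(K))
  }
  structure(list(kind = model_kind, K = as.integer(K),
                 input_dim = as.integer(input_dim), pool = pool,
                 params = params),
            class = "ord_model")
}

# Block-mean pooling as a fixed linear map: (size^2) x (pool_to^2).
.pool_matrix <- function(size, pool_to) {
  stopifnot(size >= pool_to)
  block <- size / pool_to
  P <- matrix(0, size^2, pool_to^2)
  for (px in seq_len(pool_to)) for (py in seq_len(pool_to)) {
    xs <- which(ceiling(seq_len(size) / block) == px)
    ys <- which(ceiling(seq_len(size) / block) == py)
    cells <- as.vector(outer(xs, ys, function(x, y) (y - 1L) * size + x))
    P[cells, (py - 1L) * pool_to + px] <- 1 / length(cells)
  }
  P
}

.model_input <- function(model, X) {
  X <- if (is.null(model$pool)) X else X %*% model$pool
  if (!is.null(model$scaler))
    X <- sweep(sweep(X, 2L, model$scaler$center), 2L, model$scaler$scale, `/`)
  X
}

# Column-wise standardization fitted on the training inputs (after any
# pooling); constant columns are left unscaled.
.fit_scaler <- function(X) {
  s <- apply(X, 2L, stats::sd)
  list(center = colMeans(X), scale = ifelse(s > 0, s, 1))
}

# Forward pass to unnormalized scores; returns list(Z, H) (H NULL for linear).
.forward <- function(model, X) {
  p <- model$params
  if (model$kind == "linear") {
    list(Z = sweep(X %*% p$W, 2L, p$b, `+`), H = NULL)
  } else {
    H <- tanh(sweep(X %*% p$W1, 2L, p$b1, `+`))
    list(Z = sweep(H %*% p$W2, 2L, p$b2, `+`), H = H)
  }
}

# Gradient of mean soft-CE over the batch w.r.t. all parameters.
# d/dZ of -sum_k q_k log softmax(z)_k is sum(q) * p - q.
.gradients <- function(model, X, Q, fw) {
  m <- nrow(X)
  P <- softmax(fw$Z)
  G <- (P * rowSums(Q) - Q) / m
  p <- model$params
  if (model$kind == "linear") {
    list(W = crossprod(X, G), b = colSums(G))
  } else {
    dH <- G %*% t(p$W2)
    dA <- dH * (1 - fw$H^2)
    list(W1 = crossprod(X, dA), b1 = colSums(dA),
         W2 = crossprod(fw$H, G), b2 = colSums(G))
  }
}

#' Fit the classifier with mini-batch SGD and early stopping
#'
#' Minimizes the batch soft cross-entropy of the configured label scheme
#' applied to the (noisy) training annotations. After each epoch the mean
#' cross-entropy against hard validation labels is monitored; training
#' stops once it has failed to improve for more than `patience` epochs, and
#' the parameters from the best epoch are returned. Smoothing is an
#' optimization device only — assessment always uses hard grades.
#'
#' Inputs (after any pooling stage) are standardized column-wise with a
#' scaler fitted on the training split and stored in the fitted model, so
#' from-scratch SGD at the default learning rate makes progress regardless
#' of the raw feature scale.
#'
#' @param model An [build_model()] scorer.
#' @param x_train,y_train Training features (matrix) and integer grades.
#' @param x_val,y_val Validation features and integer grades.
#' @param config A [train_config()].
#' @return An object of class `fitted_model`: the model with updated
#'   parameters plus `history` (data frame of per-epoch train loss and
#'   validation loss), `best_epoch`, `stopped_epoch`, `config`.
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        config = train_config()) {
  stopifnot(inherits(model, "ord_model"), inherits(config, "train_config"))
  if (nrow(x_train) == 0L || nrow(x_val) == 0L)
    stop("train and validation splits must be non-empty", call. = FALSE)
  K <- model$K
  if (is.null(model$scaler)) {
    raw <- as.matrix(x_train)
    model$scaler <- .fit_scaler(if (is.null(model$pool)) raw
                                else raw %*% model$pool)
  }
  Xtr <- .model_input(model, as.matrix(x_train))
  Xva <- .model_input(model, as.matrix(x_val))
  Qtr <- encode_batch(y_train, K, config$label_scheme)
  Qva <- encode_batch(y_val, K, smoothing_config("hard"))

  set.seed(config$seed)
  n <- nrow(Xtr)
  best <- Inf; best_params <- model$params; best_epoch <- 0L
  bad <- 0L
  hist_train <- hist_val <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      Xb <- Xtr[idx, , drop = FALSE]
      Qb <- Qtr[idx, , drop = FALSE]
      fw <- .forward(model, Xb)
      loss <- batch_loss(softmax(fw$Z), Qb)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d; learning rate too high?",
                     epoch), call. = FALSE)
      epoch_loss <- epoch_loss + loss * length(idx)
      gr <- .gradients(model, Xb, Qb, fw)
      for (nm in names(gr))
        model$params[[nm]] <- model$params[[nm]] - config$learning_rate * gr[[nm]]
    }
    hist_train <- c(hist_train, epoch_loss / n)
    val_loss <- batch_loss(softmax(.forward(model, Xva)$Z), Qva)
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best) {
      best <- val_loss; best_params <- model$params; best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > config$patience) break
    }
  }
  model$params <- best_params
  structure(c(unclass(model),
              list(history = data.frame(epoch = seq_along(hist_train),
                                        train_loss = hist_train,
                                        val_loss = hist_val),
                   best_epoch = best_epoch,
                   stopped_epoch = length(hist_train),
                   config = config)),
            class = c("fitted_model", "ord_model"))
}

#' Predicted score table
#'
#' Runs the (fitted) model over features and returns probability-normalized
#' scores as a [score_table()]. Deterministic.
#'
#' @param model An `ord_model` (typically a `fitted_model`).
#' @param features Feature matrix.
#' @param ids Sample identifiers.
#' @param y_true Integer true grades recorded alongside the scores.
#' @return A [score_table()].
#' @export
predict_scores <- function(model, features, ids, y_true) {
  features <- as.matrix(features)
  if (ncol(features) != model$input_dim)
    stop("feature dimension does not match the model input shape",
         call. = FALSE)
  X <- .model_input(model, features)
  probs <- if (nrow(X) == 0L) matrix(0, 0L, model$K)
           else softmax(.forward(model, X)$Z)
  colnames(probs) <- paste0("score_", seq_len(model$K) - 1L)
  score_table(ids, y_true, probs, K = model$K)
}
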