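#' Ordinal grade scale
#'
#' A grade scale is the ordered set of `K` disease severity grades, indexed
#' `0 .. K-1` in increasing severity (for diabetic retinopathy: 0 = no DR
#' through 4 = proliferative DR). Distance between grades `i` and `j` is
#' `|i - j|` grade units.
#'
#' @param K Positive integer number of grades, at least 2.
#' @return An object of class `grade_scale` with element `K`.
#' @export
#' @examples
#' grade_scale(5)
grade_scale <- function(K = 5L) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 2L)
    stop("`K` must be a single integer >= 2", call. = FALSE)
  structure(list(K = K), class = "grade_scale")
}

#' @export
print.grade_scale <- function(x, ...) {
  cat("<grade_scale> K =", x$K, "(grades 0 ..", x$K - 1L, ")\n")
  invisible(x)
}

.scale_K <- function(scale) {
  if (inherits(scale, "grade_scale")) return(scale$K)
  K <- as.integer(scale)
  if (length(K) != 1L || is.na(K) || K < 2L)
    stop("`scale` must be a grade_scale or a single integer K >= 2",
         call. = FALSE)
  K
}

.check_grade <- function(grade, K) {
  if (length(grade) != 1L || is.na(grade) || grade != as.integer(grade) ||
      grade < 0L || grade >= K)
    stop(sprintf("grade %s out of range 0 .. %d", format(grade), K - 1L),
         call. = FALSE)
  as.integer(grade)
}

#' Label smoothing configuration
#'
#' Bundles the choice of labelling scheme and its parameters. Three schemes
#' are supported: `"hard"` (one-hot), `"uls"` (uniform label smoothing with
#' weight `alpha`) and `"nuls"` (non-uniform Gaussian smoothing whose decay
#' factor `sigma` is chosen so that a fraction `neighbor_mass` of the
#' probability mass falls on the true grade and its two immediate
#' neighbors).
#'
#' @param scheme One of `"hard"`, `"uls"`, `"nuls"`.
#' @param alpha Smoothing weight in `[0, 1)` for the uniform scheme.
#' @param neighbor_mass Target mass within the true grade and its two
#'   immediate neighbors for the Gaussian scheme, in `(0, 1)`. Default 0.95.
#' @param sigma Optional explicit Gaussian decay factor (standard deviation,
#'   in grade units). When `NULL` it is derived from `neighbor_mass` via
#'   [sigma_for_neighbor_mass()].
#' @param renormalize Logical; rescale Gaussian labels at the corner grades
#'   to sum to 1. Default `FALSE` (unnormalized), which keeps the degree of
#'   truth at the annotated grade constant across all grades.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(scheme = c("hard", "uls", "nuls"),
                             alpha = 0.1,
                             neighbor_mass = 0.95,
                             sigma = NULL,
                             renormalize = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("`alpha` must be in [0, 1)", call. = FALSE)
  if (!is.numeric(neighbor_mass) || length(neighbor_mass) != 1L ||
      neighbor_mass <= 0 || neighbor_mass >= 1)
    stop("`neighbor_mass` must be in (0, 1)", call. = FALSE)
  if (!is.null(sigma) && (!is.numeric(sigma) || length(sigma) != 1L ||
                          sigma <= 0))
    stop("`sigma` must be a positive number", call. = FALSE)
  structure(list(scheme = scheme, alpha = alpha,
                 neighbor_mass = neighbor_mass, sigma = sigma,
                 renormalize = isTRUE(renormalize)),
            class = "smoothing_config")
}

#' One-hot (hard) label
#'
#' @param grade Grade index in `0 .. K-1`.
#' @param scale A [grade_scale()] or the integer `K`.
#' @return Numeric length-`K` vector with 1 at `grade`, 0 elsewhere.
#' @export
#' @examples
#' one_hot_encode(2, 5)
one_hot_encode <- function(grade, scale = grade_scale(5L)) {
  K <- .scale_K(scale)
  g <- .check_grade(grade, K)
  out <- numeric(K)
  out[g + 1L] <- 1
  out
}

#' Uniformly smoothed (ULS) label
#'
#' Convex mixture of the one-hot label with the uniform distribution over
#' all `K` grades: the true grade receives `(1 - alpha) + alpha / K` and
#' every other grade `alpha / K`, so entries always sum to 1.
#'
#' @inheritParams one_hot_encode
#' @param alpha Smoothing weight in `[0, 1)`.
#' @return Numeric length-`K` probability vector.
#' @export
#' @examples
#' uls_encode(2, 5, alpha = 0.1)
uls_encode <- function(grade, scale = grade_scale(5L), alpha = 0.1) {
  K <- .scale_K(scale)
  g <- .check_grade(grade, K)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("`alpha` must be in [0, 1)", call. = FALSE)
  out <- rep(alpha / K, K)
  out[g + 1L] <- out[g + 1L] + (1 - alpha)
  out
}

#' Decay factor from a neighbor-mass target
#'
#' Solves for the standard deviation `sigma` of a grade-centred Gaussian
#' such that exactly `neighbor_mass` of its probability mass lies within
#' `[-1.5, +1.5]` grade units, i.e. within the three unit bins covering the
#' true grade and its two immediate neighbors. Solved by root bracketing on
#' `[1e-6, 50]` to absolute tolerance 1e-10.
#'
#' @param neighbor_mass Target mass in `(0, 1)`; the default 0.95 places 95%
#'   of the mass on the true grade and its neighbors.
#' @return Positive numeric `sigma` in grade units (about 0.76532 for 0.95).
#' @export
#' @examples
#' sigma_for_neighbor_mass(0.95)
sigma_for_neighbor_mass <- function(neighbor_mass = 0.95) {
  if (!is.numeric(neighbor_mass) || length(neighbor_mass) != 1L ||
      is.na(neighbor_mass) || neighbor_mass <= 0 || neighbor_mass >= 1)
    stop("`neighbor_mass` must be in (0, 1)", call. = FALSE)
  f <- function(sigma)
    stats::pnorm(1.5 / sigma) - stats::pnorm(-1.5 / sigma) - neighbor_mass
  stats::uniroot(f, interval = c(1e-6, 50), tol = 1e-10)$root
}

.resolve_sigma <- function(config) {
  if (!is.null(config$sigma)) config$sigma
  else sigma_for_neighbor_mass(config$neighbor_mass)
}

#' Non-uniformly (Gaussian) smoothed label
#'
#' Replaces the hard annotation by a Gaussian centred at the annotated
#' grade: the entry for grade `j` is the mass of `Normal(grade, sigma^2)`
#' integrated over the unit bin `[j - 0.5, j + 0.5]`. With the default
#' `neighbor_mass = 0.95` the true grade and its two immediate neighbors
#' carry exactly 95% of the mass. By default the label is left
#' unnormalized, so corner grades (0 and `K-1`) have some missing
#' probability beyond the scale boundary while the degree of truth at the
#' annotated grade stays constant across all grades; `renormalize = TRUE`
#' rescales entries to sum to 1 instead.
#'
#' @inheritParams one_hot_encode
#' @param config A [smoothing_config()]; only `neighbor_mass`, `sigma` and
#'   `renormalize` are used.
#' @return Numeric length-`K` vector of non-negative masses.
#' @export
#' @examples
#' nuls_encode(2, 5)                       # interior grade, sums to < 1
#' nuls_encode(0, 5)                       # corner grade, more mass missing
#' nuls_encode(0, 5, smoothing_config("nuls", renormalize = TRUE))
nuls_encode <- function(grade, scale = grade_scale(5L),
                        config = smoothing_config("nuls")) {
  K <- .scale_K(scale)
  g <- .check_grade(grade, K)
  sigma <- .resolve_sigma(config)
  edges <- seq(-0.5, K - 0.5, by = 1)
  mass <- diff(stats::pnorm(edges, mean = g, sd = sigma))
  if (isTRUE(config$renormalize)) mass <- mass / sum(mass)
  mass
}

#' Encode a batch of grades under a labelling scheme
#'
#' @param grades Integer vector of grade indices in `0 .. K-1`.
#' @inheritParams one_hot_encode
#' @param config A [smoothing_config()] selecting the scheme.
#' @return Numeric matrix with one row per grade and `K` columns
#'   (`0 x K` for empty input).
#' @export
encode_batch <- function(grades, scale = grade_scale(5L),
                         config = smoothing_config("hard")) {
  K <- .scale_K(scale)
  if (!inherits(config, "smoothing_config"))
    stop("`config` must be a smoothing_config", call. = FALSE)
  n <- length(grades)
  out <- matrix(0, nrow = n, ncol = K,
                dimnames = list(NULL, paste0("mass_", seq_len(K) - 1L)))
  if (n == 0L) return(out)
  enc <- switch(config$scheme,
    hard = function(g) one_hot_encode(g, K),
    uls  = function(g) uls_encode(g, K, config$alpha),
    nuls = local({
      # resolve sigma once for the whole batch
      cfg <- config
      cfg$sigma <- .resolve_sigma(config)
      function(g) nuls_encode(g, K, cfg)
    }))
  for (i in seq_len(n)) {
    out[i, ] <- tryCatch(enc(grades[i]), error = function(e)
      stop(sprintf("element %d: %s", i, conditionMessage(e)), call. = FALSE))
  }
  out
}

#' Write smoothed labels to CSV
#'
#' Writes columns `id`, `true_grade`, `mass_0 .. mass_{K-1}`.
#'
#' @param grades Integer grade vector.
#' @param path Output CSV path.
#' @param ids Optional sample identifiers (default `s1 .. sn`).
#' @inheritParams encode_batch
#' @return The written data frame, invisibly.
#' @export
write_label_csv <- function(grades, path, scale = grade_scale(5L),
                            config = smoothing_config("hard"),
                            ids = NULL) {
  mass <- encode_batch(grades, scale, config)
  if (is.null(ids)) ids <- paste0("s", seq_along(grades))
  df <- data.frame(id = ids, true_grade = as.integer(grades),
                   mass, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
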