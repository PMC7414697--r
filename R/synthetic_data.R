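#' Reference DR screening grade counts
#'
#' Per-grade image counts from a large teleophthalmology diabetic
#' retinopathy screening programme, including the ungradable category and
#' the train/validation/test partition sizes. Shipped as a plain-text
#' fixture; used to derive the default grade prevalence profile of the
#' synthetic generator.
#'
#' @return Data frame with columns `category`, `grade`, `total`, `train`,
#'   `val`, `test`.
#' @export
screening_grade_counts <- function() {
  path <- system.file("extdata", "dr_screening_counts.csv",
                      package = "ordsmooth")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default grade prevalence profile
#'
#' The gradable-image counts of [screening_grade_counts()] renormalized to
#' a probability vector over the five DR grades (the ungradable row is
#' excluded, mirroring its absence from the train/val/test partition).
#' Heavily imbalanced: about 78% no-DR, under 1% severe DR.
#'
#' @return Numeric length-5 probability vector.
#' @export
default_prevalence <- function() {
  counts <- screening_grade_counts()
  gradable <- counts$total[!is.na(counts$grade)]
  gradable / sum(gradable)
}

#' Synthetic ordinal grading dataset configuration
#'
#' Describes a desk-scale stand-in for a fundus-grading dataset with the
#' statistical structure the smoothing method assumes: a latent severity
#' signal, heavily imbalanced grade prevalences, and annotator noise
#' concentrated on neighboring grades (two graders who disagree most often
#' do so by one grade).
#'
#' @param n_samples Total number of samples. The default 2667 yields about
#'   2000 training samples under the default 75/10/15 split.
#' @param K Number of grades (default 5).
#' @param prevalence Length-`K` probability vector of clean-grade
#'   prevalences; defaults to [default_prevalence()].
#' @param feature_mode `"vector"` (latent-severity feature vectors) or
#'   `"image"` (small synthetic fundus-like images with countable lesions).
#' @param feature_dim Dimensionality in vector mode (default 4).
#' @param image_size Side length in pixels in image mode (default 32).
#' @param severity_noise_sd Per-dimension Gaussian noise, in grade units,
#'   added to the latent severity in vector mode (default 1.0).
#' @param annotator_noise_rate Probability that a training annotation is
#'   perturbed away from the clean grade (default 0.3).
#' @param neighbor_bias Probability that a perturbation moves exactly one
#'   grade up or down rather than to a random distant grade (default 0.9).
#' @param split Train/validation/test proportions (default 0.75, 0.10,
#'   0.15).
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 2667L, K = 5L,
                             prevalence = default_prevalence(),
                             feature_mode = c("vector", "image"),
                             feature_dim = 4L, image_size = 32L,
                             severity_noise_sd = 1.0,
                             annotator_noise_rate = 0.3,
                             neighbor_bias = 0.9,
                             split = c(0.75, 0.10, 0.15),
                             seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  if (length(prevalence) != K || abs(sum(prevalence) - 1) > 1e-9 ||
      any(prevalence < 0))
    stop("`prevalence` must be a length-K probability vector", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-9 || length(split) != 3L)
    stop("`split` must be three proportions summing to 1", call. = FALSE)
  if (annotator_noise_rate < 0 || annotator_noise_rate > 1 ||
      neighbor_bias < 0 || neighbor_bias > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), K = as.integer(K),
                 prevalence = prevalence, feature_mode = feature_mode,
                 feature_dim = as.integer(feature_dim),
                 image_size = as.integer(image_size),
                 severity_noise_sd = severity_noise_sd,
                 annotator_noise_rate = annotator_noise_rate,
                 neighbor_bias = neighbor_bias,
                 split = split, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw clean grades from the prevalence profile
#'
#' @param config A [synthetic_config()].
#' @param n Number of draws; defaults to `config$n_samples`.
#' @return Integer grade vector. Uses the current RNG state.
#' @export
sample_grades <- function(config, n = config$n_samples) {
  sample.int(config$K, n, replace = TRUE, prob = config$prevalence) - 1L
}

# One synthetic fundus-like image: circular field, Poisson(1 + 3*grade)
# bright lesion blobs inside the mask, pixel noise, values clamped to [0,1].
.lesion_image <- function(grade, size, noise_sd = 0.05) {
  ctr <- (size + 1) / 2
  r <- size / 2 - 1
  xy <- expand.grid(x = seq_len(size), y = seq_len(size))
  mask <- matrix((xy$x - ctr)^2 + (xy$y - ctr)^2 <= r^2, size, size)
  img <- matrix(0.15, size, size) * mask
  n_lesions <- stats::rpois(1L, lambda = 1 + 3 * grade)
  if (n_lesions > 0L) {
    inside <- which(mask)
    pos <- sample(inside, n_lesions, replace = TRUE)
    px <- (pos - 1L) %% size + 1L
    py <- (pos - 1L) %/% size + 1L
    for (l in seq_len(n_lesions)) {
      bump <- outer(seq_len(size), seq_len(size), function(x, y)
        exp(-((x - px[l])^2 + (y - py[l])^2) / (2 * 1.2^2)))
      img <- img + 0.8 * bump
    }
  }
  img <- img + matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
  pmin(pmax(img * mask, 0), 1)
}

#' Generate features for clean grades
#'
#' Vector mode: each feature dimension is `grade + Normal(0,
#' severity_noise_sd^2)` with independent noise per dimension, so the mean
#' feature is an unbiased noisy read-out of the latent severity. Image
#' mode: a circular fundus-like field containing a Poisson(1 + 3 * grade)
#' number of small bright lesion blobs at random positions, plus pixel
#' noise, clamped to `[0, 1]` — the expected lesion count is strictly
#' increasing in grade.
#'
#' @param clean_grades Integer grade vector.
#' @param config A [synthetic_config()].
#' @return In vector mode an `n x feature_dim` matrix; in image mode an
#'   `n x image_size^2` matrix of flattened single-channel images.
#'   Uses the current RNG state.
#' @export
generate_features <- function(clean_grades, config) {
  n <- length(clean_grades)
  if (config$feature_mode == "vector") {
    d <- config$feature_dim
    noise <- matrix(stats::rnorm(n * d, sd = config$severity_noise_sd), n, d)
    matrix(clean_grades, n, d) + noise
  } else {
    size <- config$image_size
    t(vapply(clean_grades, function(g)
      as.numeric(.lesion_image(g, size)), numeric(size^2)))
  }
}

#' Apply neighbor-biased annotator noise
#'
#' Each label is independently perturbed with probability
#' `annotator_noise_rate`. A perturbation moves exactly one grade up or
#' down (direction uniform, reflected at the scale boundaries) with
#' probability `neighbor_bias`, and otherwise jumps to a uniformly random
#' non-neighbor grade — mimicking inter-observer disagreement, which
#' concentrates on adjacent severity stages.
#'
#' @param clean_grades Integer grade vector.
#' @param config A [synthetic_config()].
#' @return Integer vector of noisy grades in `0 .. K-1`. Uses the current
#'   RNG state.
#' @export
apply_annotator_noise <- function(clean_grades, config) {
  K <- config$K
  n <- length(clean_grades)
  noisy <- clean_grades
  hit <- stats::runif(n) < config$annotator_noise_rate
  for (i in which(hit)) {
    g <- clean_grades[i]
    if (stats::runif(1L) < config$neighbor_bias) {
      step <- if (stats::runif(1L) < 0.5) -1L else 1L
      cand <- g + step
      if (cand < 0L || cand >= K) cand <- g - step  # reflect at boundary
      noisy[i] <- cand
    } else {
      far <- setdiff(0:(K - 1L), c(g - 1L, g, g + 1L))
      noisy[i] <- if (length(far) == 0L) {
        cand <- g + if (stats::runif(1L) < 0.5) -1L else 1L
        if (cand < 0L || cand >= K) 2L * g - cand else cand
      } else if (length(far) == 1L) far else sample(far, 1L)
    }
  }
  noisy
}

#' Stratified train/validation/test split
#'
#' Stratifies by clean grade: within each class the (seeded, shuffled)
#' sample indices are floor-allocated to train, validation and test in the
#' configured proportions, with per-class remainders assigned in that
#' order. The result is disjoint and exhaustive.
#'
#' @param clean_grades Integer grade vector; every class needs >= 3
#'   samples.
#' @param config A [synthetic_config()].
#' @return Character vector (`"train"`, `"val"`, `"test"`) per sample.
#'   Uses the current RNG state.
#' @export
split_dataset <- function(clean_grades, config) {
  out <- character(length(clean_grades))
  for (g in sort(unique(clean_grades))) {
    idx <- which(clean_grades == g)
    if (length(idx) < 3L)
      stop(sprintf("class %d has %d samples; at least 3 needed per class",
                   g, length(idx)), call. = FALSE)
    idx <- sample(idx)  # seeded shuffle within class
    n_c <- length(idx)
    base <- floor(config$split * n_c)
    rem <- n_c - sum(base)
    if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
    lab <- rep(c("train", "val", "test"), times = base)
    out[idx] <- lab
  }
  out
}

#' Simulate a complete synthetic grading dataset
#'
#' Draws clean grades from the prevalence profile, generates features,
#' applies annotator noise to obtain the training annotations, and builds
#' the stratified split. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: list with `features`
#'   (matrix), `clean_grades`, `noisy_grades`, `split`, `ids`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  clean <- sample_grades(config)
  features <- generate_features(clean, config)
  noisy <- apply_annotator_noise(clean, config)
  split <- split_dataset(clean, config)
  structure(list(ids = paste0("s", seq_along(clean)),
                 features = features, clean_grades = clean,
                 noisy_grades = noisy, split = split, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", length(x$clean_grades), "samples,",
      x$config$K, "grades,", x$config$feature_mode, "features\n")
  cat("  split:", paste(names(table(x$split)), table(x$split),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}
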