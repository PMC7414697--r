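test_that("one-hot encoding puts all mass on the annotated grade", {
  expect_equal(one_hot_encode(2, 5), c(0, 0, 1, 0, 0))
  expect_equal(one_hot_encode(0, 5), c(1, 0, 0, 0, 0))
  expect_equal(one_hot_encode(4, grade_scale(5)), c(0, 0, 0, 0, 1))
  expect_error(one_hot_encode(4, 2), "out of range")
  expect_error(one_hot_encode(-1, 5), "out of range")
})

test_that("uniform smoothing mixes the hard label with a uniform over all K grades", {
  expect_equal(uls_encode(2, 5, alpha = 0), c(0, 0, 1, 0, 0))
  expect_equal(uls_encode(2, 5, alpha = 0.1), c(0.02, 0.02, 0.92, 0.02, 0.02))
  expect_equal(uls_encode(0, 5, alpha = 0.5), c(0.6, 0.1, 0.1, 0.1, 0.1))
  expect_error(uls_encode(2, 5, alpha = 1), "alpha")
  expect_error(uls_encode(2, 5, alpha = -0.1), "alpha")
  # unit sum for arbitrary alpha and grade
  for (a in c(0, 0.05, 0.3, 0.99)) for (g in 0:4)
    expect_equal(sum(uls_encode(g, 5, a)), 1, tolerance = 1e-12)
})

test_that("decay factor solves the neighbor-mass equation", {
  # closed-form oracle: sigma = 1.5 / qnorm((1 + m) / 2)
  for (m in c(0.5, 0.8, 0.9, 0.95, 0.99, 0.999))
    expect_equal(sigma_for_neighbor_mass(m), oracle_sigma(m),
                 tolerance = 1e-9)
  expect_equal(sigma_for_neighbor_mass(0.95), 0.76532, tolerance = 1e-4)
  # +-1.5 is about 3 sigma when sigma = 0.5 (the 0.9973 rule)
  expect_equal(sigma_for_neighbor_mass(0.9973002039367398), 0.5,
               tolerance = 1e-6)
  # larger neighbor mass -> tighter Gaussian
  masses <- seq(0.05, 0.95, by = 0.1)
  sigmas <- vapply(masses, sigma_for_neighbor_mass, numeric(1))
  expect_true(all(diff(sigmas) < 0))
  expect_error(sigma_for_neighbor_mass(1), "neighbor_mass")
})

test_that("Gaussian smoothing integrates unit bins and leaves corners unnormalized", {
  lab <- nuls_encode(2, 5)
  # frozen from the closed-form sigma + normal-CDF bin masses
  expect_equal(lab, c(0.02446, 0.23177, 0.48645, 0.23177, 0.02446),
               tolerance = 1e-4)
  # exactly 95% of the mass on the true grade and its two neighbors
  expect_equal(sum(lab[2:4]), 0.95, tolerance = 1e-9)
  # right tail truncated at the corner: total mass smaller than interior
  expect_lt(sum(nuls_encode(0, 5)), sum(nuls_encode(2, 5)))
  # degree of truth at the annotated grade constant across all grades
  peaks <- vapply(0:4, function(g) nuls_encode(g, 5)[g + 1], numeric(1))
  expect_true(all(abs(peaks - peaks[1]) < 1e-12))
  # renormalized variant sums to 1 everywhere
  cfg <- smoothing_config("nuls", renormalize = TRUE)
  for (g in 0:4) expect_equal(sum(nuls_encode(g, 5, cfg)), 1,
                              tolerance = 1e-12)
  expect_error(nuls_encode(7, 5), "out of range")
})

test_that("smoothed labels satisfy the scheme invariants", {
  for (g in 0:4) {
    lab <- nuls_encode(g, 5)
    # unnormalized mass bounded above by 1; interior grades retain at
    # least the neighbor mass, corners lose tail mass beyond the scale
    expect_lte(sum(lab), 1 + 1e-12)
    if (g %in% 1:3) expect_gte(sum(lab), 0.95 - 1e-12)
    else expect_gte(sum(lab), 0.7)
    # arg-max at the true grade, strictly decreasing away from it
    expect_equal(which.max(lab) - 1L, g)
    d <- abs(seq_along(lab) - 1L - g)
    by_dist <- tapply(lab, d, max)  # one value per distinct distance
    expect_true(all(diff(by_dist[order(as.integer(names(by_dist)))]) < 0))
    # symmetry about the true grade wherever both bins exist
    for (off in 1:4) {
      lo <- g - off; hi <- g + off
      if (lo >= 0 && hi <= 4)
        expect_equal(lab[lo + 1], lab[hi + 1], tolerance = 1e-12)
    }
  }
})

test_that("Gaussian smoothing collapses to one-hot as sigma shrinks", {
  cfg <- smoothing_config("nuls", sigma = 1e-4)
  for (g in 0:4)
    expect_lt(max(abs(nuls_encode(g, 5, cfg) - one_hot_encode(g, 5))), 1e-6)
})

test_that("batch encoding applies the scheme element-wise", {
  hard <- encode_batch(c(0, 2), 5, smoothing_config("hard"))
  expect_equal(unname(hard), rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 0)))
  empty <- encode_batch(integer(0), 5, smoothing_config("nuls"))
  expect_equal(dim(empty), c(0L, 5L))
  uls3 <- encode_batch(rep(1, 3), 5, smoothing_config("uls", alpha = 0.1))
  expect_true(all(uls3[1, ] == uls3[2, ]) && all(uls3[2, ] == uls3[3, ]))
  expect_error(encode_batch(c(1, 9), 5, smoothing_config("hard")),
               "element 2")
})

test_that("label export writes id, true_grade and per-grade mass columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_label_csv(c(0, 3), path, 5, smoothing_config("nuls"))
  back <- read.csv(path)
  expect_equal(names(back),
               c("id", "true_grade", paste0("mass_", 0:4)))
  expect_equal(back$true_grade, c(0L, 3L))
  expect_equal(back$mass_3[2], nuls_encode(3, 5)[4], tolerance = 1e-6)
})
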