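test_that("logistic maps implement the softmax model with shift invariance", {
  g <- grid_spec(4)
  set.seed(1)
  fm <- feature_map(matrix(rnorm(16 * 3), 16, 3), g)
  # zero parameters give uniform maps
  p0 <- logistic_maps(fm, logistic_params(matrix(0, 3, 3)))
  expect_true(all(abs(p0$values - 1 / 3) < 1e-12))
  # decision boundary: equal logits give (0.5, 0.5)
  fm1 <- feature_map(matrix(c(2, -2, 0, 1), 16, 1), g)
  pr <- logistic_maps(fm1, logistic_params(matrix(c(1, 1), 2, 1),
                                           c(0.5, 0.5)))
  expect_true(all(abs(pr$values - 0.5) < 1e-12))
  # shared shifts of omega and beta leave the maps unchanged
  om <- matrix(rnorm(6), 2, 3)
  be <- rnorm(2)
  base <- logistic_maps(fm, logistic_params(om, be))
  shift <- logistic_maps(fm, logistic_params(om + rep(c(3, 3), 3),
                                             be + 7))
  expect_equal(shift$values, base$values, tolerance = 1e-12)
  expect_error(logistic_maps(fm1, logistic_params(om, be)),
               "dimensionality")
})

test_that("variance parameters map to weights by the negative reciprocal", {
  vp <- variance_params(matrix(1, 2, 4))
  lp <- variance_to_logistic(vp)
  expect_true(all(lp$omega == -1))
  expect_true(all(lp$beta == 0))
  expect_error(variance_params(matrix(c(1, -1), 2, 2)), "positive")
  # one very large variance sends the corresponding weight to ~0
  vp2 <- variance_params(matrix(c(1e12, 1, 1, 1), 2, 2))
  expect_lt(abs(variance_to_logistic(vp2)$omega[1, 1]), 1e-11)
  # K = 2 maps depend only on the weight difference per component
  g <- grid_spec(3)
  set.seed(2)
  fm <- feature_map(matrix(abs(rnorm(9 * 2)), 9, 2), g)
  m1 <- logistic_maps(fm, variance_to_logistic(
    variance_params(rbind(c(4, 1), c(1, 4)))))
  delta <- -1 / c(4, 1) + 1 / c(1, 4)   # omega_1 - omega_2
  m2 <- logistic_maps(fm, logistic_params(matrix(c(delta, 0, 0), 2, 2,
                                                 byrow = TRUE)))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("cell-mean RGB features reproduce cell-wise constants", {
  g <- grid_spec(4)
  img <- array(0, dim = c(8, 8, 3))
  img[, , 1] <- 1
  f <- rgb_features(img, g)
  expect_true(all(f$values[, 1] == 1) && all(f$values[, 2:3] == 0))
  # image constant within each cell: features recover the constants
  vals <- matrix(runif(16), 4, 4)
  img2 <- array(0, dim = c(8, 8, 3))
  for (ch in 1:3) img2[, , ch] <- vals[rep(1:4, each = 2), rep(1:4, each = 2)]
  f2 <- rgb_features(img2, g)
  expect_equal(f2$values[, 2], as.numeric(t(vals)), tolerance = 1e-12)
  expect_error(rgb_features(matrix(0, 8, 8), g), "color image")
})

test_that("orientation-energy features peak at the grating orientation", {
  S <- 64
  xg <- outer(rep(1, S), seq_len(S))
  yg <- outer(seq_len(S), rep(1, S))
  for (theta in c(0, 40, 125)) {
    grat <- sin(2 * pi * 8 / S * (cos(theta * pi / 180) * xg +
                                    sin(theta * pi / 180) * yg))
    f <- orientation_energy_features(grat, grid_spec(4),
                                     n_orientations = 36, n_scales = 3)
    expect_true(all(f$values >= 0))
    peak_band <- apply(f$values, 1, which.max)
    expected <- (round(theta / 5) %% 36) + 1
    # within one 5-degree band of the grating orientation, in every cell
    band_dist <- pmin(abs(peak_band - expected), 36 - abs(peak_band - expected))
    expect_true(all(band_dist <= 1))
  }
  expect_error(orientation_energy_features(matrix(0, 8, 10), grid_spec(4)),
               "square")
})

test_that("white noise has an approximately flat orientation profile", {
  set.seed(7)
  img <- matrix(rnorm(256 * 256), 256, 256)
  f <- orientation_energy_features(img, grid_spec(4), n_orientations = 36,
                                   n_scales = 4)
  profile <- colMeans(f$values)
  cv <- stats::sd(profile) / mean(profile)
  expect_lt(cv, 0.2)
})

test_that("the parametric fit recovers maps generated from the model", {
  g <- grid_spec(10)
  hot <- sample_probmaps(g, 3, uncertainty_profile(level = 0), seed = 71)
  lab <- as.integer(t(to_segmentation(hot)$labels))
  centers <- rbind(c(0.8, 0.2, 0.2), c(0.2, 0.8, 0.2), c(0.2, 0.2, 0.8))
  set.seed(72)
  X <- centers[lab, ] + matrix(rnorm(300, 0, 0.08), 100, 3)
  fm <- feature_map(X, g)
  gen <- logistic_maps(fm, logistic_params(8 * centers))
  ps <- schedule_pairs(g, 3, seed = 73)
  ds <- simulate_responses(gen, ps, 10, seed = 74)
  fit <- fit_parametric(ds, fm, 3, seed = 2)
  expect_true(fit$converged)
  expect_lt(mean_absolute_error(fit$maps, gen), 0.15)
  # the fitted weights separate the three clusters in feature space:
  # each cluster's own logit is the largest at its centroid
  logits <- centers %*% t(fit$params$omega) +
    rep(fit$params$beta, each = 3)
  perm <- align_labels(fit$maps, gen)
  expect_equal(apply(logits, 1, which.max)[order(perm)], 1:3,
               ignore_attr = TRUE)
})

test_that("recovery error decreases with the number of blocks", {
  g <- grid_spec(8)
  hot <- sample_probmaps(g, 2, uncertainty_profile(level = 0), seed = 81)
  lab <- as.integer(t(to_segmentation(hot)$labels))
  set.seed(82)
  X <- cbind(ifelse(lab == 1, 1, 0.1), ifelse(lab == 2, 1, 0.1)) +
    matrix(rnorm(128, 0, 0.15), 64, 2)
  fm <- feature_map(X, g)
  # soft generating maps: saturated one-hot targets would let small and
  # large datasets tie at zero error
  gen <- logistic_maps(fm, logistic_params(rbind(c(1.5, -1.5),
                                                 c(-1.5, 1.5))))
  ps <- schedule_pairs(g, 2, seed = 83)
  maes <- vapply(c(1L, 8L, 64L), function(nb) {
    ds <- simulate_responses(gen, ps, nb, seed = 84)
    fit <- fit_parametric(ds, fm, 2, seed = 3, n_starts = 2)
    mean_absolute_error(fit$maps, gen)
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
  expect_lt(maes[3], 0.1)
})

test_that("differential variance signs identify the band driving each segment", {
  g <- grid_spec(8)
  hot <- sample_probmaps(g, 2, uncertainty_profile(level = 0), seed = 91)
  lab <- as.integer(t(to_segmentation(hot)$labels))
  # two disjoint active bands: band 1 carries segment-1 energy
  set.seed(92)
  X <- cbind(ifelse(lab == 1, 2, 0.2), ifelse(lab == 2, 2, 0.2)) *
    (1 + 0.1 * matrix(runif(128), 64, 2))
  fm <- feature_map(X, g)
  gen <- logistic_maps(fm, variance_to_logistic(
    variance_params(rbind(c(4, 0.5), c(0.5, 4)))))
  ps <- schedule_pairs(g, 2, seed = 93)
  ds <- simulate_responses(gen, ps, 20, seed = 94)
  fit <- fit_parametric(ds, fm, 2, parametrization = "variance", seed = 4,
                        n_starts = 3)
  dv <- fit$sigma_sq[1, ] - fit$sigma_sq[2, ]
  perm <- align_labels(fit$maps, gen)
  if (perm[1] == 2) dv <- -dv  # undo label swap
  expect_gt(dv[1], 0)
  expect_lt(dv[2], 0)
})

test_that("one-hot indicator features reproduce deterministic maps", {
  g <- grid_spec(6)
  hot <- sample_probmaps(g, 3, uncertainty_profile(level = 0), seed = 95)
  fm <- feature_map(hot$values, g)  # indicators as features
  ps <- schedule_pairs(g, 3, seed = 96)
  ds <- simulate_responses(hot, ps, 1, seed = 97)
  fit <- fit_parametric(ds, fm, 3, seed = 5)
  expect_lt(mean_absolute_error(fit$maps, hot), 0.05)
})

test_that("constant feature columns trigger a warning but not a failure", {
  g <- grid_spec(5)
  truth <- sample_probmaps(g, 2, uncertainty_profile(level = 0), seed = 98)
  X <- cbind(truth$values[, 1], 1)
  fm <- feature_map(X, g)
  ps <- schedule_pairs(g, 2, seed = 99)
  ds <- simulate_responses(truth, ps, 2, seed = 100)
  expect_warning(fit <- fit_parametric(ds, fm, 2, seed = 6, n_starts = 1),
                 "constant column")
  expect_s3_class(fit$maps, "prob_maps")
})
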