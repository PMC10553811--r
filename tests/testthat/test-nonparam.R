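test_that("pair probability is the simplex dot product", {
  expect_equal(pair_probability(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(pair_probability(c(1, 0), c(0, 1)), 0)
  expect_equal(pair_probability(rep(1 / 3, 3), rep(1 / 3, 3)), 1 / 3)
  expect_equal(pair_probability(c(0.2, 0.8), c(0.7, 0.3)),
               pair_probability(c(0.7, 0.3), c(0.2, 0.8)))
  expect_error(pair_probability(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("BCE loss equals per-trial enumeration and its closed forms", {
  g <- grid_spec(3)
  hot <- one_hot_maps(seg_map(matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 2), 3, 3,
                                     byrow = TRUE), g))
  # same-segment pairs answered "same": loss ~ 0 up to clipping
  d <- data.frame(block = 1, i = c(1, 2), j = c(2, 3), response = 1)
  ds <- response_dataset(d, g)
  expect_lt(bce_loss(hot, ds), 1e-10)
  # single trial at p_ij = 0.5 gives log 2
  u <- prob_maps(matrix(0.5, 9, 2), g)
  ds1 <- response_dataset(data.frame(block = 1, i = 1, j = 5, response = 1), g)
  expect_equal(bce_loss(u, ds1), log(2))
  # random maps and data: matches the explicit per-trial loop
  truth <- random_maps(4, 3, 2)
  ps <- schedule_pairs(grid_spec(4), 3, seed = 3)
  dsr <- simulate_responses(truth, ps, 4, seed = 4)
  m <- random_maps(4, 3, 9)
  expect_equal(bce_loss(m, dsr), bce_by_enumeration(m, dsr),
               tolerance = 1e-10)
})

test_that("SE loss equals pairwise enumeration and vanishes on exact fits", {
  truth <- random_maps(4, 2, 5)
  ps <- schedule_pairs(grid_spec(4), 2, seed = 6)
  ds <- simulate_responses(truth, ps, 8, seed = 7)
  tab <- empirical_proportions(ds)
  m <- random_maps(4, 2, 11)
  expect_equal(se_loss(m, tab), se_by_enumeration(m, tab), tolerance = 1e-12)
  # zero iff the model reproduces every proportion: use the truth's own
  # pair probabilities as synthetic proportions
  tab0 <- tab
  tab0$k <- probseg:::pair_prob_rows(truth$values, tab0$i, tab0$j)
  expect_equal(se_loss(truth, tab0), 0)
  # one pair, k = 1, p_ij = 0 gives 1
  g3 <- grid_spec(3)
  a <- one_hot_maps(seg_map(matrix(c(1, rep(2, 8)), 3, 3, byrow = TRUE), g3))
  ds1 <- response_dataset(data.frame(block = 1, i = 1, j = 2, response = 1),
                          g3)
  expect_equal(se_loss(a, empirical_proportions(ds1)), 1)
})

test_that("regularization penalty matches loop convolution with replicated edges", {
  cfg <- reg_config(lambda = 3, kernel = "laplacian4")
  # constant maps cost nothing under an averaging kernel
  g <- grid_spec(5)
  const <- prob_maps(matrix(c(0.3, 0.7), 25, 2, byrow = TRUE), g)
  expect_equal(regularization_penalty(const, cfg), 0)
  expect_equal(regularization_penalty(random_maps(5, 3, 1),
                                      reg_config(lambda = 0)), 0)
  # checkerboard one-hot two-segment map against the explicit loops
  lab <- matrix(rep_len(c(1L, 2L), 25), 5, 5)
  cb <- one_hot_maps(seg_map(lab, g))
  expect_equal(regularization_penalty(cb, cfg), penalty_by_loops(cb, cfg),
               tolerance = 1e-10)
  for (kern in c("laplacian8", "gaussian")) {
    cfgk <- reg_config(lambda = 1.5, kernel = kern)
    m <- random_maps(5, 3, 8)
    expect_equal(regularization_penalty(m, cfgk), penalty_by_loops(m, cfgk),
                 tolerance = 1e-10)
  }
  expect_error(reg_config(kernel = matrix(1, 2, 2)), "odd side")
  expect_error(reg_config(lambda = -1), "non-negative")
})

test_that("every solver iterate satisfies the simplex constraints", {
  truth <- random_maps(5, 3, 21)
  ps <- schedule_pairs(grid_spec(5), 3, seed = 22)
  ds <- simulate_responses(truth, ps, 5, seed = 23)
  for (loss in c("se", "bce")) {
    fit <- fit_nonparametric(ds, 3, reg = reg_config(lambda = 10),
                             solver = solver_config(max_iter = 200,
                                                    loss = loss, seed = 2))
    v <- fit$maps$values
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(abs(rowSums(v) - 1) <= 1e-9))
  }
})

test_that("loss trace decreases monotonically for a small step size", {
  truth <- random_maps(5, 2, 31)
  ps <- schedule_pairs(grid_spec(5), 2, seed = 32)
  ds <- simulate_responses(truth, ps, 10, seed = 33)
  fit <- fit_nonparametric(ds, 2, reg = reg_config(lambda = 1),
                           solver = solver_config(learning_rate = 1,
                                                  stop_eps = 1e-12,
                                                  max_iter = 500, seed = 3))
  expect_true(all(diff(fit$loss_trace) <= 1e-9))
})

test_that("the K = 1 fit degenerates to the all-ones maps", {
  g <- grid_spec(3)
  ds <- response_dataset(data.frame(block = 1, i = 1:8, j = 2:9,
                                    response = 1), g)
  fit <- fit_nonparametric(ds, 1)
  expect_true(all(fit$maps$values == 1))
  expect_true(fit$converged)
})

test_that("uncovered grid elements are flagged with a warning", {
  g <- grid_spec(3)
  ds <- response_dataset(data.frame(block = 1, i = c(1, 2), j = c(2, 3),
                                    response = 1), g)
  expect_warning(fit_nonparametric(ds, 2,
                                   solver = solver_config(max_iter = 10)),
                 "never tested")
})

test_that("the fitted pair probabilities match empirical proportions on an exhaustive design", {
  # N = 3, K = 2, exhaustive pairs, many blocks. With a deterministic
  # truth the empirical proportions are exactly realizable by the
  # dot-product model, so the SE minimizer must reproduce them closely.
  g <- grid_spec(3)
  truth <- sample_probmaps(g, 2, uncertainty_profile(level = 0), seed = 41)
  ps <- exhaustive_pairs(g)
  ds <- simulate_responses(truth, ps, 64, seed = 42)
  tab <- empirical_proportions(ds)
  fit <- fit_nonparametric(ds, 2, reg = reg_config(lambda = 0),
                           solver = solver_config(stop_eps = 1e-12,
                                                  max_iter = 20000, seed = 5))
  pij <- probseg:::pair_prob_rows(fit$maps$values, tab$i, tab$j)
  expect_true(all(abs(pij - tab$k) < 0.05))

  # For an interior (noisy) truth the proportions are overdetermined, so
  # instead cross-check against an independent general-purpose minimizer:
  # the exponentiated-gradient solution must be at least as good as
  # multi-start box-constrained quasi-Newton on the same objective.
  truth2 <- random_maps(3, 2, 43)
  ds2 <- simulate_responses(truth2, ps, 64, seed = 44)
  tab2 <- empirical_proportions(ds2)
  fit2 <- fit_nonparametric(ds2, 2, reg = reg_config(lambda = 0),
                            solver = solver_config(stop_eps = 1e-12,
                                                   max_iter = 20000,
                                                   seed = 5))
  obj <- function(q) {
    V <- cbind(q, 1 - q)
    sum((tab2$k - probseg:::pair_prob_rows(V, tab2$i, tab2$j))^2)
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    o <- stats::optim(runif(9), obj, method = "L-BFGS-B",
                      lower = 0, upper = 1, control = list(maxit = 500))
    best <- min(best, o$value)
  }
  expect_lte(se_loss(fit2$maps, tab2), best + 0.05)
})

test_that("bootstrap resampling summarizes reconstruction variability", {
  truth <- sample_probmaps(grid_spec(5), 2, uncertainty_profile(level = 0),
                           seed = 51)
  bt <- bootstrap_fit(truth, n_resamples = 4, seed = 52, n_blocks = 1,
                      reg = reg_config(lambda = 1),
                      solver = solver_config(max_iter = 2000, seed = 1))
  expect_equal(nrow(bt$per_resample), 4L)
  # noiseless one-hot truth: every resample reconstructs accurately
  expect_true(all(bt$per_resample$mae < 0.25))
  expect_true(all(bt$summary[, "lo"] <= bt$summary[, "hi"]))
})

test_that("unregularized MAE can rise while the data loss falls on limited data", {
  # reconstruction noise: the optimizer keeps improving the data fit while
  # moving away from the ground truth (the motivation for regularization)
  truth <- sample_probmaps(grid_spec(8), 3,
                           uncertainty_profile(0.4, 1.5), seed = 61)
  ps <- schedule_pairs(truth$grid, 3, seed = 62)
  ds <- simulate_responses(truth, ps, 10, seed = 63)
  sv <- solver_config(stop_eps = 1e-12, seed = 6)
  mid <- fit_nonparametric(ds, 3, reg = reg_config(lambda = 0),
                           solver = solver_config(max_iter = 30, seed = 6))
  full <- fit_nonparametric(ds, 3, reg = reg_config(lambda = 0),
                            solver = solver_config(max_iter = 3000, seed = 6))
  expect_lt(tail(full$loss_trace, 1), tail(mid$loss_trace, 1))
  expect_gt(mean_absolute_error(full$maps, truth),
            mean_absolute_error(mid$maps, truth))
})
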