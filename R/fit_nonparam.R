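#' Spatial regularization configuration
#'
#' The regularizer penalizes each probability value for deviating from its
#' local kernel average: \code{lambda * sum_i sum_k (p_i[k] - (G * p)_i[k])^2},
#' where \code{*} is discrete convolution with edge values replicated.
#' With the default Laplacian-style kernels (centre 0, neighbors averaging
#' to 1), \code{p - G * p} is a discrete Laplacian residual, so the penalty
#' favours locally smooth maps, encoding the Gestalt prior that nearby
#' locations tend to belong to the same segment.
#'
#' @param lambda non-negative regularization weight.
#' @param kernel either a kernel name (\code{"laplacian4"}: 4-neighbor
#'   average; \code{"laplacian8"}: 8-neighbor average; \code{"gaussian"}:
#'   3x3 Gaussian) or a numeric matrix with odd side lengths.
#' @return an object of class \code{reg_config}.
#' @export
reg_config <- function(lambda = 10, kernel = "laplacian4") {
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda >= 0))
    stop("lambda must be a single non-negative number", call. = FALSE)
  G <- if (is.character(kernel)) named_kernel(kernel) else as.matrix(kernel)
  if (any(dim(G) %% 2L == 0L))
    stop("kernel must have odd side lengths", call. = FALSE)
  structure(list(lambda = lambda, kernel = G,
                 kernel_name = if (is.character(kernel)) kernel else "custom"),
            class = "reg_config")
}

named_kernel <- function(name) {
  switch(name,
    laplacian4 = matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0) / 4, 3, 3),
    laplacian8 = matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1) / 8, 3, 3),
    gaussian   = { # 3x3 binomial
      k <- outer(c(1, 2, 1), c(1, 2, 1)); k / sum(k)
    },
    stop(sprintf("unknown kernel '%s'", name), call. = FALSE))
}

#' Solver configuration for exponentiated gradient descent
#'
#' The solver minimizes a normalized objective: the data loss averaged
#' over observations plus \code{lambda} times the regularization penalty
#' averaged over pixel-channel entries. Normalization makes the settings
#' transferable across losses, block counts and grid sizes; the exposed
#' loss functions ([se_loss()], [bce_loss()], [regularization_penalty()])
#' remain raw sums.
#'
#' @param learning_rate positive multiplicative step size on the
#'   per-observation gradient. The default 15 keeps the update stable
#'   across the regularization weights used in practice (up to
#'   lambda = 10); much larger steps oscillate when the penalty gradient
#'   is strong.
#' @param stop_eps positive convergence tolerance on the absolute change
#'   of the normalized objective between iterations.
#' @param max_iter iteration cap.
#' @param loss either \code{"se"} (squared error against empirical
#'   same-proportions; the default) or \code{"bce"} (Bernoulli negative
#'   log-likelihood).
#' @param seed seed for the random simplex initialization.
#' @return an object of class \code{solver_config}.
#' @export
solver_config <- function(learning_rate = 15, stop_eps = 1e-8,
                          max_iter = 10000L, loss = c("se", "bce"),
                          seed = 1L) {
  loss <- match.arg(loss)
  if (!(learning_rate > 0)) stop("learning_rate must be > 0", call. = FALSE)
  if (!(stop_eps > 0)) stop("stop_eps must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, stop_eps = stop_eps,
                 max_iter = as.integer(max_iter), loss = loss,
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Probability that two locations share a segment
#'
#' Under conditional independence of the per-pixel segment assignments,
#' the probability that locations i and j are perceived in the same
#' segment is the dot product of their simplex vectors.
#'
#' @param p_i,p_j numeric probability vectors on the K-simplex.
#' @return scalar in [0, 1]; symmetric in its arguments.
#' @export
pair_probability <- function(p_i, p_j) {
  if (length(p_i) != length(p_j))
    stop("probability vectors must have equal length", call. = FALSE)
  sum(p_i * p_j)
}

# pair probabilities for index vectors against a value matrix
pair_prob_rows <- function(values, ia, ib) {
  rowSums(values[ia, , drop = FALSE] * values[ib, , drop = FALSE])
}

#' Binary cross-entropy loss of probabilistic maps on a response dataset
#'
#' The negative log-likelihood of the Bernoulli responses: summed over
#' every trial, \code{-r log p_ij - (1 - r) log(1 - p_ij)} with
#' \code{p_ij} the pair probability. Pair probabilities are clipped to
#' \code{[delta, 1 - delta]} before taking logs so that deterministic maps
#' evaluate to finite loss.
#'
#' @param maps a [prob_maps()].
#' @param dataset a [response_dataset()] on the same grid.
#' @param delta clipping constant (default 1e-12).
#' @return non-negative scalar.
#' @export
bce_loss <- function(maps, dataset, delta = 1e-12) {
  stopifnot(inherits(maps, "prob_maps"), inherits(dataset, "response_dataset"))
  if (!same_grid(maps$grid, dataset$grid))
    stop("maps and dataset must share a grid", call. = FALSE)
  tab <- empirical_proportions(dataset)
  bce_from_counts(maps$values, tab$i, tab$j, tab$n_same, tab$n_obs, delta)
}

bce_from_counts <- function(values, ia, ib, n_same, n_obs, delta = 1e-12) {
  p <- pmin(pmax(pair_prob_rows(values, ia, ib), delta), 1 - delta)
  sum(-n_same * log(p) - (n_obs - n_same) * log1p(-p))
}

#' Squared-error loss against empirical same-proportions
#'
#' Sum over the tested pairs of the squared residual between the empirical
#' same-segment proportion and the model pair probability. Minimizing
#' this non-linear least-squares objective is equivalent to maximizing the
#' Bernoulli likelihood when the tested probability-vector families are
#' linearly independent.
#'
#' @param maps a [prob_maps()].
#' @param proportions a \code{proportion_table} from
#'   [empirical_proportions()].
#' @return non-negative scalar; 0 iff the model matches every proportion.
#' @export
se_loss <- function(maps, proportions) {
  stopifnot(inherits(maps, "prob_maps"),
            inherits(proportions, "proportion_table"))
  se_from_props(maps$values, proportions$i, proportions$j, proportions$k)
}

se_from_props <- function(values, ia, ib, k) {
  sum((k - pair_prob_rows(values, ia, ib))^2)
}

#' Spatial regularization penalty
#'
#' \code{lambda * sum_i sum_k (p_i[k] - (G * p)_i[k])^2} with
#' replicate-padded convolution.
#'
#' @param maps a [prob_maps()].
#' @param cfg a [reg_config()].
#' @return non-negative scalar (0 when lambda = 0 or the map is constant
#'   under an averaging kernel).
#' @export
regularization_penalty <- function(maps, cfg) {
  stopifnot(inherits(maps, "prob_maps"), inherits(cfg, "reg_config"))
  if (cfg$lambda == 0) return(0)
  C <- conv_matrix(maps$grid$N, cfg$kernel)
  R <- maps$values - as.matrix(C %*% maps$values)
  cfg$lambda * sum(R^2)
}

# Sparse N^2 x N^2 operator implementing replicate-padded convolution of
# an N x N field (row-major cell order) with kernel G. Having the operator
# as an explicit matrix gives the exact adjoint for the penalty gradient.
conv_matrix <- function(N, G) {
  key <- paste0(N, ":", paste(dim(G), collapse = "x"), ":",
                paste(signif(G, 12), collapse = ","))
  cached <- conv_cache[[key]]
  if (!is.null(cached)) return(cached)
  hr <- (nrow(G) - 1L) %/% 2L
  hc <- (ncol(G) - 1L) %/% 2L
  rows <- rep(seq_len(N), each = N)   # row-major: row varies slowest
  cols <- rep(seq_len(N), times = N)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dr in -hr:hr) for (dc in -hc:hc) {
    w <- G[dr + hr + 1L, dc + hc + 1L]
    if (w == 0) next
    # convolution: (G * p)_i = sum_j G_j p_{i-j}; replicate out-of-grid
    sr <- pmin(pmax(rows - dr, 1L), N)
    sc <- pmin(pmax(cols - dc, 1L), N)
    ii <- c(ii, (rows - 1L) * N + cols)
    jj <- c(jj, (sr - 1L) * N + sc)
    xx <- c(xx, rep(w, N * N))
  }
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N * N, N * N))
  conv_cache[[key]] <- C
  C
}

conv_cache <- new.env(parent = emptyenv())

# t(I - C) %*% (I - C), the Hessian-like operator of the penalty
penalty_operator <- function(N, G) {
  C <- conv_matrix(N, G)
  A <- Matrix::Diagonal(N * N) - C
  Matrix::t(A) %*% A
}

#' Non-parametric reconstruction of probabilistic maps
#'
#' Estimates the probabilistic segmentation maps from same/different
#' responses by minimizing the chosen objective (squared error against
#' empirical proportions, or binary cross-entropy) plus the spatial
#' regularization penalty, under per-pixel simplex constraints. The
#' solver is exponentiated gradient descent: multiplicative update
#' \code{p <- p * exp(-lr * grad)} followed by per-row renormalization,
#' which preserves positivity and the simplex at every iterate; it stops
#' when the objective changes by at most \code{stop_eps} between
#' iterations or at \code{max_iter}.
#'
#' @param dataset a [response_dataset()].
#' @param K number of segments to reconstruct (K = 1 returns the trivial
#'   all-ones maps).
#' @param reg a [reg_config()]; use \code{reg_config(lambda = 0)} to
#'   disable regularization.
#' @param solver a [solver_config()].
#' @return an object of class \code{fit_result}: \code{maps}
#'   ([prob_maps()]), \code{loss_trace}, \code{iterations},
#'   \code{converged}, \code{uncovered} (cells never tested, left at their
#'   initialization).
#' @export
fit_nonparametric <- function(dataset, K,
                              reg = reg_config(),
                              solver = solver_config()) {
  stopifnot(inherits(dataset, "response_dataset"),
            inherits(reg, "reg_config"), inherits(solver, "solver_config"))
  grid <- dataset$grid
  M <- n_cells(grid)
  K <- as.integer(K)
  tab <- empirical_proportions(dataset)
  uncovered <- setdiff(seq_len(M), unique(c(tab$i, tab$j)))
  if (length(uncovered))
    warning(sprintf("%d grid element(s) never tested; they stay at their initialization",
                    length(uncovered)), call. = FALSE)
  if (K == 1L) {
    maps <- prob_maps(matrix(1, M, 1L), grid)
    return(structure(list(maps = maps, loss_trace = numeric(0),
                          iterations = 0L, converged = TRUE,
                          uncovered = uncovered, solver = solver, reg = reg),
                     class = "fit_result"))
  }
  P <- with_seed(solver$seed, init_simplex(M, K))
  res <- eg_descent(P, tab, grid, reg, solver)
  structure(c(list(maps = prob_maps(res$P, grid), uncovered = uncovered,
                   solver = solver, reg = reg),
              res[c("loss_trace", "iterations", "converged")]),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  lt <- x$loss_trace
  cat(sprintf("<fit_result> K = %d, %d iteration(s), %sconverged%s\n",
              x$maps$K, x$iterations, if (x$converged) "" else "NOT ",
              if (length(lt)) sprintf(", final loss %.6g", lt[length(lt)]) else ""))
  invisible(x)
}

# independent uniform draws on the simplex (symmetric Dirichlet, alpha = 1)
init_simplex <- function(M, K) {
  e <- matrix(stats::rexp(M * K), M, K)
  e / rowSums(e)
}

# Core exponentiated-gradient loop (compiled; see src/eg_descent.cpp).
#
# The optimized objective is normalized: data term averaged over
# observations (pairs for SE, pair-block trials for BCE), penalty
# averaged over pixel-channel entries. This makes lambda a scale-free
# trade-off between per-observation error and per-pixel smoothness, so
# the same lambda regularizes the SE and BCE objectives comparably
# (the raw BCE sum grows with N_b and would otherwise dilute the
# penalty N_b-fold). The compiled core works on raw sums; the
# normalization is folded into its lambda, learning rate and tolerance.
eg_descent <- function(P, tab, grid, reg, solver) {
  Lop <- if (reg$lambda > 0) penalty_operator(grid$N, reg$kernel)
  else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nrow(P), nrow(P)))
  n_obs_total <- if (solver$loss == "bce") sum(tab$n_obs) else nrow(tab)
  lambda_core <- reg$lambda * n_obs_total / length(P)
  res <- .eg_descent_cpp(P, tab$i - 1L, tab$j - 1L, tab$k, tab$n_same,
                         tab$n_obs,
                         use_bce = solver$loss == "bce",
                         lambda = lambda_core,
                         Lop = methods::as(Lop, "dgCMatrix"),
                         lr = solver$learning_rate / n_obs_total,
                         eps = solver$stop_eps * n_obs_total,
                         max_iter = solver$max_iter)
  res$loss_trace <- res$loss_trace / n_obs_total
  res
}

#' Bootstrap the reconstruction over pair-design resamples
#'
#' Repeats the full simulation pipeline — schedule a fresh pair design,
#' simulate Bernoulli responses from the ground truth, fit — and
#' summarizes the sampling variability of the reconstruction error and of
#' the final loss with 95 percent percentile intervals.
#'
#' @param truth a [prob_maps()] ground truth.
#' @param n_resamples number of pair-design resamples (>= 2).
#' @param seed master seed; resample r uses seed + r for its design and
#'   simulation.
#' @param n_blocks blocks per simulated experiment.
#' @param n_trials pairs per design (default \code{K * N^2}).
#' @param reg,solver configurations passed to [fit_nonparametric()].
#' @return list with \code{per_resample} (data.frame of MAE and final
#'   loss) and \code{summary} (mean, 2.5 and 97.5 percentiles of each).
#' @export
bootstrap_fit <- function(truth, n_resamples = 50L, seed = 1L,
                          n_blocks = 10L, n_trials = NULL,
                          reg = reg_config(), solver = solver_config()) {
  stopifnot(inherits(truth, "prob_maps"), n_resamples >= 2L)
  K <- truth$K
  grid <- truth$grid
  if (is.null(n_trials)) n_trials <- K * n_cells(grid)
  rows <- lapply(seq_len(n_resamples), function(r) {
    s <- seed + r
    ps <- schedule_pairs(grid, K, n_trials, seed = s)
    ds <- simulate_responses(truth, ps, n_blocks, seed = s)
    fit <- fit_nonparametric(ds, K, reg = reg, solver = solver)
    data.frame(resample = r,
               mae = mean_absolute_error(fit$maps, truth),
               final_loss = tail1(fit$loss_trace),
               iterations = fit$iterations,
               converged = fit$converged)
  })
  per <- do.call(rbind, rows)
  summ <- function(x) c(mean = mean(x),
                        lo = unname(stats::quantile(x, 0.025)),
                        hi = unname(stats::quantile(x, 0.975)))
  list(per_resample = per,
       summary = rbind(mae = summ(per$mae), final_loss = summ(per$final_loss)))
}

tail1 <- function(x) if (length(x)) x[length(x)] else NA_real_
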