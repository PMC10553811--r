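#' Per-cell feature map
#'
#' A D-dimensional feature vector for every grid element, e.g. mean RGB
#' values or oriented wavelet energies. Stored as an N^2 x D matrix in
#' row-major cell order.
#'
#' @param values numeric N^2 x D matrix of finite values.
#' @param grid a [grid_spec()].
#' @return an object of class \code{feature_map}.
#' @export
feature_map <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != n_cells(grid))
    stop("values must have N^2 rows", call. = FALSE)
  if (ncol(values) < 1L) stop("D must be >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("feature values must be finite", call. = FALSE)
  structure(list(values = values, D = ncol(values), grid = grid),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> D = %d features on a %d x %d grid\n",
              x$D, x$grid$N, x$grid$N))
  invisible(x)
}

#' Multinomial logistic parameters
#'
#' Weights and intercepts of the softmax model for class probabilities.
#' Only the differences between rows are identifiable (softmax shift
#' invariance).
#'
#' @param omega numeric K x D weight matrix.
#' @param beta numeric K intercept vector (defaults to zeros).
#' @return an object of class \code{logistic_params}.
#' @export
logistic_params <- function(omega, beta = rep(0, nrow(omega))) {
  omega <- as.matrix(omega)
  if (length(beta) != nrow(omega))
    stop("beta must have one entry per class", call. = FALSE)
  if (!all(is.finite(omega)) || !all(is.finite(beta)))
    stop("parameters must be finite", call. = FALSE)
  structure(list(omega = omega, beta = as.numeric(beta),
                 K = nrow(omega), D = ncol(omega)),
            class = "logistic_params")
}

#' Variance parametrization of the logistic model
#'
#' For texture experiments the model is reparametrized with zero
#' intercepts and weights \code{omega_k = -1 / sigma_sq_k} (component
#' wise), so that \code{sigma_sq_k[d]} is interpretable as the average
#' energy of feature band d under segment k. For K = 2 only the
#' differential variance \code{(s1 - s2) / (s1 * s2)} per band is
#' identifiable.
#'
#' @param sigma_sq strictly positive K x D matrix.
#' @return an object of class \code{variance_params}.
#' @export
variance_params <- function(sigma_sq) {
  sigma_sq <- as.matrix(sigma_sq)
  if (!all(is.finite(sigma_sq)) || any(sigma_sq <= 0))
    stop("sigma_sq entries must be strictly positive", call. = FALSE)
  structure(list(sigma_sq = sigma_sq, K = nrow(sigma_sq), D = ncol(sigma_sq)),
            class = "variance_params")
}

#' Convert variance parameters to logistic parameters
#' @param vp a [variance_params()].
#' @return a [logistic_params()] with zero intercepts and
#'   \code{omega = -1 / sigma_sq}.
#' @export
variance_to_logistic <- function(vp) {
  stopifnot(inherits(vp, "variance_params"))
  logistic_params(-1 / vp$sigma_sq, rep(0, vp$K))
}

#' Probabilistic maps from the multinomial logistic model
#'
#' \code{p_i[k] = exp(omega_k . x_i + beta_k) / sum_l exp(omega_l . x_i +
#' beta_l)}, computed with per-row max subtraction for overflow safety.
#'
#' @param features a [feature_map()].
#' @param params a [logistic_params()] with matching D.
#' @return a [prob_maps()].
#' @export
logistic_maps <- function(features, params) {
  stopifnot(inherits(features, "feature_map"),
            inherits(params, "logistic_params"))
  if (params$D != features$D)
    stop("feature dimensionality does not match the parameters", call. = FALSE)
  P <- softmax_rows(features$values %*% t(params$omega) +
                      rep(params$beta, each = n_cells(features$grid)))
  prob_maps(P, features$grid)
}

softmax_rows <- function(eta) {
  eta <- eta - apply(eta, 1L, max)
  e <- exp(eta)
  e / rowSums(e)
}

#' Per-cell mean RGB features
#'
#' Averages the red, green and blue values of the image pixels falling in
#' each grid cell (D = 3).
#'
#' @param image numeric H x W x 3 array with values in [0, 1].
#' @param grid a [grid_spec()]; the image sides must be at least N.
#' @return a [feature_map()] with D = 3.
#' @export
rgb_features <- function(image, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("rgb_features requires an H x W x 3 color image", call. = FALSE)
  v <- vapply(1:3, function(ch) cell_means(image[, , ch], grid),
              numeric(n_cells(grid)))
  feature_map(v, grid)
}

# average an H x W matrix over the N x N grid cells (row-major cell order)
cell_means <- function(m, grid) {
  N <- grid$N
  H <- nrow(m); W <- ncol(m)
  if (H < N || W < N) stop("image is smaller than the grid", call. = FALSE)
  ri <- pmin(((seq_len(H) - 1L) * N) %/% H + 1L, N)
  ci <- pmin(((seq_len(W) - 1L) * N) %/% W + 1L, N)
  cellidx <- (ri[row(m)] - 1L) * N + ci[col(m)]
  as.numeric(rowsum(as.numeric(m), cellidx) /
               as.numeric(rowsum(rep(1, length(m)), cellidx)))
}

#' Oriented wavelet-energy features
#'
#' Applies a log-Gabor filter bank (\code{n_orientations} orientation
#' bands times \code{n_scales} scales) to a square grayscale image,
#' squares the complex responses, averages the energies over scales and
#' over the pixels of each grid cell. This is the feature representation
#' used to relate oriented-texture stimuli to segmentation judgments.
#'
#' @param image numeric square matrix (grayscale).
#' @param grid a [grid_spec()].
#' @param n_orientations number of orientation bands spanning [0, 180)
#'   degrees (default 36, i.e. 5-degree spacing).
#' @param n_scales number of filter scales (default 4).
#' @param freq_max centre frequency of the finest scale, cycles per image
#'   (coarser scales are spaced by octaves).
#' @param freq_bandwidth log-radial bandwidth factor (> 1).
#' @return a [feature_map()] with D = \code{n_orientations}; band d is
#'   centred at \code{(d - 1) * 180 / n_orientations} degrees.
#' @export
orientation_energy_features <- function(image, grid, n_orientations = 36L,
                                        n_scales = 4L, freq_max = NULL,
                                        freq_bandwidth = 1.6) {
  stopifnot(inherits(grid, "grid_spec"))
  image <- as.matrix(image)
  S <- nrow(image)
  if (ncol(image) != S)
    stop("orientation_energy_features requires a square image", call. = FALSE)
  if (is.null(freq_max)) freq_max <- S / 4
  FI <- stats::fft(image)
  thetas <- (seq_len(n_orientations) - 1L) * 180 / n_orientations
  sigma_theta <- 180 / n_orientations  # neighboring bands overlap
  M <- n_cells(grid)
  out <- matrix(0, M, n_orientations)
  for (d in seq_len(n_orientations)) {
    energy <- matrix(0, S, S)
    for (s in seq_len(n_scales)) {
      A <- log_gabor_filter(S, thetas[d], sigma_theta,
                            freq_max / 2^(s - 1L), freq_bandwidth)
      z <- stats::fft(FI * A, inverse = TRUE) / (S * S)
      energy <- energy + Mod(z)^2
    }
    out[, d] <- cell_means(energy / n_scales, grid)
  }
  feature_map(out, grid)
}

# one-sided (analytic) log-Gabor filter: complex-valued spatial response
log_gabor_filter <- function(S, theta_deg, sigma_theta_deg,
                             freq_center, freq_bandwidth) {
  f <- c(0:(S %/% 2), -((S - S %/% 2 - 1):1)) / S
  fx <- matrix(f, S, S, byrow = TRUE)
  fy <- matrix(f, S, S)
  rho <- sqrt(fx^2 + fy^2)
  rho0 <- freq_center / S
  radial <- exp(-(log(pmax(rho, 1e-12) / rho0))^2 /
                  (2 * log(freq_bandwidth)^2))
  radial[rho == 0] <- 0
  theta <- theta_deg * pi / 180
  ang <- atan2(fy, fx)
  d <- (ang - theta + pi) %% (2 * pi) - pi  # one-sided: direction theta only
  sigma <- sigma_theta_deg * pi / 180
  radial * exp(-d^2 / (2 * sigma^2))
}

#' Parametric reconstruction of probabilistic maps
#'
#' Fits the multinomial logistic model by minimizing the squared error
#' between the empirical same-proportions and the model pair
#' probabilities \code{p_ij(theta) = p_i(theta) . p_j(theta)}, optionally
#' plus the spatial regularization penalty on the induced maps. The
#' optimizer is limited-memory quasi-Newton (L-BFGS-B) with analytic
#' gradients; the variance parametrization enforces positivity through a
#' log transform (\code{sigma_sq = exp(s)}). Multi-start over random
#' initializations is supported; the best stationary point is returned.
#'
#' @param dataset a [response_dataset()].
#' @param features a [feature_map()] on the same grid.
#' @param K number of segments.
#' @param reg a [reg_config()]; the default puts no penalty on parametric
#'   fits, as the model family already constrains the maps.
#' @param parametrization \code{"free"} (omega and beta unconstrained) or
#'   \code{"variance"} (\code{beta = 0}, \code{omega = -1 / sigma_sq}).
#' @param seed seed for the random starts.
#' @param n_starts number of random initializations.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return list with \code{params} (a [logistic_params()]),
#'   \code{sigma_sq} (K x D matrix, variance parametrization only),
#'   \code{maps} (fitted [prob_maps()]), \code{value} (final objective),
#'   \code{converged}, and \code{start_values} (objective per start).
#' @export
fit_parametric <- function(dataset, features, K,
                           reg = reg_config(lambda = 0),
                           parametrization = c("free", "variance"),
                           seed = 1L, n_starts = 3L, maxit = 500L) {
  stopifnot(inherits(dataset, "response_dataset"),
            inherits(features, "feature_map"))
  if (!same_grid(dataset$grid, features$grid))
    stop("dataset and features must be on the same grid", call. = FALSE)
  parametrization <- match.arg(parametrization)
  K <- as.integer(K)
  D <- features$D
  X <- features$values
  if (any(apply(X, 2L, stats::sd) == 0))
    warning("feature map has constant column(s); the fit proceeds but those bands are uninformative",
            call. = FALSE)
  tab <- empirical_proportions(dataset)
  ia <- tab$i; ib <- tab$j; kk <- tab$k
  Tn <- nrow(tab); M <- nrow(X)
  Ai <- Matrix::sparseMatrix(i = ia, j = seq_len(Tn), x = 1, dims = c(M, Tn))
  Aj <- Matrix::sparseMatrix(i = ib, j = seq_len(Tn), x = 1, dims = c(M, Tn))
  Lop <- if (reg$lambda > 0) penalty_operator(dataset$grid$N, reg$kernel)
  else NULL

  unpack <- function(theta) {
    if (parametrization == "free") {
      list(omega = matrix(theta[seq_len(K * D)], K, D),
           beta = theta[K * D + seq_len(K)])
    } else {
      list(omega = -exp(-matrix(theta, K, D)), beta = rep(0, K),
           s = matrix(theta, K, D))
    }
  }
  maps_of <- function(par) {
    softmax_rows(X %*% t(par$omega) + rep(par$beta, each = M))
  }
  objective <- function(theta) {
    P <- maps_of(unpack(theta))
    v <- se_from_props(P, ia, ib, kk)
    if (!is.null(Lop)) v <- v + reg$lambda * sum(P * as.matrix(Lop %*% P))
    v
  }
  gradient <- function(theta) {
    par <- unpack(theta)
    P <- maps_of(par)
    Pi <- P[ia, , drop = FALSE]; Pj <- P[ib, , drop = FALSE]
    coef <- -2 * (kk - rowSums(Pi * Pj))
    Gp <- as.matrix(Ai %*% (coef * Pj) + Aj %*% (coef * Pi))  # dL/dP
    if (!is.null(Lop)) Gp <- Gp + 2 * reg$lambda * as.matrix(Lop %*% P)
    # chain through the softmax: dL/deta_il = p_il (Gp_il - sum_k Gp_ik p_ik)
    B <- P * (Gp - rowSums(Gp * P))
    gomega <- t(B) %*% X                       # K x D
    if (parametrization == "free") {
      c(as.numeric(gomega), colSums(B))
    } else {
      as.numeric(gomega * (-par$omega))        # d omega / d s = -omega
    }
  }

  n_par <- if (parametrization == "free") K * D + K else K * D
  best <- NULL
  start_values <- numeric(n_starts)
  for (st in seq_len(n_starts)) {
    theta0 <- with_seed(seed + st - 1L, {
      if (parametrization == "free") stats::rnorm(n_par, 0, 0.5)
      else stats::rnorm(n_par, 0, 0.5)  # s = log sigma^2 near 0
    })
    opt <- stats::optim(theta0, objective, gradient, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    start_values[st] <- opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- unpack(best$par)
  params <- logistic_params(par$omega, par$beta)
  out <- list(params = params,
              maps = prob_maps(maps_of(par), dataset$grid),
              value = best$value,
              converged = best$convergence == 0L,
              start_values = start_values)
  if (parametrization == "variance") out$sigma_sq <- exp(par$s)
  if (!out$converged)
    warning("parametric fit did not report convergence; returning the best point found",
            call. = FALSE)
  out
}
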