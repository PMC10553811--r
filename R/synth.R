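#' Uncertainty profile for synthetic ground-truth maps
#'
#' Controls how far the generated maps are from a deterministic one-hot
#' partition: \code{level} = 0 gives one-hot maps, 1 maximal blur and
#' mixing toward the uniform vector; \code{spatial_scale} sets the width
#' (in grid units) of the uncertain band around segment boundaries.
#'
#' @param level real in [0, 1].
#' @param spatial_scale positive real, grid units.
#' @return an object of class \code{uncertainty_profile}.
#' @export
uncertainty_profile <- function(level = 0.4, spatial_scale = 1.5) {
  if (!(level >= 0 && level <= 1))
    stop("level must lie in [0, 1]", call. = FALSE)
  if (!(spatial_scale > 0))
    stop("spatial_scale must be > 0", call. = FALSE)
  structure(list(level = level, spatial_scale = spatial_scale),
            class = "uncertainty_profile")
}

#' Sample synthetic ground-truth probabilistic maps
#'
#' Draws K compact random regions (a nearest-seed partition of the grid
#' from K random seed cells), builds one-hot maps, then softens them:
#' the label indicators are blurred with a Gaussian kernel of standard
#' deviation \code{level * spatial_scale} grid units (replicate-padded,
#' so channel sums stay 1) and mixed toward the uniform vector with
#' weight \code{level}. \code{level} = 0 therefore returns one-hot maps,
#' and the mean entropy grows monotonically with \code{level}.
#'
#' @param grid a [grid_spec()].
#' @param K number of segments (at most N^2).
#' @param profile an [uncertainty_profile()].
#' @param seed integer seed.
#' @return a [prob_maps()] ground truth.
#' @export
sample_probmaps <- function(grid, K, profile = uncertainty_profile(),
                            seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(profile, "uncertainty_profile"))
  K <- as.integer(K)
  M <- n_cells(grid)
  if (K > M) stop("K cannot exceed the number of grid elements", call. = FALSE)
  coords <- cell_coords(grid, seq_len(M))
  with_seed(seed, {
    # farthest-point seeding, then nearest-seed (Voronoi) labels: K compact
    # regions of comparable size, avoiding degenerate slivers
    seeds <- sample.int(M, 1L)
    while (length(seeds) < K) {
      d2 <- outer(coords$row, coords$row[seeds], "-")^2 +
        outer(coords$col, coords$col[seeds], "-")^2
      seeds <- c(seeds, which.max(apply(as.matrix(d2), 1L, min)))
    }
    d2 <- outer(coords$row, coords$row[seeds], "-")^2 +
      outer(coords$col, coords$col[seeds], "-")^2
    lab <- max.col(-d2, ties.method = "first")
    v <- matrix(0, M, K)
    v[cbind(seq_len(M), lab)] <- 1
    lv <- profile$level
    if (lv > 0) {
      sigma <- lv * profile$spatial_scale
      Gk <- gaussian_kernel(sigma, max_radius = grid$N - 1L)
      C <- conv_matrix(grid$N, Gk)
      v <- as.matrix(C %*% v)
      v <- (1 - lv) * v + lv / K
      v <- v / rowSums(v)
    }
    prob_maps(v, grid)
  })
}

# normalized 2-D Gaussian kernel, odd side, radius 3 sigma (clamped)
gaussian_kernel <- function(sigma, max_radius = Inf) {
  r <- max(1L, min(ceiling(3 * sigma), max_radius))
  x <- seq(-r, r)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

#' Simulate Bernoulli same/different responses
#'
#' For each tested pair, draws \code{n_blocks} independent Bernoulli
#' responses with success probability equal to the pair probability (dot
#' product of the ground-truth simplex vectors); the same pair set is
#' used at every block.
#'
#' @param truth a [prob_maps()] ground truth.
#' @param pairset a [pair_set()] on the same grid.
#' @param n_blocks number of blocks (repetitions per pair).
#' @param seed integer seed.
#' @return a [response_dataset()].
#' @export
simulate_responses <- function(truth, pairset, n_blocks = 1L, seed = 1L) {
  stopifnot(inherits(truth, "prob_maps"), inherits(pairset, "pair_set"))
  if (!same_grid(truth$grid, pairset$grid))
    stop("truth and pair set must share a grid", call. = FALSE)
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1L)
  Tn <- length(pairset)
  pij <- pair_prob_rows(truth$values, pairset$i, pairset$j)
  with_seed(seed, {
    r <- stats::rbinom(Tn * n_blocks, 1L, rep(pij, times = n_blocks))
    response_dataset(data.frame(
      block = rep(seq_len(n_blocks), each = Tn),
      i = rep(pairset$i, times = n_blocks),
      j = rep(pairset$j, times = n_blocks),
      response = r), truth$grid)
  })
}

#' Specification of a two-region composite oriented texture
#'
#' The image is split into two regions by a random smooth boundary; each
#' region is filled with bandpass Gaussian noise whose orientation
#' distribution is Gaussian around that region's centre orientation.
#' Narrow, well-separated orientation bandwidths give a low-uncertainty
#' stimulus (weakly overlapping distributions); broad bandwidths give a
#' high-uncertainty stimulus (strongly overlapping distributions).
#'
#' @param size image side length in pixels.
#' @param center_orientations two angles in degrees, each in [0, 180).
#' @param orientation_bandwidths two positive angular standard deviations
#'   in degrees.
#' @param freq_center radial centre frequency, cycles per image.
#' @param freq_bandwidth log-radial bandwidth (octave-like factor > 1).
#' @param boundary_smoothness smoothness of the random boundary (larger
#'   is straighter).
#' @return an object of class \code{texture_spec}.
#' @export
texture_spec <- function(size = 128L,
                         center_orientations = c(80, 100),
                         orientation_bandwidths = c(8, 8),
                         freq_center = 16, freq_bandwidth = 1.4,
                         boundary_smoothness = 2) {
  if (any(orientation_bandwidths <= 0))
    stop("orientation bandwidths must be > 0", call. = FALSE)
  if (any(center_orientations < 0 | center_orientations >= 180))
    stop("centre orientations must lie in [0, 180)", call. = FALSE)
  structure(list(size = as.integer(size),
                 center_orientations = center_orientations,
                 orientation_bandwidths = orientation_bandwidths,
                 freq_center = freq_center, freq_bandwidth = freq_bandwidth,
                 boundary_smoothness = boundary_smoothness),
            class = "texture_spec")
}

#' Sample a random smooth boundary mask
#'
#' Draws a smooth random curve crossing the image left to right (a random
#' cosine series whose amplitudes shrink with \code{smoothness} and with
#' harmonic number) and returns the binary mask of the region above the
#' curve. Resamples internally (bounded retries) until the region area
#' fraction falls in [0.25, 0.75].
#'
#' @param size image side length in pixels.
#' @param smoothness positive; larger values give straighter boundaries.
#' @param seed integer seed.
#' @return logical size x size matrix; TRUE marks region 1.
#' @export
sample_boundary <- function(size, smoothness = 2, seed = 1L) {
  if (!(smoothness > 0)) stop("smoothness must be > 0", call. = FALSE)
  size <- as.integer(size)
  with_seed(seed, {
    for (try in 1:50) {
      x <- seq_len(size)
      offset <- stats::runif(1, 0.35, 0.65) * size
      m <- 1:4
      amp <- stats::rnorm(4, 0, size / (6 * smoothness * m))
      phase <- stats::runif(4, 0, 2 * pi)
      curve <- offset + colSums(amp * sin(outer(m, x) * 2 * pi / size +
                                            phase))
      mask <- outer(seq_len(size), curve, "<=")
      frac <- mean(mask)
      if (frac >= 0.25 && frac <= 0.75) return(mask)
    }
    mask  # last attempt; area constraint nearly always met well before
  })
}

#' Synthesize a composite oriented texture with ground-truth mask
#'
#' Filters one white Gaussian noise image in the frequency domain with two
#' oriented log-radial bandpass filters (one per region) and composites
#' the two textures along a random smooth boundary. The returned mask is
#' the ground-truth segmentation of the stimulus.
#'
#' @param spec a [texture_spec()].
#' @param seed integer seed.
#' @param blend \code{"hard"} (default, 1-pixel transition) or
#'   \code{"cosine"} for a smooth cross-fade near the boundary.
#' @param blend_width cross-fade width in pixels (cosine blend only).
#' @return list with \code{image} (size x size matrix in [0, 1]),
#'   \code{mask} (logical matrix, TRUE = region 1), and \code{spec}.
#' @export
synthesize_composite_texture <- function(spec, seed = 1L,
                                         blend = c("hard", "cosine"),
                                         blend_width = 4) {
  stopifnot(inherits(spec, "texture_spec"))
  blend <- match.arg(blend)
  S <- spec$size
  mask <- sample_boundary(S, spec$boundary_smoothness, seed = seed)
  noise <- with_seed(seed + 1L, matrix(stats::rnorm(S * S), S, S))
  W <- stats::fft(noise)
  tex <- lapply(1:2, function(r) {
    A <- oriented_bandpass_filter(S, spec$center_orientations[r],
                                  spec$orientation_bandwidths[r],
                                  spec$freq_center, spec$freq_bandwidth)
    t_r <- Re(stats::fft(W * A, inverse = TRUE)) / (S * S)
    t_r / stats::sd(t_r)
  })
  w <- if (blend == "hard") {
    ifelse(mask, 1, 0)
  } else {
    d <- distance_to_boundary(mask)
    s <- pmin(pmax(d / blend_width, -1), 1)  # signed distance, clipped
    0.5 * (1 + sin(s * pi / 2))
  }
  img <- w * tex[[1L]] + (1 - w) * tex[[2L]]
  img <- (img - min(img)) / (max(img) - min(img))
  list(image = img, mask = mask, spec = spec)
}

# signed Chebyshev-ish distance to the mask boundary (positive inside)
distance_to_boundary <- function(mask) {
  S <- nrow(mask)
  d <- matrix(Inf, S, S)
  # boundary cells: any 4-neighbor differs
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(row(m) + dr, 1L), S); c <- pmin(pmax(col(m) + dc, 1L), S)
    matrix(m[cbind(as.vector(r), as.vector(c))], S, S)
  }
  bd <- (mask != pad(mask, 1L, 0L)) | (mask != pad(mask, -1L, 0L)) |
    (mask != pad(mask, 0L, 1L)) | (mask != pad(mask, 0L, -1L))
  idx <- which(bd, arr.ind = TRUE)
  for (p in seq_len(S)) {
    # distance per column to the nearest boundary row in that column
    rows_b <- idx[idx[, 2L] == p, 1L]
    if (!length(rows_b)) next
    d[, p] <- vapply(seq_len(S), function(r) min(abs(r - rows_b)), numeric(1))
  }
  ifelse(mask, d, -d)
}

# one-sided oriented log-radial bandpass filter in the frequency domain
oriented_bandpass_filter <- function(S, theta_deg, sigma_theta_deg,
                                     freq_center, freq_bandwidth) {
  f <- c(0:(S %/% 2), -((S - S %/% 2 - 1):1)) / S   # cycles / pixel
  fx <- matrix(f, S, S, byrow = TRUE)
  fy <- matrix(f, S, S)
  rho <- sqrt(fx^2 + fy^2)
  rho0 <- freq_center / S
  radial <- exp(-(log(pmax(rho, 1e-12) / rho0))^2 /
                  (2 * log(freq_bandwidth)^2))
  radial[rho == 0] <- 0
  theta <- theta_deg * pi / 180
  ang <- atan2(fy, fx)
  # wrapped angular distance with period pi (orientation, not direction)
  d <- (ang - theta + pi / 2) %% pi - pi / 2
  sigma <- sigma_theta_deg * pi / 180
  radial * exp(-d^2 / (2 * sigma^2))
}
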