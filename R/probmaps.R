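#' Probabilistic segmentation maps
#'
#' The central estimand: for every grid element i, a probability vector
#' p_i over K segments (a point on the K-simplex). Values are stored as an
#' N^2 x K matrix in row-major cell order (see [cell_index()]).
#'
#' @param values numeric N^2 x K matrix; each row must sum to 1 (within
#'   1e-9) with entries in [0, 1].
#' @param grid a [grid_spec()].
#' @return an object of class \code{prob_maps}.
#' @examples
#' g <- grid_spec(3)
#' p <- prob_maps(matrix(1 / 2, n_cells(g), 2), g)
#' to_segmentation(p)
#' @export
prob_maps <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != n_cells(grid))
    stop("values must have N^2 rows", call. = FALSE)
  K <- ncol(values)
  if (K < 1L)
    stop("K must be at least 1", call. = FALSE)
  if (anyNA(values) || any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(values) - 1) > 1e-9))
    stop("each row of a prob_maps must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  structure(list(values = pmin(pmax(values, 0), 1), K = K, grid = grid),
            class = "prob_maps")
}

#' @export
print.prob_maps <- function(x, ...) {
  cat(sprintf("<prob_maps> K = %d segments on a %d x %d grid\n",
              x$K, x$grid$N, x$grid$N))
  invisible(x)
}

#' One-hot probabilistic maps from a segmentation map
#'
#' @param segmap a [seg_map()] (or integer matrix of labels).
#' @param K number of channels; defaults to the largest label.
#' @param grid grid used when \code{segmap} is a bare matrix.
#' @return a \code{prob_maps} whose rows are indicator vectors.
#' @export
one_hot_maps <- function(segmap, K = NULL, grid = NULL) {
  if (inherits(segmap, "seg_map")) {
    grid <- segmap$grid
    labels <- as.integer(t(segmap$labels))  # row-major cell order
  } else {
    stopifnot(inherits(grid, "grid_spec"))
    labels <- as.integer(t(as.matrix(segmap)))
  }
  if (is.null(K)) K <- max(labels)
  if (any(labels < 1L | labels > K))
    stop("labels must lie in 1..K", call. = FALSE)
  v <- matrix(0, length(labels), K)
  v[cbind(seq_along(labels), labels)] <- 1
  prob_maps(v, grid)
}

#' Hard segmentation map
#'
#' Integer label in 1..K per grid element. When derived from probabilistic
#' maps the label is the argmax segment, ties broken toward the smallest
#' label index.
#'
#' @param labels integer N x N matrix of labels.
#' @param grid a [grid_spec()].
#' @param K number of segments the labels refer to.
#' @return an object of class \code{seg_map}.
#' @export
seg_map <- function(labels, grid, K = max(labels)) {
  stopifnot(inherits(grid, "grid_spec"))
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(dim(labels) == grid$N))
    stop("labels must be an N x N matrix", call. = FALSE)
  if (anyNA(labels) || any(labels < 1L) || any(labels > K))
    stop("labels must lie in 1..K", call. = FALSE)
  structure(list(labels = labels, K = as.integer(K), grid = grid),
            class = "seg_map")
}

#' @export
print.seg_map <- function(x, ...) {
  cat(sprintf("<seg_map> %d x %d grid, %d segment labels\n",
              x$grid$N, x$grid$N, x$K))
  invisible(x)
}

#' Scalar field on the cue grid
#'
#' Used for entropy maps and per-pixel error maps.
#'
#' @param value numeric N x N matrix of finite values.
#' @param grid a [grid_spec()].
#' @export
scalar_field <- function(value, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  value <- as.matrix(value)
  storage.mode(value) <- "double"
  if (!all(dim(value) == grid$N))
    stop("value must be an N x N matrix", call. = FALSE)
  if (!all(is.finite(value)))
    stop("scalar field values must be finite", call. = FALSE)
  structure(list(value = value, grid = grid), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d x %d grid, range [%.4g, %.4g]\n",
              x$grid$N, x$grid$N, min(x$value), max(x$value)))
  invisible(x)
}

# N^2 x K value matrix -> N x N matrix for one channel
channel_matrix <- function(maps, k) {
  matrix(maps$values[, k], maps$grid$N, maps$grid$N, byrow = TRUE)
}

#' Minimal number of trials for map reconstruction
#'
#' The probabilistic maps have (K - 1) N^2 free parameters, so at least
#' (K - 1) N^2 pairs must be tested to identify them.
#'
#' @param K number of segments (>= 2).
#' @param N grid side length (>= 3).
#' @return integer trial count \code{(K - 1) * N^2}.
#' @examples
#' minimal_trials(5, 16)  # 1024
#' @export
minimal_trials <- function(K, N) {
  K <- as.integer(K); N <- as.integer(N)
  if (length(K) != 1L || is.na(K) || K < 2L)
    stop("K must be a single integer >= 2", call. = FALSE)
  if (length(N) != 1L || is.na(N) || N < 3L)
    stop("N must be a single integer >= 3", call. = FALSE)
  (K - 1L) * N * N
}

#' Argmax segmentation of probabilistic maps
#'
#' @param maps a [prob_maps()].
#' @return a [seg_map()]; ties broken toward the smallest label index.
#' @export
to_segmentation <- function(maps) {
  stopifnot(inherits(maps, "prob_maps"))
  lab <- max.col(maps$values, ties.method = "first")
  seg_map(matrix(lab, maps$grid$N, maps$grid$N, byrow = TRUE),
          maps$grid, K = maps$K)
}

#' Mean absolute error between probabilistic maps
#'
#' The L1 norm of the difference between the K-tuples of estimated and
#' reference probabilities at each grid element, averaged over elements.
#' Because the reconstruction likelihood is invariant to label permutation,
#' the default aligns channels by the best permutation first.
#'
#' @param est,truth [prob_maps()] on the same grid with the same K.
#' @param align if \code{TRUE} (default), minimize over channel
#'   permutations via [align_labels()] before measuring.
#' @return non-negative scalar; 0 iff the maps agree (up to permutation
#'   when \code{align} is on).
#' @export
mean_absolute_error <- function(est, truth, align = TRUE) {
  stopifnot(inherits(est, "prob_maps"), inherits(truth, "prob_maps"))
  if (!same_grid(est$grid, truth$grid) || est$K != truth$K)
    stop("maps must share the same grid and K", call. = FALSE)
  perm <- if (align) align_labels(est, truth) else seq_len(est$K)
  mean(rowSums(abs(est$values - truth$values[, perm, drop = FALSE])))
}

#' Best channel permutation aligning two probabilistic maps
#'
#' Exhaustive search over all K! permutations of the reference channels,
#' minimizing the unaligned mean absolute error; among minimizers the
#' lexicographically smallest permutation is returned, so the result is
#' deterministic.
#'
#' @param est,ref [prob_maps()] on the same grid with the same K (K <= 8).
#' @return integer permutation \code{perm} of 1..K such that channel k of
#'   \code{est} matches channel \code{perm[k]} of \code{ref}.
#' @export
align_labels <- function(est, ref) {
  stopifnot(inherits(est, "prob_maps"), inherits(ref, "prob_maps"))
  if (!same_grid(est$grid, ref$grid) || est$K != ref$K)
    stop("maps must share the same grid and K", call. = FALSE)
  K <- est$K
  if (K > 8L)
    stop("exhaustive label alignment supports K <= 8", call. = FALSE)
  # K x K cost matrix: total L1 between est channel k and ref channel l
  cost <- matrix(0, K, K)
  for (k in seq_len(K))
    for (l in seq_len(K))
      cost[k, l] <- sum(abs(est$values[, k] - ref$values[, l]))
  perms <- permutations(K)
  tot <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(K), p)]))
  # perms are generated in lexicographic order; which.min takes the first
  unname(perms[which.min(tot), ])
}

# all permutations of 1..K in lexicographic order
permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(K - 1L)
  out <- matrix(0L, 0L, K)
  for (first in seq_len(K)) {
    rest <- seq_len(K)[-first]
    block <- cbind(first, matrix(rest[sub], nrow(sub), K - 1L))
    out <- rbind(out, block)
  }
  out
}

#' Per-element Shannon entropy of probabilistic maps
#'
#' Natural-log entropy -sum_k p log p with 0 log 0 = 0, per grid element,
#' plus a summary (mean over elements and its standard error across
#' elements). Quantifies the measured perceptual uncertainty at each
#' location.
#'
#' @param maps a [prob_maps()].
#' @return list with \code{map} (a [scalar_field()]), \code{mean} and
#'   \code{se}.
#' @export
entropy_map <- function(maps) {
  stopifnot(inherits(maps, "prob_maps"))
  v <- maps$values
  h <- -rowSums(ifelse(v > 0, v * log(v), 0))
  h <- pmax(h, 0)
  list(map = scalar_field(matrix(h, maps$grid$N, maps$grid$N, byrow = TRUE),
                          maps$grid),
       mean = mean(h),
       se = stats::sd(h) / sqrt(length(h)))
}

#' Count channels that carry probability mass
#'
#' When the reconstruction is run with more channels than the true number
#' of segments, regularized fits drive the superfluous channels to
#' (near-)zero everywhere. The true K can then be read off as the number
#' of channels whose maximum probability exceeds a threshold.
#'
#' @param maps a [prob_maps()].
#' @param mass_threshold a channel counts as non-empty when its maximum
#'   over grid elements exceeds this value. The default 0.2 separates
#'   channels that only pick up boundary-blur residue (maxima near 0.1 in
#'   the simulation studies) from genuine segments (maxima above 0.7).
#' @return integer number of non-empty channels.
#' @export
count_nonempty_segments <- function(maps, mass_threshold = 0.2) {
  stopifnot(inherits(maps, "prob_maps"))
  if (!(mass_threshold > 0 && mass_threshold < 1))
    stop("mass_threshold must lie in (0, 1)", call. = FALSE)
  sum(apply(maps$values, 2L, max) > mass_threshold)
}

#' Write probabilistic maps as per-channel CSV files
#'
#' One CSV per channel, N rows x N columns, no header; files are named
#' \code{<prefix>_channel<k>.csv}. Optionally also writes an 8-bit
#' grayscale PNG per channel when the \pkg{png} package is available.
#'
#' @param maps a [prob_maps()].
#' @param prefix path prefix for the output files.
#' @param png also write PNG renderings.
#' @return invisibly, the vector of files written.
#' @export
write_probmaps <- function(maps, prefix, png = FALSE) {
  stopifnot(inherits(maps, "prob_maps"))
  files <- character(0)
  for (k in seq_len(maps$K)) {
    f <- sprintf("%s_channel%d.csv", prefix, k)
    utils::write.table(channel_matrix(maps, k), f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
    if (png && requireNamespace("png", quietly = TRUE)) {
      fp <- sprintf("%s_channel%d.png", prefix, k)
      png::writePNG(channel_matrix(maps, k), fp)
      files <- c(files, fp)
    }
  }
  invisible(files)
}

#' Read probabilistic maps from per-channel CSV files
#'
#' @param prefix the path prefix used by [write_probmaps()].
#' @param K number of channels to read.
#' @return a [prob_maps()].
#' @export
read_probmaps <- function(prefix, K) {
  chans <- lapply(seq_len(K), function(k) {
    f <- sprintf("%s_channel%d.csv", prefix, k)
    as.matrix(utils::read.table(f, sep = ",", header = FALSE))
  })
  N <- nrow(chans[[1L]])
  g <- grid_spec(N)
  v <- vapply(chans, function(m) as.numeric(t(m)), numeric(N * N))
  v <- v / rowSums(v)  # absorb CSV rounding
  prob_maps(v, g)
}

#' Write a segmentation map as a single integer CSV
#' @param segmap a [seg_map()].
#' @param path output file.
#' @export
write_segmap <- function(segmap, path) {
  stopifnot(inherits(segmap, "seg_map"))
  utils::write.table(segmap$labels, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
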