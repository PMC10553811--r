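#' Cue-grid specification
#'
#' Defines the square N x N grid of cue locations superimposed on an image.
#' Grid elements are squares tiling the image; each element is addressed by
#' (row, col) in 1..N and its centre maps to image pixel coordinates
#' \code{(idx - 0.5) * image_size / N}.
#'
#' @param N integer grid side length, at least 3.
#' @param image_size integer image side length in pixels (defaults to
#'   \code{N}, i.e. one grid element per pixel).
#' @return an object of class \code{grid_spec}.
#' @examples
#' g <- grid_spec(11)
#' n_cells(g)
#' @export
grid_spec <- function(N, image_size = N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 3L)
    stop("grid side length N must be a single integer >= 3", call. = FALSE)
  image_size <- as.integer(image_size)
  if (length(image_size) != 1L || is.na(image_size) || image_size < N)
    stop("image_size must be an integer >= N", call. = FALSE)
  structure(list(N = N, image_size = image_size), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cue grid on a %d-pixel image\n",
              x$N, x$N, x$image_size))
  invisible(x)
}

#' Number of grid elements
#' @param grid a \code{grid_spec}.
#' @return integer \code{N^2}.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$N * grid$N
}

#' Convert (row, col) grid coordinates to linear cell indices
#'
#' Cells are numbered row-major: \code{idx = (row - 1) * N + col}.
#'
#' @param grid a \code{grid_spec}.
#' @param row,col integer vectors in 1..N.
#' @return integer vector of linear indices in 1..N^2.
#' @export
cell_index <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 1L | row > grid$N | col < 1L | col > grid$N, na.rm = FALSE) ||
      anyNA(row) || anyNA(col))
    stop(sprintf("grid coordinates out of bounds for N = %d", grid$N),
         call. = FALSE)
  (row - 1L) * grid$N + col
}

#' Convert linear cell indices back to (row, col) coordinates
#' @param grid a \code{grid_spec}.
#' @param idx integer vector of linear indices.
#' @return data.frame with columns \code{row}, \code{col}.
#' @export
cell_coords <- function(grid, idx) {
  stopifnot(inherits(grid, "grid_spec"))
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L | idx > n_cells(grid)))
    stop("cell index out of bounds", call. = FALSE)
  data.frame(row = (idx - 1L) %/% grid$N + 1L,
             col = (idx - 1L) %% grid$N + 1L)
}

same_grid <- function(a, b) {
  identical(a$N, b$N)
}
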