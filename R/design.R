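#' Set of tested pixel pairs
#'
#' Unordered pairs of distinct grid elements; a pair and its mirror count
#' as the same element. Stored canonically with the smaller linear cell
#' index first.
#'
#' @param i,j integer vectors of linear cell indices (see [cell_index()]).
#' @param grid a [grid_spec()].
#' @return an object of class \code{pair_set} with integer columns
#'   \code{i}, \code{j} (i < j after canonicalization).
#' @export
pair_set <- function(i, j, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j))
    stop("i and j must have equal length", call. = FALSE)
  M <- n_cells(grid)
  if (anyNA(i) || anyNA(j) || any(i < 1L | i > M | j < 1L | j > M))
    stop("pair indices out of grid bounds", call. = FALSE)
  if (any(i == j))
    stop("pairs of identical points are uninformative and not allowed",
         call. = FALSE)
  a <- pmin(i, j); b <- pmax(i, j)
  structure(list(i = a, j = b, grid = grid), class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d unordered pairs on a %d x %d grid\n",
              length(x$i), x$grid$N, x$grid$N))
  invisible(x)
}

#' @export
length.pair_set <- function(x) length(x$i)

#' Schedule tested pairs for an experiment or simulation
#'
#' Builds a pseudo-random pair design of exactly \code{n_trials} unordered
#' pairs in which every grid element is tested at least once, no element is
#' over-used (per-element appearance count stays below
#' \code{ceiling(2 * n_trials / N^2) + 1}), and partners are preferentially
#' drawn at Chebyshev distance at least \code{min_distance}, so the tested
#' pairs are scattered across the image rather than clustered locally.
#'
#' @param grid a [grid_spec()].
#' @param K expected number of segments; fixes the identifiability bound
#'   \code{minimal_trials(K, N)} below which the design is rejected.
#' @param n_trials number of pairs; default \code{K * N^2}, one more
#'   equation per element than strictly necessary.
#' @param seed integer seed; the design is reproducible given the seed.
#' @param min_distance minimum preferred Chebyshev partner distance in
#'   grid units; default \code{N / 4}.
#' @return a [pair_set()].
#' @export
schedule_pairs <- function(grid, K, n_trials = K * n_cells(grid),
                           seed = 1L, min_distance = grid$N / 4) {
  stopifnot(inherits(grid, "grid_spec"))
  if (min_distance < 0) stop("min_distance must be >= 0", call. = FALSE)
  N <- grid$N
  minimum <- minimal_trials(K, N)
  if (n_trials < minimum)
    stop(sprintf(
      "n_trials = %d is below the identifiability bound (K - 1) N^2 = %d",
      n_trials, minimum), call. = FALSE)
  M <- n_cells(grid)
  cap <- ceiling(2 * n_trials / M) + 1
  coords <- cell_coords(grid, seq_len(M))
  with_seed(seed, {
    degree <- integer(M)
    ia <- integer(n_trials); ib <- integer(n_trials)
    seen <- new.env(hash = TRUE, size = 2L * n_trials)
    for (t in seq_len(n_trials)) {
      # least-tested element first guarantees coverage within the first M trials
      cand <- which(degree == min(degree))
      i <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      cheb <- pmax(abs(coords$row - coords$row[i]),
                   abs(coords$col - coords$col[i]))
      ok_far  <- cheb >= min_distance & degree < cap
      ok_near <- seq_len(M) != i & degree < cap
      j <- pick_partner(i, which(ok_far), which(ok_near), seen)
      if (is.na(j)) { # last resort: ignore the load cap, keep i != j
        pool <- setdiff(seq_len(M), i)
        j <- pool[sample.int(length(pool), 1L)]
      }
      ia[t] <- i; ib[t] <- j
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
      assign(pair_key(i, j), TRUE, envir = seen)
    }
    pair_set(ia, ib, grid)
  })
}

pair_key <- function(i, j) paste0(min(i, j), "_", max(i, j))

# try scattered unused partners, then any unused, then scattered used ones
pick_partner <- function(i, far, near, seen) {
  for (pool in list(far, near)) {
    pool <- setdiff(pool, i)
    while (length(pool)) {
      idx <- if (length(pool) == 1L) 1L else sample.int(length(pool), 1L)
      j <- pool[idx]
      if (!exists(pair_key(i, j), envir = seen, inherits = FALSE)) return(j)
      pool <- pool[-idx]
    }
  }
  for (pool in list(far, near)) { # allow duplicate pairs if unavoidable
    pool <- setdiff(pool, i)
    if (length(pool)) return(pool[sample.int(length(pool), 1L)])
  }
  NA_integer_
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Validate a pair set
#'
#' Report-only diagnostics: identical-point pairs, grid elements never
#' tested, duplicated unordered pairs, and the per-element degree
#' distribution.
#'
#' @param pairset a [pair_set()].
#' @return list with \code{coverage} (logical), \code{uncovered} (cell
#'   indices), \code{n_duplicates}, \code{n_identical}, and
#'   \code{degree_table}.
#' @export
validate_pairset <- function(pairset) {
  stopifnot(inherits(pairset, "pair_set"))
  M <- n_cells(pairset$grid)
  deg <- tabulate(c(pairset$i, pairset$j), nbins = M)
  uncovered <- which(deg == 0L)
  key <- paste0(pairset$i, "_", pairset$j)
  list(coverage = length(uncovered) == 0L,
       uncovered = uncovered,
       n_duplicates = sum(duplicated(key)),
       n_identical = sum(pairset$i == pairset$j),
       degree_table = table(deg))
}

#' Per-pixel design diagnostic against a known segmentation
#'
#' In the ideal design for a deterministic K-segment map, every pixel is
#' tested against one same-segment partner and one partner in each of the
#' other K - 1 segments. Given a ground-truth segmentation this reports
#' the fraction of pixels whose partner set spans all K segments.
#'
#' @param pairset a [pair_set()].
#' @param segmap a [seg_map()] on the same grid.
#' @return fraction in [0, 1].
#' @export
partner_span_fraction <- function(pairset, segmap) {
  stopifnot(inherits(pairset, "pair_set"), inherits(segmap, "seg_map"))
  if (!same_grid(pairset$grid, segmap$grid))
    stop("pair set and segmentation must share a grid", call. = FALSE)
  lab <- as.integer(t(segmap$labels))
  M <- n_cells(pairset$grid)
  spans <- vapply(seq_len(M), function(i) {
    partners <- c(pairset$j[pairset$i == i], pairset$i[pairset$j == i])
    length(unique(lab[partners])) == segmap$K
  }, logical(1))
  mean(spans)
}

#' Response dataset
#'
#' Per-trial records of the same/different task: which block, which pair
#' of grid elements, and the binary response (1 = "same segment").
#' Multiple blocks give repeated Bernoulli observations per pair.
#'
#' @param data data.frame with integer columns \code{block}, \code{i},
#'   \code{j} (linear cell indices) and \code{response} in \{0, 1\}.
#' @param grid a [grid_spec()].
#' @return an object of class \code{response_dataset}.
#' @export
response_dataset <- function(data, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(data))
  need <- c("block", "i", "j", "response")
  if (!all(need %in% names(data)))
    stop("data must have columns block, i, j, response", call. = FALSE)
  data <- data[need]
  for (cn in need) data[[cn]] <- as.integer(data[[cn]])
  if (!all(data$response %in% c(0L, 1L)))
    stop("responses must be binary (0/1)", call. = FALSE)
  if (any(data$block < 1L))
    stop("block indices must be >= 1", call. = FALSE)
  M <- n_cells(grid)
  if (any(data$i < 1L | data$i > M | data$j < 1L | data$j > M))
    stop("pair indices out of grid bounds", call. = FALSE)
  if (any(data$i == data$j))
    stop("pairs of identical points are not allowed", call. = FALSE)
  a <- pmin(data$i, data$j); b <- pmax(data$i, data$j)
  data$i <- a; data$j <- b
  structure(list(data = data, grid = grid,
                 n_blocks = max(data$block)),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf(
    "<response_dataset> %d trials, %d block(s), %d x %d grid, mean(same) = %.3f\n",
    nrow(x$data), x$n_blocks, x$grid$N, x$grid$N, mean(x$data$response)))
  invisible(x)
}

#' Empirical same-segment proportions per pair
#'
#' Aggregates the responses over blocks: for each unordered pair, the
#' proportion of "same" responses and the number of observations. These
#' proportions are the sufficient statistics the squared-error objective
#' consumes.
#'
#' @param dataset a [response_dataset()].
#' @return data.frame of class \code{proportion_table} with columns
#'   \code{i}, \code{j}, \code{k} (proportion in [0, 1]), \code{n_same},
#'   \code{n_obs}; the grid is attached as attribute \code{grid}.
#' @export
empirical_proportions <- function(dataset) {
  stopifnot(inherits(dataset, "response_dataset"))
  d <- dataset$data
  key <- paste0(d$i, "_", d$j)
  agg <- stats::aggregate(d$response, by = list(key = key, i = d$i, j = d$j),
                          FUN = function(r) c(sum(r), length(r)))
  tab <- data.frame(i = agg$i, j = agg$j,
                    n_same = agg$x[, 1L], n_obs = agg$x[, 2L])
  tab <- tab[order(tab$i, tab$j), , drop = FALSE]
  rownames(tab) <- NULL
  tab$k <- tab$n_same / tab$n_obs
  tab <- tab[c("i", "j", "k", "n_same", "n_obs")]
  attr(tab, "grid") <- dataset$grid
  class(tab) <- c("proportion_table", "data.frame")
  tab
}

#' Write responses to CSV
#'
#' Column layout: \code{block,i_row,i_col,j_row,j_col,response} with
#' 1-based grid coordinates. [read_responses()] inverts this exactly.
#'
#' @param dataset a [response_dataset()].
#' @param path output file.
#' @export
write_responses <- function(dataset, path) {
  stopifnot(inherits(dataset, "response_dataset"))
  d <- dataset$data
  ci <- cell_coords(dataset$grid, d$i)
  cj <- cell_coords(dataset$grid, d$j)
  out <- data.frame(block = d$block,
                    i_row = ci$row, i_col = ci$col,
                    j_row = cj$row, j_col = cj$col,
                    response = d$response)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read responses from CSV
#'
#' @param path CSV file written by [write_responses()] (header
#'   \code{block,i_row,i_col,j_row,j_col,response}, 1-based coordinates).
#' @param grid a [grid_spec()]; coordinates are checked against it.
#' @return a [response_dataset()].
#' @export
read_responses <- function(path, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  raw <- utils::read.csv(path, header = TRUE)
  need <- c("block", "i_row", "i_col", "j_row", "j_col", "response")
  if (!all(need %in% names(raw)))
    stop(sprintf("%s: expected header %s", path, paste(need, collapse = ",")),
         call. = FALSE)
  for (cn in need) {
    v <- raw[[cn]]
    vi <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vi) | vi != round(vi))
    if (length(bad))
      stop(sprintf("%s: malformed value in column %s at data line %d",
                   path, cn, bad[1L]), call. = FALSE)
  }
  if (!all(raw$response %in% c(0L, 1L))) {
    bad <- which(!(raw$response %in% c(0L, 1L)))[1L]
    stop(sprintf("%s: non-binary response at data line %d", path, bad),
         call. = FALSE)
  }
  N <- grid$N
  oob <- which(raw$i_row < 1 | raw$i_row > N | raw$i_col < 1 | raw$i_col > N |
                 raw$j_row < 1 | raw$j_row > N | raw$j_col < 1 | raw$j_col > N)
  if (length(oob))
    stop(sprintf("%s: coordinates out of the %d x %d grid at data line %d",
                 path, N, N, oob[1L]), call. = FALSE)
  response_dataset(data.frame(
    block = as.integer(raw$block),
    i = cell_index(grid, raw$i_row, raw$i_col),
    j = cell_index(grid, raw$j_row, raw$j_col),
    response = as.integer(raw$response)), grid)
}

#' Write a pair set to CSV
#' @param pairset a [pair_set()].
#' @param path output file (columns i_row,i_col,j_row,j_col, 1-based).
#' @export
write_pairset <- function(pairset, path) {
  stopifnot(inherits(pairset, "pair_set"))
  ci <- cell_coords(pairset$grid, pairset$i)
  cj <- cell_coords(pairset$grid, pairset$j)
  utils::write.csv(data.frame(i_row = ci$row, i_col = ci$col,
                              j_row = cj$row, j_col = cj$col),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pair set from CSV
#' @param path file written by [write_pairset()].
#' @param grid a [grid_spec()].
#' @export
read_pairset <- function(path, grid) {
  raw <- utils::read.csv(path, header = TRUE)
  pair_set(cell_index(grid, raw$i_row, raw$i_col),
           cell_index(grid, raw$j_row, raw$j_col), grid)
}
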