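# Shared fixtures, built in code.

# small random probabilistic maps (rows drawn from a symmetric Dirichlet)
random_maps <- function(N, K, seed) {
  g <- grid_spec(N)
  set.seed(seed)
  v <- matrix(rexp(N * N * K), N * N, K)
  prob_maps(v / rowSums(v), g)
}

# permute the channels of a prob_maps
permute_channels <- function(maps, perm) {
  prob_maps(maps$values[, perm, drop = FALSE], maps$grid)
}

# exhaustive pair set: all unordered pairs of distinct cells
exhaustive_pairs <- function(grid) {
  M <- n_cells(grid)
  idx <- utils::combn(M, 2L)
  pair_set(idx[1L, ], idx[2L, ], grid)
}

# independent per-trial BCE: explicit loop over the long trial records
bce_by_enumeration <- function(maps, dataset, delta = 1e-12) {
  d <- dataset$data
  tot <- 0
  for (t in seq_len(nrow(d))) {
    p <- sum(maps$values[d$i[t], ] * maps$values[d$j[t], ])
    p <- min(max(p, delta), 1 - delta)
    r <- d$response[t]
    tot <- tot - r * log(p) - (1 - r) * log(1 - p)
  }
  tot
}

# independent SE: explicit loop over the proportion table
se_by_enumeration <- function(maps, proportions) {
  tot <- 0
  for (t in seq_len(nrow(proportions))) {
    p <- sum(maps$values[proportions$i[t], ] * maps$values[proportions$j[t], ])
    tot <- tot + (proportions$k[t] - p)^2
  }
  tot
}

# independent penalty: replicate-padded convolution by explicit loops
penalty_by_loops <- function(maps, cfg) {
  N <- maps$grid$N
  G <- cfg$kernel
  hr <- (nrow(G) - 1L) %/% 2L
  hc <- (ncol(G) - 1L) %/% 2L
  tot <- 0
  for (k in seq_len(maps$K)) {
    ch <- matrix(maps$values[, k], N, N, byrow = TRUE)
    for (r in seq_len(N)) for (c in seq_len(N)) {
      acc <- 0
      for (dr in -hr:hr) for (dc in -hc:hc) {
        rr <- min(max(r - dr, 1L), N)
        cc <- min(max(c - dc, 1L), N)
        acc <- acc + G[dr + hr + 1L, dc + hc + 1L] * ch[rr, cc]
      }
      tot <- tot + (ch[r, c] - acc)^2
    }
  }
  cfg$lambda * tot
}
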