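# shared fixtures and independent oracles used across test files

# minimal synthetic profile: k markers with chosen means/sds on a small
# band library
toy_profile <- function(means, sds, loading, offset, name = "toy") {
  species_profile(name, means, sds, loading, offset)
}

toy_bands <- function(centers = c(9000, 7000, 5000), widths = 100,
                      mode = "NIR") {
  band_library(mode, centers = centers, widths = widths,
               assignments = rep("toy", length(centers)))
}

# brute-force triple-loop asynchronous map (independent of the matrix-product
# implementation)
async_brute <- function(K) {
  m <- nrow(K); p <- ncol(K)
  N <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m))
    if (a != b) N[a, b] <- 1 / (pi * (b - a))
  out <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    s <- 0
    for (a in seq_len(m)) for (b in seq_len(m))
      s <- s + K[a, j] * N[a, b] * K[b, k]
    out[j, k] <- s / (m - 1)
  }
  out
}

# independent re-derivation of greedy Kennard-Stone selection, written as
# plain O(n^3) loops over the definition
ks_brute <- function(X, n_train) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(1, 2); bestd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_train) {
    cand_best <- NA; cand_d <- -Inf
    for (i in setdiff(seq_len(n), sel)) {
      dmin <- min(D[i, sel])
      if (dmin > cand_d) { cand_d <- dmin; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# two well-separated point clouds for classifier tests
two_clouds <- function(n_per = 10, sep = 8, p = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}
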