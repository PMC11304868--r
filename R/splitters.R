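#' Kennard-Stone sample-set partitioning
#'
#' Deterministic max-min-distance selection of a representative training
#' set: seed with the pair at maximal Euclidean distance, then iteratively
#' add the candidate whose minimum distance to the selected set is largest.
#' Ties (e.g. duplicated rows) are resolved toward the lowest row index.
#'
#' @param X Samples x features numeric matrix.
#' @param n_train Training-set size, `2 <= n_train <= nrow(X) - 1`.
#' @param center Mean-center the features before computing distances
#'   (default `FALSE`: raw feature rows).
#' @return Object of class `split_result`: `train_idx` (in selection order),
#'   `test_idx`, `method`, `ratio`.
#' @export
#' @examples
#' kennard_stone(matrix(c(0, 1, 10)), n_train = 2)$train_idx  # 1 and 3
kennard_stone <- function(X, n_train, center = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_train < 2 || n_train > n - 1)
    stop("n_train must satisfy 2 <= n_train <= n - 1")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  D <- as.matrix(stats::dist(X))
  sel <- seed_farthest_pair(D)
  dmin <- pmin(D[, sel[1]], D[, sel[2]])
  dmin[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(dmin)          # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    dmin <- pmin(dmin, D[, nxt])
    dmin[nxt] <- -Inf
  }
  new_split(sel, setdiff(seq_len(n), sel), "KS", n_train / n)
}

#' Kennard-Stone duplex partitioning
#'
#' Duplex variant: the two farthest points seed the calibration set, the two
#' farthest remaining points seed the validation set, and further points are
#' assigned alternately (calibration first) by the same max-min-distance
#' rule until the validation quota `round(n * (1 - ratio))`
#' (half away from zero) is filled; all remaining points go to calibration.
#'
#' @param X Samples x features numeric matrix (n >= 4).
#' @param ratio Training (calibration) fraction in (0, 1); default 2/3, which
#'   divides 30 samples into 20 calibration and 10 validation.
#' @param center Mean-center features before distances (default `FALSE`).
#' @return A `split_result` with `method = "KS-duplex"`.
#' @export
ks_duplex <- function(X, ratio = 2 / 3, center = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("ks_duplex needs n >= 4")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  quota_val <- floor(n * (1 - ratio) + 0.5)
  quota_val <- max(2L, min(quota_val, n - 2L))
  D <- as.matrix(stats::dist(X))
  remaining <- rep(TRUE, n)
  cal <- seed_farthest_pair(D)
  remaining[cal] <- FALSE
  Dr <- D; Dr[!remaining, ] <- -1; Dr[, !remaining] <- -1
  val <- seed_farthest_pair(Dr)
  remaining[val] <- FALSE
  dmin_cal <- apply(D[, cal, drop = FALSE], 1, min)
  dmin_val <- apply(D[, val, drop = FALSE], 1, min)
  turn <- "cal"
  while (any(remaining)) {
    if (length(val) >= quota_val) turn <- "cal"
    if (turn == "cal") {
      cand <- dmin_cal; cand[!remaining] <- -Inf
      nxt <- which.max(cand)
      cal <- c(cal, nxt)
      dmin_cal <- pmin(dmin_cal, D[, nxt])
      turn <- "val"
    } else {
      cand <- dmin_val; cand[!remaining] <- -Inf
      nxt <- which.max(cand)
      val <- c(val, nxt)
      dmin_val <- pmin(dmin_val, D[, nxt])
      turn <- "cal"
    }
    remaining[nxt] <- FALSE
  }
  new_split(cal, val, "KS-duplex", 1 - quota_val / n)
}

seed_farthest_pair <- function(D) {
  ij <- which(D == max(D), arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]   # lowest index on ties
  as.integer(ij[1, ])
}

new_split <- function(train_idx, test_idx, method, ratio) {
  structure(list(train_idx = as.integer(train_idx),
                 test_idx = as.integer(test_idx),
                 method = method, ratio = ratio),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result (%s): %d train / %d test (ratio %.3f)\n",
              x$method, length(x$train_idx), length(x$test_idx), x$ratio))
  invisible(x)
}

#' Write a split to CSV (sample ID, subset, selection rank)
#'
#' @param split A `split_result`.
#' @param sample_ids Sample identifiers, indexed by the split's indices.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_split <- function(split, sample_ids, path) {
  df <- rbind(
    data.frame(sample_id = sample_ids[split$train_idx], subset = "train",
               selection_rank = seq_along(split$train_idx)),
    data.frame(sample_id = sample_ids[split$test_idx], subset = "test",
               selection_rank = seq_along(split$test_idx)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
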