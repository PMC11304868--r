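#' Dynamic spectra (reference-subtracted intensity matrix)
#'
#' Builds the m x p matrix of dynamic spectra K, where row i is spectrum i
#' minus the reference spectrum. With the default mean reference every
#' column of K sums to zero; the sample index plays the role of the
#' perturbation variable, so row order matters for the asynchronous map and
#' is recorded.
#'
#' @param table A [spectra_table] or coercible object with m >= 2 spectra.
#' @param reference `"mean"` (default) or an explicit reference spectrum on
#'   the same grid.
#' @return Object of class `dynamic_spectra`: `wavenumbers`, `K`,
#'   `reference`, `order` (sample IDs in perturbation order).
#' @export
dynamic_spectra <- function(table, reference = "mean") {
  table <- as_spectra_table(table)
  m <- nrow(table$spectra)
  if (m < 2) stop("need at least 2 spectra (m >= 2)")
  if (identical(reference, "mean")) {
    ref <- colMeans(table$spectra)
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != length(table$wavenumbers))
      stop("reference grid mismatch: expected length ", length(table$wavenumbers))
  }
  K <- sweep(table$spectra, 2, ref)
  structure(list(wavenumbers = table$wavenumbers, K = unname(K),
                 reference = ref, order = table$sample_ids),
            class = "dynamic_spectra")
}

#' Hilbert-Noda transformation matrix
#'
#' The m x m antisymmetric matrix with `N[j,k] = 1/(pi*(k-j))` off the
#' diagonal and 0 on it, used to compute the asynchronous correlation map.
#'
#' @param m Number of perturbation steps (>= 2).
#' @return m x m numeric matrix.
#' @export
#' @examples
#' noda_matrix(2)   # [[0, 1/pi], [-1/pi, 0]]
noda_matrix <- function(m) {
  if (m < 2) stop("m must be >= 2")
  j <- seq_len(m)
  d <- outer(j, j, function(a, b) b - a)
  N <- ifelse(d == 0, 0, 1 / (pi * d))
  N
}

#' Synchronous 2D correlation map
#'
#' `Phi = t(K) %*% K / (m - 1)`: the covariance-like map of in-phase
#' intensity changes. Symmetric; with a mean reference its diagonal equals
#' the per-wavenumber sample variance.
#'
#' @param dyn A [dynamic_spectra] object.
#' @return p x p symmetric matrix.
#' @export
synchronous_map <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_spectra"))
  m <- nrow(dyn$K)
  crossprod(dyn$K) / (m - 1)
}

#' Asynchronous 2D correlation map
#'
#' `phi = t(K) %*% N %*% K / (m - 1)` with N the Hilbert-Noda matrix:
#' the map of out-of-phase (sequential) intensity changes. Antisymmetric;
#' identically zero when all variation is perfectly correlated (rank-one K).
#'
#' @param dyn A [dynamic_spectra] object.
#' @return p x p antisymmetric matrix.
#' @export
asynchronous_map <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_spectra"))
  m <- nrow(dyn$K)
  N <- noda_matrix(m)
  crossprod(dyn$K, N %*% dyn$K) / (m - 1)
}

#' Compute synchronous and asynchronous correlation maps
#'
#' Convenience wrapper computing both maps, optionally on a wavenumber
#' subrange (maps are then computed on the restricted grid, the default
#' convention for per-region analyses).
#'
#' @param table A [spectra_table] or coercible object.
#' @param reference `"mean"` or explicit reference spectrum (full grid).
#' @param subrange Optional `c(lo, hi)` wavenumber window (cm^-1).
#' @return Object of class `correlation_maps`: `wavenumbers`, `sync`,
#'   `async`, `m`, `order`.
#' @export
#' @examples
#' ds <- generate_dataset(n_per_species = 3, seed = 1)
#' maps <- correlation_maps(ds, subrange = c(5300, 7000))
correlation_maps <- function(table, reference = "mean", subrange = NULL) {
  table <- as_spectra_table(table)
  if (!is.null(subrange)) {
    keep <- table$wavenumbers >= min(subrange) & table$wavenumbers <= max(subrange)
    if (sum(keep) < 2) stop("subrange covers fewer than 2 grid points")
    ref <- if (identical(reference, "mean")) "mean" else as.numeric(reference)[keep]
    table <- spectra_table(table$wavenumbers[keep],
                           table$spectra[, keep, drop = FALSE],
                           table$sample_ids)
    reference <- ref
  }
  dyn <- dynamic_spectra(table, reference)
  structure(list(wavenumbers = dyn$wavenumbers,
                 sync = synchronous_map(dyn),
                 async = asynchronous_map(dyn),
                 m = nrow(dyn$K), order = dyn$order),
            class = "correlation_maps")
}

#' Detect auto peaks on the synchronous diagonal
#'
#' Auto peaks are local maxima of the synchronous-map diagonal (the
#' per-wavenumber intensity variance) above a prominence threshold expressed
#' as a fraction of the diagonal maximum.
#'
#' @param maps A [correlation_maps] object.
#' @param min_prominence Threshold in (0, 1] (default 0.05).
#' @return data.frame with columns `wavenumber`, `intensity`, ordered by
#'   decreasing intensity; zero rows if the map is flat zero.
#' @export
detect_auto_peaks <- function(maps, min_prominence = 0.05) {
  stopifnot(inherits(maps, "correlation_maps"))
  if (min_prominence <= 0 || min_prominence > 1)
    stop("min_prominence must lie in (0, 1]")
  d <- diag(maps$sync)
  top <- max(d)
  if (top <= 0)
    return(data.frame(wavenumber = numeric(0), intensity = numeric(0)))
  n <- length(d)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) d[i - 1] else -Inf
    right <- if (i < n) d[i + 1] else -Inf
    d[i] >= left && d[i] > right && d[i] >= min_prominence * top
  }, logical(1))
  out <- data.frame(wavenumber = maps$wavenumbers[is_peak],
                    intensity = d[is_peak])
  out[order(-out$intensity), , drop = FALSE]
}

#' Noda's sequential-order rule for one cross peak
#'
#' Given the signs of the synchronous and asynchronous cross peak at
#' (v1, v2) with v1 > v2: equal nonzero signs mean the higher-wavenumber
#' intensity change occurs first; opposite signs mean the lower-wavenumber
#' change occurs first; a zero asynchronous sign means the changes are
#' simultaneous; a zero synchronous sign leaves the order indeterminate.
#'
#' @param sync_sign,async_sign Values in `{-1, 0, 1}` (or any numbers; only
#'   the sign is used).
#' @return One of `"higher wavenumber first"`, `"lower wavenumber first"`,
#'   `"simultaneous"`, `"indeterminate"`.
#' @export
#' @examples
#' sequence_rule(+1, +1)  # higher wavenumber first
#' sequence_rule(+1, -1)  # lower wavenumber first
sequence_rule <- function(sync_sign, async_sign) {
  s <- sign(sync_sign); a <- sign(async_sign)
  if (s == 0) return("indeterminate")
  if (a == 0) return("simultaneous")
  if (s == a) "higher wavenumber first" else "lower wavenumber first"
}

#' Cross-peak table and event ordering for a pair of correlation maps
#'
#' For every pair of detected auto peaks (v1 > v2, the canonical half above
#' the diagonal), reads the synchronous and asynchronous signs at the
#' maximum-|sync| point in a small window around the pair (ties broken
#' toward higher v1) and applies [sequence_rule]. The event order ranks
#' wavenumbers by how often they are inferred to change first.
#'
#' @param maps A [correlation_maps] object.
#' @param min_prominence Passed to [detect_auto_peaks].
#' @param window Half-width (grid steps) of the sign-reading window
#'   (default 2).
#' @return Object of class `peak_report`: `auto_peaks` (data.frame),
#'   `cross_peaks` (data.frame with v1, v2, sync_sign, async_sign, verdict),
#'   `event_order` (wavenumbers, earliest change first), `order` (the
#'   perturbation ordering the asynchronous map assumed).
#' @export
peak_report <- function(maps, min_prominence = 0.05, window = 2) {
  stopifnot(inherits(maps, "correlation_maps"))
  ap <- detect_auto_peaks(maps, min_prominence)
  w <- maps$wavenumbers
  idx <- match(ap$wavenumber, w)
  cross <- NULL
  if (length(idx) >= 2) {
    pairs <- utils::combn(seq_along(idx), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- idx[pairs[1, k]]; j <- idx[pairs[2, k]]
      # canonical half: v1 > v2 (grids are descending so lower index = higher v)
      if (w[i] < w[j]) { tmp <- i; i <- j; j <- tmp }
      ri <- pmax(1, i - window):pmin(length(w), i + window)
      rj <- pmax(1, j - window):pmin(length(w), j + window)
      sub <- maps$sync[ri, rj, drop = FALSE]
      best <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)
      # ties toward higher v1 = smaller row index on a descending grid
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      bi <- ri[best[1]]; bj <- rj[best[2]]
      ss <- sign(maps$sync[bi, bj]); as <- sign(maps$async[bi, bj])
      data.frame(v1 = w[i], v2 = w[j], sync_sign = ss, async_sign = as,
                 verdict = sequence_rule(ss, as))
    })
    cross <- do.call(rbind, rows)
  }
  event_order <- NULL
  if (!is.null(cross) && nrow(cross) > 0) {
    votes <- stats::setNames(numeric(length(ap$wavenumber)), ap$wavenumber)
    for (r in seq_len(nrow(cross))) {
      v <- cross[r, ]
      if (v$verdict == "higher wavenumber first") {
        votes[as.character(v$v1)] <- votes[as.character(v$v1)] + 1
      } else if (v$verdict == "lower wavenumber first") {
        votes[as.character(v$v2)] <- votes[as.character(v$v2)] + 1
      }
    }
    event_order <- as.numeric(names(sort(votes, decreasing = TRUE)))
  }
  structure(list(auto_peaks = ap, cross_peaks = cross,
                 event_order = event_order, order = maps$order),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  cat("peak_report:", nrow(x$auto_peaks), "auto peak(s)\n")
  if (nrow(x$auto_peaks)) print(x$auto_peaks, row.names = FALSE)
  if (!is.null(x$cross_peaks) && nrow(x$cross_peaks)) {
    cat("cross peaks (canonical half, v1 > v2):\n")
    print(x$cross_peaks, row.names = FALSE)
  }
  if (!is.null(x$event_order))
    cat("inferred event order (first -> last):",
        paste(x$event_order, collapse = " -> "), "cm^-1\n")
  invisible(x)
}

#' Export a correlation map as CSV
#'
#' Writes the map as v1 rows x v2 columns with wavenumber headers.
#'
#' @param maps A [correlation_maps] object.
#' @param what `"sync"` or `"async"`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(maps, what = c("sync", "async"), path) {
  what <- match.arg(what)
  m <- maps[[what]]
  dimnames(m) <- list(format_wavenumber(maps$wavenumbers),
                      format_wavenumber(maps$wavenumbers))
  utils::write.csv(as.data.frame(m, check.names = FALSE), path)
  invisible(path)
}
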