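# Deterministic rasterisation of correlation maps: fixed diverging colormap
# symmetric about zero (red = positive, blue = negative), no axes/colorbar,
# nearest-neighbour resampling (no interpolation smoothing).

# map matrix values -> H x W x 3 RGB array in [0,1]
diverging_rgb <- function(z, limit = NULL) {
  if (is.null(limit)) limit <- max(abs(z))
  v <- if (limit > 0) pmin(pmax(z / limit, -1), 1) else z * 0
  r <- ifelse(v >= 0, 1, 1 + v)
  g <- 1 - abs(v)
  b <- ifelse(v >= 0, 1 - v, 1)
  out <- array(0, c(nrow(z), ncol(z), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

resample_matrix <- function(z, size_px) {
  ri <- round(seq(1, nrow(z), length.out = size_px))
  ci <- round(seq(1, ncol(z), length.out = size_px))
  z[ri, ci, drop = FALSE]
}

# Lambertian hillshade of the (normalised) surface; gives the "3DCOS"
# surface-relief rendering. relief scales surface height in pixel units.
hillshade <- function(z, relief = 25) {
  limit <- max(abs(z))
  zn <- if (limit > 0) z / limit * relief else z * 0
  n <- nrow(zn); m <- ncol(zn)
  gx <- (zn[c(2:n, n), ] - zn[c(1, 1:(n - 1)), ]) / 2
  gy <- (zn[, c(2:m, m)] - zn[, c(1, 1:(m - 1))]) / 2
  light <- c(0.5, 0.5, 0.7); light <- light / sqrt(sum(light^2))
  nrm <- sqrt(gx^2 + gy^2 + 1)
  shade <- pmax((-gx * light[1] - gy * light[2] + light[3]) / nrm, 0)
  0.3 + 0.7 * shade
}

render_map_rgb <- function(z, style = c("contour2d", "surface3d"),
                           size_px = 128, limit = NULL, relief = 25) {
  style <- match.arg(style)
  z <- resample_matrix(z, size_px)
  rgb <- diverging_rgb(z, limit = limit)
  if (style == "surface3d") {
    sh <- hillshade(z, relief = relief)
    for (k in 1:3) rgb[, , k] <- rgb[, , k] * sh
  }
  rgb
}

#' Render a correlation map to a PNG image
#'
#' Rasterises the synchronous or asynchronous map to a square image with a
#' fixed diverging colormap symmetric about zero (red = positive, white =
#' zero, blue = negative), no axes or colorbar, so the image is pure signal
#' for the image classifier. `"contour2d"` gives the flat 2DCOS view;
#' `"surface3d"` adds deterministic Lambertian surface shading (the 3DCOS
#' view). Rendering is bit-reproducible: identical maps and settings yield
#' byte-identical files.
#'
#' @param maps A [correlation_maps] object (or a bare numeric matrix).
#' @param path Output PNG path.
#' @param what `"sync"` or `"async"`.
#' @param style `"contour2d"` or `"surface3d"`.
#' @param size_px Image edge in pixels (default 128).
#' @param limit Optional fixed colormap half-range; default is the map's
#'   absolute maximum (symmetric normalisation, so sign survives).
#' @return Invisibly, `path`.
#' @export
render_maps <- function(maps, path, what = c("sync", "async"),
                        style = c("contour2d", "surface3d"), size_px = 128,
                        limit = NULL) {
  what <- match.arg(what); style <- match.arg(style)
  z <- if (inherits(maps, "correlation_maps")) maps[[what]] else as.matrix(maps)
  rgb <- render_map_rgb(z, style = style, size_px = size_px, limit = limit)
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' Per-sample correlation images for the image classifier
#'
#' For each sample, forms the dynamic spectrum against a common reference
#' (default: the mean spectrum of all samples, or of a supplied index set
#' such as the training split), computes the sample's synchronous
#' self-correlation map on a grid resampled to `size_px` points, and renders
#' it in the requested style. Computing the map directly on the resampled
#' grid makes per-sample image generation cheap without changing the
#' rendered content.
#'
#' @param table A [spectra_table] or coercible object.
#' @param reference `"mean"`, or indices of the samples whose mean defines
#'   the reference (e.g. a training split), or an explicit spectrum.
#' @param style `"contour2d"` or `"surface3d"` (default, the 3DCOS view).
#' @param size_px Image edge (default 128).
#' @return Array n x size_px x size_px x 3 of RGB values in [0, 1].
#' @export
sample_correlation_images <- function(table, reference = "mean",
                                      style = "surface3d", size_px = 128) {
  table <- as_spectra_table(table)
  x <- table$spectra
  if (identical(reference, "mean")) {
    ref <- colMeans(x)
  } else if (length(reference) < ncol(x) && all(reference == round(reference))) {
    ref <- colMeans(x[as.integer(reference), , drop = FALSE])
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != ncol(x)) stop("reference grid mismatch")
  }
  # resample spectra and reference onto a size_px-point grid
  ci <- round(seq(1, ncol(x), length.out = size_px))
  xs <- x[, ci, drop = FALSE]
  refs <- ref[ci]
  out <- array(0, c(nrow(x), size_px, size_px, 3))
  for (i in seq_len(nrow(x))) {
    d <- xs[i, ] - refs
    z <- tcrossprod(d)           # per-sample synchronous self-correlation
    out[i, , , ] <- render_map_rgb(z, style = style, size_px = size_px)
  }
  dimnames(out) <- list(table$sample_ids, NULL, NULL, NULL)
  out
}

#' Write per-sample correlation images into per-class folders
#'
#' @param images Array from [sample_correlation_images].
#' @param labels Class label per sample.
#' @param dir Output directory; one subfolder per class is created.
#' @return Invisibly, the vector of file paths.
#' @export
write_image_folders <- function(images, labels, dir) {
  labels <- as.character(labels)
  ids <- dimnames(images)[[1]]
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(dim(images)[1]))
  paths <- character(dim(images)[1])
  for (i in seq_len(dim(images)[1])) {
    sub <- file.path(dir, gsub("[^A-Za-z0-9_-]", "_", labels[i]))
    if (!dir.exists(sub)) dir.create(sub, recursive = TRUE)
    paths[i] <- file.path(sub, paste0(ids[i], ".png"))
    png::writePNG(images[i, , , ], target = paths[i])
  }
  invisible(paths)
}
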