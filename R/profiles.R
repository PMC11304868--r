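#' Construct a species profile for the spectrum generator
#'
#' A species profile couples the per-marker concentration distribution
#' (mean +/- SD) of one bolete species to the band model of the simulated
#' spectrometer: a nonnegative `loading_matrix` (bands x markers) mapping
#' concentrations to band amplitudes, plus a per-band `species_offset`
#' describing the marker-independent matrix absorbance of that species.
#'
#' @param name Species identifier.
#' @param marker_means,marker_sds Numeric vectors of equal length (the 16
#'   markers for the default profiles); SDs must be nonnegative.
#' @param loading_matrix Nonnegative matrix, `length(species_offset)` rows x
#'   `length(marker_means)` columns.
#' @param species_offset Per-band baseline amplitude (absorbance units).
#' @param units Optional per-marker unit strings.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name, marker_means, marker_sds, loading_matrix,
                            species_offset, units = NULL) {
  if (length(marker_means) != length(marker_sds))
    stop("marker_means and marker_sds must have identical length")
  if (any(marker_sds < 0)) stop("marker SDs must be nonnegative")
  loading_matrix <- as.matrix(loading_matrix)
  if (any(loading_matrix < 0)) stop("loading_matrix entries must be nonnegative")
  if (ncol(loading_matrix) != length(marker_means))
    stop("loading_matrix must have one column per marker")
  if (nrow(loading_matrix) != length(species_offset))
    stop("loading_matrix must have one row per band (= length of species_offset)")
  structure(list(name = name,
                 marker_means = marker_means,
                 marker_sds = marker_sds,
                 loading_matrix = loading_matrix,
                 species_offset = species_offset,
                 units = units),
            class = "species_profile")
}

#' Default band assignment of the 16 markers
#'
#' Which markers contribute to which band of the default band library. The
#' assignment reflects the variance structure of the marker reference table:
#' the four markers whose within-species spread is largest relative to their
#' between-species spread (L-Asparagine, N-Acetylaspartate,
#' N-Isovaleroylglycine, N-alpha-Acetyl-L-glutamine) are placed on
#' sparsely occupied bands of their own so that their concentrations remain
#' linearly recoverable from band amplitudes; the remaining markers share
#' the first four bands in groups balanced by their squared within-species
#' coefficients of variation. This keeps the concentration -> spectrum
#' linear map well-posed for every marker.
#'
#' @param n_bands 7 (NIR) or 8 (FTIR) for the curated assignment; other
#'   counts fall back to round-robin.
#' @return List of integer vectors, one per band (marker indices into the
#'   rows of [bolete_marker_table]).
#' @export
default_band_assignment <- function(n_bands) {
  if (n_bands == 7) {
    list(c(11L, 16L, 9L), c(3L, 15L, 1L), c(2L, 7L, 12L), c(5L, 8L, 10L),
         c(4L, 6L), 13L, 14L)
  } else if (n_bands == 8) {
    list(c(11L, 16L, 9L), c(3L, 15L, 1L), c(2L, 7L, 12L), c(5L, 8L, 10L),
         4L, 6L, 13L, 14L)
  } else {
    split(seq_len(16L), rep_len(seq_len(n_bands), 16L))
  }
}

#' Default band-loading matrix linking markers to band amplitudes
#'
#' Beer-Lambert-style linear mixing: each marker adds `amplitude` absorbance
#' units per grand-mean concentration unit to the band(s) it is assigned to
#' (see [default_band_assignment]), so concentration differences modulate
#' band heights around the species matrix absorbance.
#'
#' @param n_bands Number of bands of the target `band_library`.
#' @param grand_means Grand-mean concentration per marker (averaged over the
#'   species), used for unit normalisation.
#' @param amplitude Absorbance contributed by one grand-mean unit of the
#'   marker on a shared band (default 0.03 AU; concentration effects are a
#'   small modulation on the species baseline, as in real powdered-sample
#'   spectra).
#' @param exclusive_amplitude Absorbance per grand-mean unit on a band the
#'   marker occupies alone (default 0.15 AU; a marker given a dedicated band
#'   is, by construction, the dominant absorber there).
#' @param assignment Band assignment (list of marker-index vectors); default
#'   [default_band_assignment].
#' @return Nonnegative matrix, `n_bands` x `length(grand_means)`.
#' @export
default_loading_matrix <- function(n_bands, grand_means, amplitude = 0.03,
                                   exclusive_amplitude = 0.15,
                                   assignment = NULL) {
  p <- length(grand_means)
  if (is.null(assignment)) assignment <- default_band_assignment(n_bands)
  if (length(assignment) != n_bands)
    stop("assignment must list one marker group per band")
  L <- matrix(0, n_bands, p)
  for (b in seq_along(assignment)) {
    a <- if (length(assignment[[b]]) == 1) exclusive_amplitude else amplitude
    for (j in assignment[[b]]) L[b, j] <- a / grand_means[j]
  }
  L
}

#' Default per-band species offsets
#'
#' Species matrix absorbance per band: the first four bands carry
#' species-specific baselines on a Latin-square grid (every species pair
#' differs in every one of these bands, and the four offset patterns plus an
#' intercept span the full five-species contrast space), while the
#' remaining bands have a species-independent baseline, leaving them clean
#' readouts for the markers assigned there.
#'
#' @param n_bands Number of bands.
#' @param base Baseline absorbance common to all bands (default 0.1 AU).
#' @param step Offset increment between Latin-square levels (default 0.15
#'   AU).
#' @return Matrix (5 species x `n_bands`), absorbance units.
#' @export
default_species_offsets <- function(n_bands, base = 0.1, step = 0.15) {
  lat <- cbind(c(0, 1, 2, 3, 4), c(2, 4, 1, 3, 0),
               c(4, 2, 0, 1, 3), c(1, 3, 4, 0, 2))
  off <- matrix(base, 5, n_bands)
  for (k in seq_len(min(4L, n_bands)))
    off[, k] <- base + step * lat[, k]
  rownames(off) <- bolete_species_abbrev()
  off
}

#' Default species profiles of the five boletes
#'
#' Builds one [species_profile] per bolete species from the marker reference
#' table ([bolete_marker_table]), the default loading matrix and the default
#' species offsets for the requested spectral mode.
#'
#' @param mode `"NIR"` or `"FTIR"`.
#' @param bands A [band_library]; defaults to `band_library(mode)`.
#' @param amplitude Passed to [default_loading_matrix].
#' @return Named list of 5 `species_profile` objects.
#' @export
#' @examples
#' profs <- bolete_profiles("NIR")
#' names(profs)
bolete_profiles <- function(mode = c("NIR", "FTIR"), bands = NULL,
                            amplitude = 0.03) {
  mode <- match.arg(mode)
  if (is.null(bands)) bands <- band_library(mode)
  tab <- bolete_marker_table()
  ab <- bolete_species_abbrev()
  nm <- bolete_species()
  grand <- rowMeans(as.matrix(tab[, paste0("mean_", ab)]))
  L <- default_loading_matrix(length(bands$centers), grand,
                              amplitude = amplitude)
  off <- default_species_offsets(length(bands$centers))
  profs <- lapply(seq_along(ab), function(i) {
    species_profile(name = nm[i],
                    marker_means = stats::setNames(tab[[paste0("mean_", ab[i])]], tab$marker),
                    marker_sds = stats::setNames(tab[[paste0("sd_", ab[i])]], tab$marker),
                    loading_matrix = L,
                    species_offset = off[i, ],
                    units = tab$unit)
  })
  names(profs) <- nm
  profs
}
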