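#' Vibrational band library for FT-NIR / ATR-FTIR bolete spectra
#'
#' Band centers of the absorption features that dominate the average bolete
#' spectra: seven NIR bands (overtone/combination region, 10,000--4000
#' cm^-1) and eight mid-IR bands (4000--400 cm^-1), together with Gaussian
#' width parameters and functional-group assignments.
#'
#' @param mode `"NIR"` or `"FTIR"`.
#' @param centers Optional override of band-center wavenumbers (cm^-1).
#' @param widths Optional per-band Gaussian standard deviations (cm^-1);
#'   recycled if length 1. Defaults give mildly overlapping neighbours,
#'   matching the broad absorption features of powdered-mushroom spectra.
#' @param assignments Optional character labels per band.
#' @return An object of class `band_library` with fields `mode`, `centers`,
#'   `widths`, `assignments`.
#' @export
#' @examples
#' band_library("NIR")$centers
band_library <- function(mode = c("NIR", "FTIR"), centers = NULL,
                         widths = NULL, assignments = NULL) {
  mode <- match.arg(mode)
  if (is.null(centers)) {
    centers <- switch(mode,
      NIR  = c(8350, 6776, 6286, 5789, 5160, 4624, 4331),
      FTIR = c(3269, 2926, 1670, 1625, 1553, 1376, 1261, 1018))
  }
  if (is.null(assignments)) {
    assignments <- switch(mode,
      NIR = c("CH/CH2/CH3 2nd overtone", "C-H 2nd overtone (protein)",
              "O-H 2nd overtone (starch)", "CH2/CH 1st overtone",
              "O-H and C-O stretch combination", "C=O-O/C-O/OH 1st overtone",
              "C-H + C-N-C combination (protein/lipid)"),
      FTIR = c("N-H stretch (protein/amino acid)", "C-H stretch (fatty acid/polyol)",
               "amide I (C=O stretch)", "amide I (COO-)", "amide II (N-H bend/C-N)",
               "C-O-H / C-N stretch", "N-H bend (amino acid)",
               "C-C/C-O/C-OH (polysaccharide)"))
    assignments <- assignments[seq_along(centers)]
  }
  if (is.null(widths)) widths <- if (mode == "NIR") 90 else 30
  widths <- rep_len(widths, length(centers))
  rng <- wavenumber_range(mode)
  if (any(centers < rng[1] | centers > rng[2]))
    stop(sprintf("band centers must lie within [%g, %g] cm^-1 for mode %s",
                 rng[1], rng[2], mode))
  if (any(widths <= 0)) stop("band widths must be positive")
  structure(list(mode = mode, centers = centers, widths = widths,
                 assignments = assignments),
            class = "band_library")
}

wavenumber_range <- function(mode) {
  switch(mode, NIR = c(4000, 10000), FTIR = c(400, 4000),
         stop("unknown spectral mode: ", mode))
}

#' Default wavenumber grid for a spectral mode
#'
#' Descending grid (spectroscopy convention) at 8 cm^-1 spectral resolution:
#' 10,000--4000 cm^-1 for FT-NIR, 4000--400 cm^-1 for ATR-FTIR.
#'
#' @param mode `"NIR"` or `"FTIR"`.
#' @param step Grid step in cm^-1 (default 8).
#' @return Numeric vector of wavenumbers, descending.
#' @export
default_wavenumbers <- function(mode = c("NIR", "FTIR"), step = 8) {
  mode <- match.arg(mode)
  rng <- wavenumber_range(mode)
  seq(rng[2], rng[1], by = -abs(step))
}
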