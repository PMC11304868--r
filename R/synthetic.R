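#' Draw marker concentrations for one species
#'
#' Samples each marker from a normal distribution with the profile's mean
#' and SD, truncated at zero (concentrations cannot be negative). Marginals
#' are exact truncated normals via the inverse-CDF construction. Replicate
#' fruiting bodies of one species do not vary independently marker by
#' marker: sample-level drivers (maturity, moisture, total metabolite load)
#' move many metabolites together, so draws share a per-sample latent
#' factor through a Gaussian copula with pairwise latent correlation
#' `within_correlation` (set it to 0 for fully independent draws).
#'
#' @param profile A [species_profile].
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param within_correlation Shared-factor variance fraction on the latent
#'   (copula) scale, in `[0, 1)` (default 0.85).
#' @return `n` x markers matrix with marker names as column names.
#' @export
#' @examples
#' p <- bolete_profiles("NIR")[["Lanmaoa asiatica"]]
#' colMeans(generate_concentrations(p, 200, seed = 1))[["L-Arginine"]]
generate_concentrations <- function(profile, n, seed = NULL,
                                    within_correlation = 0.85) {
  stopifnot(inherits(profile, "species_profile"))
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  if (within_correlation < 0 || within_correlation >= 1)
    stop("within_correlation must lie in [0, 1)")
  mu <- profile$marker_means
  sd <- profile$marker_sds
  if (length(mu) != length(sd))
    stop("mismatched mean/SD lengths in profile")
  if (!is.null(seed)) set.seed(seed)
  p <- length(mu)
  z <- stats::rnorm(n)                       # shared per-sample factor
  eps <- matrix(stats::rnorm(n * p), n, p)
  w <- within_correlation
  u <- stats::pnorm(sqrt(w) * z + sqrt(1 - w) * eps)
  out <- matrix(0, n, p)
  for (j in seq_len(p)) {
    if (sd[j] == 0) {
      out[, j] <- mu[j]
    } else {
      lo <- stats::pnorm(0, mean = mu[j], sd = sd[j])
      out[, j] <- stats::qnorm(lo + u[, j] * (1 - lo), mean = mu[j], sd = sd[j])
    }
  }
  colnames(out) <- names(mu)
  out
}

#' Simulate one absorbance spectrum from marker concentrations
#'
#' Linear (Beer-Lambert-style) mixing model: each band contributes a
#' Gaussian line centred at its band-center wavenumber whose amplitude is
#' `species_offset + loading %*% concentrations`; a polynomial baseline and
#' iid Gaussian noise are added on top.
#'
#' @param concentrations Marker concentration vector (length = columns of the
#'   profile's loading matrix).
#' @param profile A [species_profile].
#' @param bands A [band_library] whose centers lie inside the wavenumber grid.
#' @param wavenumbers Wavenumber grid; defaults to
#'   `default_wavenumbers(bands$mode)`.
#' @param noise_sd SD of iid absorbance noise (default 0 = noiseless).
#' @param baseline Polynomial baseline coefficients `c(b0, b1, b2, ...)` in
#'   the scaled coordinate `(wavenumber - mid)/span` (default none).
#' @param seed Integer seed for the noise draw; `NULL` uses the current
#'   stream.
#' @return Numeric absorbance vector along `wavenumbers`.
#' @export
generate_spectrum <- function(concentrations, profile, bands,
                              wavenumbers = NULL, noise_sd = 0,
                              baseline = 0, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(bands, "band_library"))
  L <- profile$loading_matrix
  if (length(concentrations) != ncol(L))
    stop("concentration vector length must match loading_matrix columns")
  if (nrow(L) != length(bands$centers))
    stop("profile and band library disagree on the number of bands")
  if (is.null(wavenumbers)) wavenumbers <- default_wavenumbers(bands$mode)
  rng <- range(wavenumbers)
  if (any(bands$centers < rng[1] | bands$centers > rng[2]))
    stop("band centers outside the wavenumber grid for mode ", bands$mode)
  amp <- profile$species_offset + as.vector(L %*% as.numeric(concentrations))
  spec <- numeric(length(wavenumbers))
  for (b in seq_along(bands$centers)) {
    spec <- spec + amp[b] *
      exp(-0.5 * ((wavenumbers - bands$centers[b]) / bands$widths[b])^2)
  }
  if (any(baseline != 0)) {
    x <- (wavenumbers - mean(rng)) / diff(rng)
    for (d in seq_along(baseline))
      spec <- spec + baseline[d] * x^(d - 1)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    spec <- spec + stats::rnorm(length(spec), sd = noise_sd)
  }
  spec
}

#' Generate a linked synthetic bolete cohort
#'
#' Draws `n_per_species` marker-concentration vectors per species from the
#' default (or supplied) species profiles and converts each to an FT-NIR or
#' ATR-FTIR absorbance spectrum. Defaults emulate the study cohort: 5
#' species x 19 replicates = 95 samples on an 8 cm^-1 grid with low
#' instrument noise.
#'
#' @param n_per_species Replicates per species (>= 2; default 19).
#' @param mode `"NIR"` or `"FTIR"`.
#' @param noise_sd Absorbance noise SD (default 0.002 AU, typical FT instrument noise).
#' @param seed Integer seed making the whole dataset reproducible.
#' @param profiles Optional list of 5 [species_profile]s.
#' @param bands Optional [band_library].
#' @param baseline Polynomial baseline coefficients (default 0).
#' @param within_correlation Latent cross-marker correlation of replicate
#'   draws (see [generate_concentrations]; default 0.85).
#' @return Object of class `synthetic_dataset`: `wavenumbers`, `spectra`
#'   (samples x wavenumbers), `labels` (factor), `concentrations` (samples x
#'   markers), `sample_ids`, `units`, `seed`, `generator_params`.
#' @export
#' @examples
#' ds <- generate_dataset(n_per_species = 3, mode = "NIR", seed = 1)
#' dim(ds$spectra)
generate_dataset <- function(n_per_species = 19, mode = c("NIR", "FTIR"),
                             noise_sd = 0.002, seed = 1, profiles = NULL,
                             bands = NULL, baseline = 0,
                             within_correlation = 0.85) {
  mode <- match.arg(mode)
  if (n_per_species < 2) stop("n_per_species must be >= 2")
  if (is.null(bands)) bands <- band_library(mode)
  if (is.null(profiles)) profiles <- bolete_profiles(mode, bands = bands)
  wavenumbers <- default_wavenumbers(mode)
  set.seed(seed)
  spectra <- NULL; conc <- NULL; labels <- character(0); ids <- character(0)
  ab <- bolete_species_abbrev()
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    ci <- generate_concentrations(pr, n_per_species, seed = NULL,
                                  within_correlation = within_correlation)
    si <- t(apply(ci, 1, function(cv)
      generate_spectrum(cv, pr, bands, wavenumbers = wavenumbers,
                        noise_sd = noise_sd, baseline = baseline,
                        seed = NULL)))
    spectra <- rbind(spectra, si)
    conc <- rbind(conc, ci)
    labels <- c(labels, rep(pr$name, n_per_species))
    code <- if (i <= length(ab)) ab[i] else paste0("S", i)
    ids <- c(ids, sprintf("%s_%02d", code, seq_len(n_per_species)))
  }
  rownames(spectra) <- ids
  rownames(conc) <- ids
  colnames(spectra) <- format_wavenumber(wavenumbers)
  structure(list(
    wavenumbers = wavenumbers,
    spectra = spectra,
    labels = factor(labels, levels = vapply(profiles, `[[`, "", "name")),
    concentrations = conc,
    sample_ids = ids,
    units = profiles[[1]]$units,
    seed = seed,
    generator_params = list(n_per_species = n_per_species, mode = mode,
                            noise_sd = noise_sd, baseline = baseline,
                            within_correlation = within_correlation,
                            bands = bands,
                            profiles = profiles)),
    class = "synthetic_dataset")
}

format_wavenumber <- function(w) sprintf("%g", w)

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples x %d wavenumbers (%s, %g-%g cm^-1)\n",
              nrow(x$spectra), ncol(x$spectra), x$generator_params$mode,
              max(x$wavenumbers), min(x$wavenumbers)))
  cat(sprintf("  species: %s\n", paste(levels(x$labels), collapse = ", ")))
  cat(sprintf("  markers: %d linked concentrations; seed %d\n",
              ncol(x$concentrations), x$seed))
  invisible(x)
}

#' Write a synthetic dataset to CSV + config files
#'
#' Writes four files into `dir`: `spectra.csv` (first column
#' `wavenumber_cm-1`, one column per sample), `labels.csv` (sample ID,
#' species), `concentrations.csv` (sample ID x markers, units in headers)
#' and `generator.json` (generator parameters + seed).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             labels = file.path(dir, "labels.csv"),
             concentrations = file.path(dir, "concentrations.csv"),
             generator = file.path(dir, "generator.json"))
  sp <- data.frame(check.names = FALSE, `wavenumber_cm-1` = dataset$wavenumbers)
  m <- t(dataset$spectra)
  colnames(m) <- dataset$sample_ids
  sp <- cbind(sp, as.data.frame(m, check.names = FALSE))
  utils::write.csv(sp, paths["spectra"], row.names = FALSE)
  utils::write.csv(data.frame(sample_id = dataset$sample_ids,
                              species = as.character(dataset$labels)),
                   paths["labels"], row.names = FALSE)
  cc <- as.data.frame(dataset$concentrations, check.names = FALSE)
  colnames(cc) <- paste0(colnames(dataset$concentrations),
                         " (", dataset$units, ")")
  cc <- cbind(data.frame(sample_id = dataset$sample_ids), cc)
  utils::write.csv(cc, paths["concentrations"], row.names = FALSE)
  gp <- dataset$generator_params
  cfg <- list(seed = dataset$seed,
              n_per_species = gp$n_per_species, mode = gp$mode,
              noise_sd = gp$noise_sd, baseline = gp$baseline,
              band_centers = gp$bands$centers, band_widths = gp$bands$widths,
              species = vapply(gp$profiles, `[[`, "", "name"))
  jsonlite::write_json(cfg, paths["generator"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
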