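test_that("concentration draws reproduce the profile moments", {
  p <- bolete_profiles("NIR")[["Lanmaoa asiatica"]]
  cc <- generate_concentrations(p, 5000, seed = 1)
  # L-Arginine in this species: mean 0.94, SD 0.02 (far from the 0 bound)
  expect_equal(mean(cc[, "L-Arginine"]), 0.94, tolerance = 0.005)

  # moment oracle at large n: sample SD within 5% of the profile SD for
  # markers whose mean is many SDs above zero (negligible truncation)
  q <- toy_profile(means = c(10, 50, 7), sds = c(1, 4, 0.5),
                   loading = matrix(1, 3, 3), offset = rep(0, 3))
  cc <- generate_concentrations(q, 10000, seed = 7)
  expect_true(all(abs(apply(cc, 2, sd) / q$marker_sds - 1) < 0.05))
  expect_true(all(abs(colMeans(cc) / q$marker_means - 1) < 0.02))
})

test_that("degenerate SDs give identical rows and draws are deterministic", {
  q <- toy_profile(means = c(3, 1, 2), sds = c(0, 0, 0),
                   loading = matrix(1, 3, 3), offset = rep(0, 3))
  cc <- generate_concentrations(q, 3, seed = 1)
  expect_equal(unname(cc), matrix(rep(c(3, 1, 2), each = 3), 3, 3))

  p <- bolete_profiles("NIR")[[1]]
  expect_identical(generate_concentrations(p, 10, seed = 5),
                   generate_concentrations(p, 10, seed = 5))
  expect_error(generate_concentrations(p, 0), "positive count")
})

test_that("concentrations are nonnegative even for near-zero means", {
  # Trimethylamine N-Oxide in R. extremiorientalis: 0.01 +/- 0.009
  p <- bolete_profiles("NIR")[["Rugiboletus extremiorientalis"]]
  cc <- generate_concentrations(p, 2000, seed = 3)
  expect_true(all(cc >= 0))
})

test_that("profile constructor enforces its invariants", {
  expect_error(species_profile("x", 1:3, 1:2, matrix(1, 2, 3), c(0, 0)),
               "identical length")
  expect_error(species_profile("x", 1:3, c(1, 1, -1), matrix(1, 2, 3), c(0, 0)),
               "nonnegative")
  expect_error(species_profile("x", 1:3, rep(1, 3), matrix(-1, 2, 3), c(0, 0)),
               "nonnegative")
  # default species offsets differ pairwise in at least one entry
  off <- default_species_offsets(7)
  for (i in 1:4) for (j in (i + 1):5)
    expect_gt(max(abs(off[i, ] - off[j, ])), 0)
})

test_that("spectrum generation is a linear map of concentrations", {
  bands <- toy_bands()
  prof <- toy_profile(means = c(1, 1), sds = c(0, 0),
                      loading = matrix(c(1, 0, 0.5, 0, 2, 0), 3, 2),
                      offset = rep(0, 3))
  wn <- default_wavenumbers("NIR")
  z <- generate_spectrum(c(0, 0), prof, bands, wn)
  expect_equal(z, rep(0, length(wn)))
  s1 <- generate_spectrum(c(1, 2), prof, bands, wn)
  s2 <- generate_spectrum(c(2, 4), prof, bands, wn)
  expect_equal(s2, 2 * s1)                               # homogeneity
  sa <- generate_spectrum(c(1, 0), prof, bands, wn)
  sb <- generate_spectrum(c(0, 2), prof, bands, wn)
  expect_equal(sa + sb, s1)                              # additivity
})

test_that("single-band peak height matches the closed form", {
  bands <- toy_bands(centers = 7003, widths = 120)
  prof <- toy_profile(means = 1, sds = 0, loading = matrix(1, 1, 1),
                      offset = 0.25)
  wn <- default_wavenumbers("NIR")
  cval <- 1.7
  s <- generate_spectrum(cval, prof, bands, wn)
  i <- which.max(s)
  expect_equal(wn[i], wn[which.min(abs(wn - 7003))])
  # closed-form Gaussian at the nearest grid point
  expect_equal(s[i], (cval + 0.25) * exp(-0.5 * ((wn[i] - 7003) / 120)^2))
  # a band whose centre misses the (restricted) grid is refused
  expect_error(generate_spectrum(1, prof, toy_bands(centers = 5000),
                                 wavenumbers = seq(9000, 8000, by = -8)),
               "outside the wavenumber grid")
})

test_that("datasets have the study-cohort shape and are bit-reproducible", {
  ds <- generate_dataset(19, "NIR", seed = 11)
  expect_equal(nrow(ds$spectra), 95)
  expect_equal(nrow(ds$concentrations), 95)
  expect_equal(length(ds$labels), 95)
  expect_equal(ncol(ds$concentrations), 16)
  expect_true(all(is.finite(ds$spectra)))
  ds2 <- generate_dataset(19, "NIR", seed = 11)
  expect_identical(ds$spectra, ds2$spectra)
  expect_identical(ds$concentrations, ds2$concentrations)
  expect_error(generate_dataset(1), ">= 2")
})

test_that("noiseless spectra regenerate exactly from their concentrations", {
  ds <- generate_dataset(3, "FTIR", noise_sd = 0, seed = 2)
  gp <- ds$generator_params
  for (i in c(1, 7, 15)) {
    pr <- gp$profiles[[as.integer(ds$labels[i])]]
    s <- generate_spectrum(ds$concentrations[i, ], pr, gp$bands,
                           wavenumbers = ds$wavenumbers)
    expect_equal(unname(ds$spectra[i, ]), s)
  }
})

test_that("default cohort is separable by a nearest-centroid classifier", {
  ds <- generate_dataset(6, "NIR", seed = 4)
  X <- ds$spectra; y <- ds$labels
  cent <- rowsum(X, y) / as.vector(table(y))
  pred <- apply(X, 1, function(s) rownames(cent)[
    which.min(colSums((t(cent) - s)^2))])
  expect_equal(mean(pred == as.character(y)), 1)
})

test_that("dataset round-trips through the CSV interchange format", {
  ds <- generate_dataset(2, "NIR", seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_spectra(paths["spectra"])
  expect_equal(tab$sample_ids, ds$sample_ids)
  expect_equal(unname(tab$spectra), unname(ds$spectra), tolerance = 1e-9)
  cfg <- jsonlite::read_json(paths["generator"])
  expect_equal(cfg$seed, 9)
  expect_equal(unlist(cfg$band_centers), band_library("NIR")$centers)
})
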