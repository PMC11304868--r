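grid5 <- function(p = 5) seq(8000, by = -8, length.out = p)

test_that("dynamic spectra subtract the reference and centre columns", {
  s <- c(1, 2, 3, 4, 5)
  tab <- spectra_table(grid5(), rbind(s, s), c("a", "b"))
  dyn <- dynamic_spectra(tab)
  expect_equal(dyn$K, matrix(0, 2, 5), ignore_attr = TRUE)

  tab2 <- spectra_table(grid5(), rbind(s, -s), c("a", "b"))
  dyn2 <- dynamic_spectra(tab2)
  expect_equal(dyn2$K[1, ], s)
  expect_equal(dyn2$K[2, ], -s)

  set.seed(3)
  tab3 <- spectra_table(grid5(40), matrix(rnorm(120), 3, 40),
                        paste0("s", 1:3))
  dyn3 <- dynamic_spectra(tab3)
  expect_true(all(abs(colSums(dyn3$K)) < 1e-12))

  expect_error(dynamic_spectra(spectra_table(grid5(), matrix(1:5, 1),
                                             "only")), "m >= 2")
  expect_error(dynamic_spectra(tab3, reference = c(1, 2)), "mismatch")
})

test_that("Hilbert-Noda matrix matches its closed form and is antisymmetric", {
  expect_equal(noda_matrix(2),
               matrix(c(0, -1 / pi, 1 / pi, 0), 2, 2))
  expect_equal(noda_matrix(3),
               matrix(c(0, -1 / pi, -1 / (2 * pi),
                        1 / pi, 0, -1 / pi,
                        1 / (2 * pi), 1 / pi, 0), 3, 3))
  for (m in c(2, 5, 11)) {
    N <- noda_matrix(m)
    expect_true(all(N + t(N) == 0))   # exact antisymmetry
    expect_true(all(diag(N) == 0))
  }
  expect_error(noda_matrix(1), ">= 2")
})

test_that("synchronous map is the (m-1)-normalised cross product", {
  # single nonzero column
  K <- matrix(0, 4, 3); K[, 2] <- c(1, -1, 2, -2)
  dyn <- structure(list(wavenumbers = grid5(3), K = K, reference = rep(0, 3)),
                   class = "dynamic_spectra")
  Phi <- synchronous_map(dyn)
  expect_equal(Phi[2, 2], sum(K[, 2]^2) / 3)
  expect_equal(sum(abs(Phi)), Phi[2, 2])

  # diagonal equals column variances for mean-centred data; symmetry
  set.seed(4)
  X <- matrix(rnorm(7 * 6), 7, 6)
  tab <- spectra_table(grid5(6), X, paste0("s", 1:7))
  maps <- correlation_maps(tab)
  expect_equal(diag(maps$sync), apply(X, 2, var), ignore_attr = TRUE)
  expect_equal(maps$sync, t(maps$sync))
  # energy conservation: trace * (m-1) = total squared deviation
  expect_equal(sum(diag(maps$sync)) * 6,
               sum(sweep(X, 2, colMeans(X))^2))
})

test_that("asynchronous map is antisymmetric and vanishes on rank-one data", {
  set.seed(5)
  c1 <- rnorm(6); s1 <- rnorm(4)
  dyn <- structure(list(wavenumbers = grid5(4), K = outer(c1, s1),
                        reference = rep(0, 4)), class = "dynamic_spectra")
  phi <- asynchronous_map(dyn)
  expect_true(all(abs(phi) < 1e-12))

  K <- matrix(rnorm(5 * 4), 5, 4)
  dyn2 <- structure(list(wavenumbers = grid5(4), K = K,
                         reference = rep(0, 4)), class = "dynamic_spectra")
  phi2 <- asynchronous_map(dyn2)
  expect_true(all(abs(phi2 + t(phi2)) < 1e-12))
  # brute-force triple-loop oracle
  expect_equal(phi2, async_brute(K), tolerance = 1e-10)

  K3 <- matrix(c(0.3, -1.1, 0.8, 0.2, 0.5, -0.7), 3, 2)
  dyn3 <- structure(list(wavenumbers = grid5(2), K = K3,
                         reference = rep(0, 2)), class = "dynamic_spectra")
  expect_equal(asynchronous_map(dyn3), async_brute(K3), tolerance = 1e-12)
})

test_that("auto peaks are found where variance is injected", {
  # flat zero map -> no peaks
  tab0 <- spectra_table(grid5(30), matrix(1, 3, 30), paste0("s", 1:3))
  expect_equal(nrow(detect_auto_peaks(correlation_maps(tab0))), 0)

  # single Gaussian variance profile -> one peak at its centre
  wn <- default_wavenumbers("NIR")
  prof <- exp(-0.5 * ((wn - 6000) / 150)^2)
  X <- rbind(2 * prof, -2 * prof, 0 * prof)
  maps <- correlation_maps(spectra_table(wn, X, paste0("s", 1:3)))
  ap <- detect_auto_peaks(maps)
  expect_equal(nrow(ap), 1)
  expect_equal(ap$wavenumber, wn[which.min(abs(wn - 6000))])

  # dominant variation injected at the 6776 and 5789 cm-1 bands is
  # recovered at those centres (within one grid step)
  bands <- band_library("NIR")
  prof1 <- toy_profile(1, 0, matrix(0, 7, 1),
                       offset = c(0, 1, 0, 1, 0, 0, 0))
  s_hi <- generate_spectrum(0, prof1, bands, wn)       # peaks at 6776, 5789
  X <- rbind(1.5 * s_hi, 0.5 * s_hi, 1.0 * s_hi)
  maps <- correlation_maps(spectra_table(wn, X, paste0("s", 1:3)),
                           subrange = c(5300, 7000))
  ap <- detect_auto_peaks(maps, min_prominence = 0.2)
  expect_true(any(abs(ap$wavenumber - 6776) <= 8))
  expect_true(any(abs(ap$wavenumber - 5789) <= 8))

  expect_error(detect_auto_peaks(maps, min_prominence = 0), "0, 1")
})

test_that("the sequential-order sign rule follows Noda's conventions", {
  expect_equal(sequence_rule(+1, +1), "higher wavenumber first")
  expect_equal(sequence_rule(-1, -1), "higher wavenumber first")
  expect_equal(sequence_rule(+1, -1), "lower wavenumber first")
  expect_equal(sequence_rule(-1, +1), "lower wavenumber first")
  expect_equal(sequence_rule(+1, 0), "simultaneous")
  expect_equal(sequence_rule(0, +1), "indeterminate")
  expect_equal(sequence_rule(0, 0), "indeterminate")
})

test_that("a planted sequential system recovers its event order", {
  # two bands responding with a phase lag along the perturbation axis:
  # the high-wavenumber band leads
  wn <- default_wavenumbers("NIR")
  g1 <- exp(-0.5 * ((wn - 6776) / 100)^2)   # leads
  g2 <- exp(-0.5 * ((wn - 5789) / 100)^2)   # lags
  t <- seq(0, pi, length.out = 9)
  X <- outer(sin(t), g1) + outer(sin(t - pi / 3), g2)
  maps <- correlation_maps(spectra_table(wn, X, paste0("s", 1:9)),
                           subrange = c(5300, 7000))
  rep <- peak_report(maps, min_prominence = 0.2)
  expect_true(all(rep$cross_peaks$v1 > rep$cross_peaks$v2))
  lead <- rep$cross_peaks[abs(rep$cross_peaks$v1 - 6776) <= 16 &
                            abs(rep$cross_peaks$v2 - 5789) <= 16, ]
  expect_equal(lead$verdict[1], "higher wavenumber first")
  expect_equal(rep$event_order[1], lead$v1[1])
})

test_that("map export writes wavenumber-labelled CSV", {
  set.seed(6)
  tab <- spectra_table(grid5(4), matrix(rnorm(12), 3, 4), paste0("s", 1:3))
  maps <- correlation_maps(tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_map(maps, "sync", path)
  back <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(maps$sync), tolerance = 1e-9)
  expect_equal(colnames(back), format(grid5(4), trim = TRUE))
})

test_that("rendered images have the requested size and are deterministic", {
  set.seed(7)
  tab <- spectra_table(grid5(40), matrix(rnorm(200), 5, 40), paste0("s", 1:5))
  maps <- correlation_maps(tab)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  for (style in c("contour2d", "surface3d")) {
    render_maps(maps, f1, "sync", style, size_px = 128)
    img <- png::readPNG(f1)
    expect_equal(dim(img)[1:2], c(128, 128))
    render_maps(maps, f2, "sync", style, size_px = 128)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  # zero map renders as a uniform white (mid-colormap) image
  zero <- maps; zero$sync <- maps$sync * 0
  render_maps(zero, f1, "sync", "contour2d", size_px = 32)
  img <- png::readPNG(f1)
  expect_true(all(img == 1))
})

test_that("per-sample correlation images are deterministic and sized", {
  ds <- generate_dataset(2, "NIR", seed = 3)
  im1 <- sample_correlation_images(ds, size_px = 64)
  im2 <- sample_correlation_images(ds, size_px = 64)
  expect_identical(im1, im2)
  expect_equal(dim(im1), c(10, 64, 64, 3))
  expect_true(all(im1 >= 0 & im1 <= 1))
})
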