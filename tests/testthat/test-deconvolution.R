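test_that("average_spectra is the identity on one scan and on equal scans", {
  d <- tiny_design()
  run <- simulate_run(d)
  one <- average_spectra(run, c(run$rt[10], run$rt[10]))
  expect_equal(one$intensity, run$intensity[, 10])
  # constant signal across scans: average equals any single scan
  const <- run
  const$intensity <- matrix(run$intensity[, 40],
                            nrow = nrow(run$intensity),
                            ncol = ncol(run$intensity))
  avg <- average_spectra(const, range(run$rt))
  expect_equal(avg$intensity, run$intensity[, 40], tolerance = 1e-12)
  expect_error(average_spectra(run, c(100, 101)), "selects no scans")
})

test_that("pick_peaks centroids synthetic Gaussians to sub-mTh accuracy", {
  fw <- 1056.26 / 60000
  sg <- fw / (2 * sqrt(2 * log(2)))
  mz <- seq(1056, 1056.6, by = fw / 4)
  flat <- structure(list(mz = mz, intensity = rep(1, length(mz)),
                         centroided = FALSE), class = "spectrum")
  expect_equal(nrow(pick_peaks(flat, 5)), 0)
  y <- 1000 * exp(-(mz - 1056.26)^2 / (2 * sg^2)) + runif(length(mz))
  one <- structure(list(mz = mz, intensity = y, centroided = FALSE),
                   class = "spectrum")
  pk <- pick_peaks(one, 5)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 1056.26), 0.002)
  expect_lt(abs(pk$fwhm - fw) / fw, 0.1)
  # two Gaussians ten FWHM apart resolve into two centroids
  y2 <- y + 800 * exp(-(mz - (1056.26 + 10 * fw))^2 / (2 * sg^2))
  two <- structure(list(mz = mz, intensity = y2, centroided = FALSE),
                   class = "spectrum")
  expect_equal(nrow(pick_peaks(two, 5)), 2)
})

test_that("charge inference is exact for clean combs and flags dispersion", {
  expect_equal(infer_charge(1056.26 + (0:5) * 0.0556861)$z, 18L)
  expect_equal(infer_charge(500 + (0:4) * 1.00235)$z, 1L)
  set.seed(1)
  bad <- infer_charge(sort(500 + cumsum(runif(6, 0.02, 0.9))))
  expect_false(bad$resolved)
  expect_false(infer_charge(c(1, 2))$resolved)   # too few centroids
  # exact for all z in 5..40, noise-free
  for (z in 5:40) {
    mzs <- ion_mz(19000, z) + (0:6) * 1.00235 / z
    expect_equal(infer_charge(mzs)$z, z)
  }
})

test_that("deconvolution recovers a 19 kDa proteoform within 10 ppm", {
  reg <- cached_registry()
  p <- reg[["kCN B-1P"]]
  d <- run_design(list(p), concentrations = 10, duration = 2,
                  rt_start = 7.3, rt_centers = 8.28, rt_sigma = 0.3,
                  noise_floor = 2, seed = 42)
  run <- simulate_run(d)
  expect_equal(nrow(deconvolute(
    structure(list(mz = numeric(), intensity = numeric(),
                   centroided = FALSE), class = "spectrum"))), 0)
  pk <- deconvolute(average_spectra(run, c(8.0, 8.6)), min_snr = 5)
  expect_gte(nrow(pk), 1)
  expect_lt(abs(ppm_error(p$mono_mass, pk$mass[1])), 10)
  expect_gte(pk$n_charges[1], 5)
  expect_false(pk$average_only[1])
  # reported resolution consistent with the generator's resolving power
  expect_lt(abs(pk$resolution[1] - 60000) / 60000, 0.2)
})

test_that("isotope-unresolved species fall back to a flagged average mass", {
  reg <- cached_registry()
  p <- reg[["BSA"]]
  d <- run_design(list(p), concentrations = 10, duration = 1.5,
                  rt_start = 15.8, rt_centers = 16.53, rt_sigma = 0.25,
                  noise_floor = 0, response_factors = 5e7, seed = 7)
  run <- simulate_run(d)
  pk <- deconvolute(average_spectra(run, c(16, 17)), min_snr = 5)
  expect_gte(nrow(pk), 1)
  expect_true(pk$average_only[1])
  expect_lt(abs(pk$mass[1] - p$avg_mass), 0.5)
})

test_that("identity matching reproduces the report-card arithmetic", {
  reg <- cached_registry()
  obs <- data.frame(mass = 23600.2457, intensity = 1, s_n = 10,
                    fwhm = 0.6, resolution = 4e4, n_charges = 8L,
                    charges = "10", average_only = FALSE)
  id <- match_identities(obs, reg)
  expect_equal(id$protein_code, "aS1CN B-8P")
  expect_equal(id$mass_difference, 0.2263, tolerance = 1e-4)
  expect_equal(id$error_ppm, 9.59, tolerance = 0.005)
  # exact theoretical mass gives zero difference
  id0 <- match_identities(transform(obs, mass = 23600.472), reg)
  expect_equal(id0$mass_difference, 0, tolerance = 1e-9)
  # far-away mass stays unassigned
  idna <- match_identities(transform(obs, mass = 23100.0), reg)
  expect_true(is.na(idna$protein_code))
})
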