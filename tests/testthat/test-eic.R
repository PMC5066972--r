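make_trace <- function(rt, intensity, code = "X") {
  structure(list(rt = rt, intensity = intensity),
            proteoform_code = code, tolerance = 0.1, target = "apex",
            n_ions = 1, class = "eic_trace")
}

test_that("EIC of an empty run is all zero; selectivity holds for disjoint series", {
  d <- tiny_design()
  d$mix[[1]]$concentration <- 0
  run <- simulate_run(d)
  p <- d$mix[[1]]$proteoform
  tr <- extract_eic(run, ion_series(p))
  expect_true(all(tr$intensity == 0))

  a <- tiny_form(mass = 15000, code = "A", rf = 1e6, rt = 5)
  b <- tiny_form(mass = 15050, code = "B", rf = 2e6, rt = 5)
  d2 <- run_design(list(a, b), concentrations = c(1, 1), duration = 4,
                   rt_start = 3, rt_centers = c(5, 5), mode = "centroid",
                   seed = 9)
  run2 <- simulate_run(d2)
  ar_a <- sum(extract_eic(run2, ion_series(a))$intensity)
  ar_b <- sum(extract_eic(run2, ion_series(b))$intensity)
  cap_a <- eic_capture_fraction(d2, "A")
  cap_b <- eic_capture_fraction(d2, "B")
  expect_equal(ar_a, 1e6 * cap_a, tolerance = 0.01)
  expect_equal(ar_b, 2e6 * cap_b, tolerance = 0.01)
})

test_that("EIC recovers the generated envelope area within 1% (noise-free)", {
  d <- tiny_design()
  run <- simulate_run(d)
  p <- d$mix[[1]]$proteoform
  tr <- extract_eic(run, ion_series(p))
  expect_equal(sum(tr$intensity),
               1e6 * eic_capture_fraction(d, "TEST"), tolerance = 0.01)
})

test_that("integration matches the Gaussian closed form and window semantics", {
  rt <- seq(0, 10, by = 0.01)
  tr <- make_trace(rt, exp(-(rt - 5)^2 / (2 * 0.2^2)))
  pk <- suppressWarnings(integrate_peak(tr, 5, window = 4))
  expect_equal(pk$area, 0.2 * sqrt(2 * pi), tolerance = 0.005)
  expect_equal(pk$rt_apex, 5, tolerance = 0.01)
  # peak centered at the window edge integrates to about half
  half <- suppressWarnings(integrate_peak(tr, 5 + 2, window = 4))
  expect_equal(half$area, 0.2 * sqrt(2 * pi) / 2, tolerance = 0.02)
  # all-zero trace
  z <- suppressWarnings(integrate_peak(make_trace(rt, rep(0, length(rt))), 5))
  expect_equal(z$area, 0)
  expect_error(integrate_peak(tr, 50, window = 4), "does not overlap")
  expect_error(integrate_peak(tr, 5, window = -1), "window must be")
})

test_that("area is invariant to rt-grid refinement", {
  d <- tiny_design()
  p <- d$mix[[1]]$proteoform
  run1 <- simulate_run(d)
  d2 <- d; d2$scan_period <- 1.5
  run2 <- simulate_run(d2)
  a1 <- suppressWarnings(
    integrate_peak(extract_eic(run1, ion_series(p)), 5, 4))$area
  a2 <- suppressWarnings(
    integrate_peak(extract_eic(run2, ion_series(p)), 5, 4))$area
  # counts scale with scan density; compare count-rate areas (area / dt)
  expect_equal(a1 / (3 / 60), a2 / (1.5 / 60), tolerance = 0.01)
})

test_that("noise for S/N comes from blank traces, with a documented fallback", {
  d <- tiny_design(noise_floor = 2)
  run <- simulate_run(d)
  blanks <- simulate_dilution_series(tiny_design(noise_floor = 2), 0, 3)
  p <- d$mix[[1]]$proteoform
  ser <- ion_series(p)
  tr <- extract_eic(run, ser)
  btr <- lapply(blanks, extract_eic, series = ser)
  pk <- integrate_peak(tr, 5, 4, blank_traces = btr)
  expect_gt(pk$s_n, 10)
  expect_warning(integrate_peak(tr, 5, 4), "10th")
})

test_that("summed_response and normalize_to_is behave per contract", {
  rows <- data.frame(protein_code = c("a", "b"), area = c(10, 2))
  expect_equal(summed_response(rows), 12)
  expect_equal(summed_response(rows[1, ]), 10)
  expect_error(summed_response(rows[0, ]), "at least one")
  is_row <- data.frame(protein_code = "IS", area = 2)
  out <- normalize_to_is(rows, is_row)
  expect_equal(out$normalized_response, c(5, 1))
  expect_error(normalize_to_is(rows, data.frame(protein_code = "IS",
                                                area = 0)), "failed spike")
})

test_that("normalized responses are invariant to global intensity rescaling", {
  a <- tiny_form(mass = 15000, code = "A", rf = 1e6, rt = 5)
  is_p <- tiny_form(mass = 16941, code = "IS", rf = 2e6, rt = 5.5)
  d <- run_design(list(a, is_p), concentrations = c(1, 1), is_code = "IS",
                  duration = 4, rt_start = 3, rt_centers = c(5, 5.5),
                  mode = "centroid", seed = 2)
  run <- simulate_run(d)
  scaled <- run
  scaled$intensity <- run$intensity * 7.3
  norm_of <- function(r) {
    ta <- sum(extract_eic(r, ion_series(a))$intensity)
    ti <- sum(extract_eic(r, ion_series(is_p))$intensity)
    ta / ti
  }
  expect_equal(norm_of(run), norm_of(scaled), tolerance = 1e-12)
})

test_that("rank_by_response orders responses and groups ties", {
  rows <- data.frame(protein_code = c("a", "b"), area = c(3, 1))
  rk <- rank_by_response(rows)
  expect_equal(rk$protein_code, c("a", "b"))
  tie <- rank_by_response(data.frame(protein_code = c("x", "y"),
                                     area = c(100, 99.5)))
  expect_equal(tie$rank, c(1L, 1L))
  # synthetic mix with response factors 5:2:1 ranks accordingly
  forms <- list(tiny_form(15000, "P5", 5e6, 5),
                tiny_form(15500, "P2", 2e6, 5),
                tiny_form(16000, "P1", 1e6, 5))
  d <- run_design(forms, concentrations = 1, duration = 4, rt_start = 3,
                  rt_centers = 5, mode = "centroid", seed = 12)
  run <- simulate_run(d)
  areas <- vapply(forms, function(p)
    sum(extract_eic(run, ion_series(p))$intensity), 0)
  rk2 <- rank_by_response(data.frame(
    protein_code = c("P5", "P2", "P1"), area = areas))
  expect_equal(rk2$protein_code, c("P5", "P2", "P1"))
})

test_that("EIC area is linear in concentration over a 40x range", {
  d <- tiny_design(replicate_cv = 0.02)
  conc <- c(0.25, 0.5, 1, 2.5, 5, 10)
  runs <- simulate_dilution_series(d, conc, replicates = 2)
  p <- d$mix[[1]]$proteoform
  areas <- vapply(runs, function(r)
    sum(extract_eic(r, ion_series(p))$intensity), 0)
  mean_area <- tapply(areas, attr(runs, "concentration"), mean)
  fit <- stats::lm(mean_area ~ conc)
  expect_gt(summary(fit)$r.squared, 0.99)
})
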