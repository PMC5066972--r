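test_that("scan count follows duration and period, and runs are deterministic", {
  d <- tiny_design(noise_floor = 1)
  d$duration <- 10
  run <- simulate_run(d)
  expect_equal(length(run$rt), 200)          # 10 min at one scan per 3 s
  expect_true(all(diff(run$rt) > 0))
  expect_true(!is.unsorted(run$mz))
  run2 <- simulate_run(d)
  expect_identical(run$intensity, run2$intensity)
  run3 <- simulate_run(d, seed = 99)
  expect_false(identical(run$intensity, run3$intensity))
})

test_that("a default-width peak spans at least 20 scans above noise", {
  d <- tiny_design(noise_floor = 2)
  run <- simulate_run(d)
  p <- d$mix[[1]]$proteoform
  tr <- extract_eic(run, ion_series(p))
  blank_level <- stats::median(tr$intensity[tr$rt < 4])
  n_signal <- sum(tr$intensity > 10 * blank_level &
                  abs(tr$rt - 5) < 2)
  expect_gte(n_signal, 20)
})

test_that("total ion current is conserved noise-free", {
  d <- tiny_design()
  run <- simulate_run(d)
  expected <- 1 * 1e6          # concentration x response_factor
  expect_equal(total_ion_current(run), expected, tolerance = 0.01)
  # with suppression
  d2 <- tiny_design(suppression_factor = 0.15)
  expect_equal(total_ion_current(simulate_run(d2)), expected * 0.85,
               tolerance = 0.01)
})

test_that("an envelope fully outside the window warns and is omitted", {
  p <- proteoform("OUT", curated_mass = 24000, charges = 1L,
                  expected_rt = 5, response_factor = 1e6)
  d <- run_design(list(p), concentrations = 1, duration = 2, rt_start = 4,
                  mode = "centroid", seed = 3)
  expect_warning(run <- simulate_run(d), "outside the m/z window")
  expect_equal(length(run$mz), 0)
})

test_that("noise-free dilution series recovers exact area ratios and blanks", {
  d <- tiny_design()
  runs <- simulate_dilution_series(d, c(1, 2, 4), replicates = 1)
  p <- d$mix[[1]]$proteoform
  areas <- vapply(runs, function(r)
    sum(extract_eic(r, ion_series(p))$intensity), 0)
  expect_equal(areas / areas[1], c(1, 2, 4), tolerance = 1e-9)

  d_noise <- tiny_design(noise_floor = 1)
  blanks <- simulate_dilution_series(d_noise, 0, replicates = 3)
  for (b in blanks) {
    tr <- extract_eic(b, ion_series(p))
    # noise-only: no elution structure, low flat signal
    expect_lt(max(tr$intensity), 50 * stats::median(tr$intensity))
  }
})

test_that("replicate areas follow the lognormal area-level contract", {
  d <- tiny_design(replicate_cv = 0.05)
  p <- d$mix[[1]]$proteoform
  areas <- vapply(1:30, function(r)
    sum(extract_eic(simulate_run(d, seed = 1000 + r),
                    ion_series(p))$intensity), 0)
  cap <- eic_capture_fraction(d, "TEST")
  expect_equal(mean(areas), 1e6 * cap, tolerance = 0.05)
  expect_equal(stats::sd(areas) / mean(areas), 0.05, tolerance = 0.5)
  # fast path draws from the same law
  fast <- simulate_responses(d, 500, seed = 5)[, "TEST"]
  expect_equal(mean(fast), 1e6, tolerance = 0.02)
  expect_equal(stats::sd(fast) / mean(fast), 0.05, tolerance = 0.15)
})

test_that("two-group study shares acquisition and differs by concentration", {
  da <- tiny_design()
  db <- tiny_design()
  db$mix[[1]]$concentration <- 3
  st <- simulate_two_group_study(da, db, replicates = 2)
  p <- da$mix[[1]]$proteoform
  a1 <- sum(extract_eic(st$a[[1]], ion_series(p))$intensity)
  b1 <- sum(extract_eic(st$b[[1]], ion_series(p))$intensity)
  expect_equal(b1 / a1, 3, tolerance = 1e-6)
  expect_error(simulate_two_group_study(da, db, replicates = 0), ">= 1")
  db2 <- tiny_design()
  db2$scan_period <- 1.5
  expect_error(simulate_two_group_study(da, db2), "scan_period")
})

test_that("IS area is independent of the analyte mix (no cross-talk)", {
  a <- tiny_form(mass = 15000, code = "A", rf = 1e6, rt = 5)
  is_p <- tiny_form(mass = 16941, code = "IS", rf = 2e6, rt = 5.5)
  d1 <- run_design(list(a, is_p), concentrations = c(1, 1), is_code = "IS",
                   is_concentration = 0.2, duration = 4, rt_start = 3,
                   rt_centers = c(5, 5.5), mode = "centroid", seed = 2)
  d2 <- d1; d2$mix[["A"]]$concentration <- 8
  is_series <- ion_series(is_p)
  ar1 <- sum(extract_eic(simulate_run(d1), is_series)$intensity)
  ar2 <- sum(extract_eic(simulate_run(d2), is_series)$intensity)
  expect_equal(ar1, ar2, tolerance = 1e-9)
})
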