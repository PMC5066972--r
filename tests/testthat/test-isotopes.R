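test_that("single-element patterns match the abundance table", {
  p <- isotope_distribution(composition(C = 1), prune = 0)
  expect_equal(p$offset, c(0L, 1L))
  expect_equal(p$mass, c(12, 13.00335), tolerance = 1e-5)
  expect_equal(p$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
  w <- isotope_distribution(composition(H = 2, O = 1), prune = 0)
  expect_equal(sum(w$abundance), 1, tolerance = 1e-9)
  expect_equal(w$mass[1], 18.010565, tolerance = 1e-6)
})

test_that("convolution agrees with the brute-force enumeration oracle", {
  cases <- list(c(C = 3, H = 5, N = 1, O = 1, S = 1),
                c(C = 6, H = 12, N = 2, O = 2),
                c(C = 2, H = 3, O = 4, S = 2),
                c(C = 8, H = 10, N = 3, O = 2, P = 1))
  for (cts in cases) {
    got <- isotope_distribution(do.call(composition, as.list(cts)),
                                prune = 0)
    want <- oracle_pattern(as.list(cts))
    n <- min(nrow(got), 8)
    expect_equal(got$abundance[1:n], want$abundance[1:n], tolerance = 1e-9)
    expect_equal(got$mass[1:n], want$mass[1:n], tolerance = 1e-6)
  }
})

test_that("pattern of a sum equals the convolution of the patterns (semigroup)", {
  set.seed(7)
  for (i in 1:10) {
    a <- composition(C = sample(1:20, 1), H = sample(1:30, 1),
                     O = sample(0:5, 1))
    b <- composition(C = sample(1:20, 1), N = sample(0:4, 1),
                     S = sample(0:2, 1))
    pa <- isotope_distribution(a, prune = 0)
    pb <- isotope_distribution(b, prune = 0)
    pab <- isotope_distribution(a + b, prune = 0)
    va <- numeric(max(pa$offset) + 1); va[pa$offset + 1] <- pa$abundance
    vb <- numeric(max(pb$offset) + 1); vb[pb$offset + 1] <- pb$abundance
    conv <- oracle_convolve_ab(va, vb)
    # the package trims offsets below 1e-12 abundance; compare the shared
    # head and require the dropped tail to be negligible
    n <- min(length(conv), nrow(pab))
    expect_equal(pab$abundance[1:n], conv[1:n], tolerance = 1e-9)
    if (length(conv) > n) expect_lt(sum(conv[(n + 1):length(conv)]), 1e-9)
  }
})

test_that("pruning at 1e-10 barely changes total abundance up to 70 kDa", {
  comp <- averagine_composition(70000)
  full <- isotope_distribution(comp, prune = 0)
  pruned <- isotope_distribution(comp, prune = 1e-10)
  common <- intersect(full$offset, pruned$offset)
  expect_lt(max(abs(pruned$abundance[match(common, pruned$offset)] -
                    full$abundance[match(common, full$offset)])), 1e-6)
})

test_that("most_abundant_offset picks the tallest offset, ties to smaller k", {
  expect_equal(most_abundant_offset(
    isotope_distribution(composition(H = 2, O = 1))), 0L)
  expect_equal(most_abundant_offset(
    isotope_distribution(composition(C = 1))), 0L)
  # heavy protein: the monoisotopic species is no longer tallest
  p24 <- isotope_distribution(averagine_composition(24000))
  expect_gte(most_abundant_offset(p24), 10L)
  expect_equal(most_abundant_offset(p24), p24$offset[which.max(p24$abundance)])
})

test_that("averagine_composition scales and pads to the target mass", {
  u <- averagine_composition(111.1254)
  expect_lte(abs(monoisotopic_mass(u) - 111.1254), 0.55)
  big <- averagine_composition(22225)
  expect_equal(unclass(big)[["C"]], round(4.9384 * 22225 / 111.1254),
               tolerance = 2)
  expect_lt(abs(monoisotopic_mass(big) - 22225), 1)
  expect_error(averagine_composition(0), "M must be")
})

test_that("FWHM grows linearly with m/z at fixed resolving power", {
  mz <- c(600, 1200, 2400)
  f <- peak_fwhm(mz, 60000)
  expect_equal(f[2] / f[1], 2, tolerance = 1e-12)
  expect_equal(f[3] / f[1], 4, tolerance = 1e-12)
  expect_equal(peak_fwhm(1056.26, 60000), 1056.26 / 60000)
})
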