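# Independent oracles and small shared fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force isotope-pattern oracle: enumerates, per element, all ways of
# distributing n atoms over that element's isotopes (multinomial), then
# combines elements by a cartesian product. Exponential - only for tiny
# compositions - and entirely independent of the package's convolution.
oracle_pattern <- function(counts) {
  iso <- list(
    C = list(offset = c(0, 1), mass = c(12, 13.0033548378),
             ab = c(0.9893, 0.0107)),
    H = list(offset = c(0, 1), mass = c(1.0078250319, 2.014101778),
             ab = c(0.999885, 0.000115)),
    N = list(offset = c(0, 1), mass = c(14.0030740052, 15.0001088984),
             ab = c(0.99636, 0.00364)),
    O = list(offset = c(0, 1, 2),
             mass = c(15.9949146221, 16.9991315, 17.9991604),
             ab = c(0.99757, 0.00038, 0.00205)),
    S = list(offset = c(0, 1, 2, 4),
             mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
             ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
    P = list(offset = 0, mass = 30.97376151, ab = 1)
  )
  partitions <- function(n, k) {
    if (k == 1) return(matrix(n, ncol = 1))
    out <- NULL
    for (i in 0:n) out <- rbind(out, cbind(i, partitions(n - i, k - 1)))
    out
  }
  per_el <- list()
  for (el in names(counts)) {
    n <- counts[[el]]
    if (is.na(n) || n == 0) next
    e <- iso[[el]]
    part <- partitions(n, length(e$offset))
    ab <- apply(part, 1, function(v)
      exp(lgamma(n + 1) - sum(lgamma(v + 1)) + sum(v * log(e$ab))))
    per_el[[el]] <- data.frame(
      offset = as.vector(part %*% e$offset),
      mass = as.vector(part %*% e$mass),
      ab = ab)
  }
  total <- Reduce(function(a, b) {
    g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(offset = a$offset[g$i] + b$offset[g$j],
               mass = a$mass[g$i] + b$mass[g$j],
               ab = a$ab[g$i] * b$ab[g$j])
  }, per_el)
  agg_ab <- tapply(total$ab, total$offset, sum)
  agg_m <- tapply(total$ab * total$mass, total$offset, sum) / agg_ab
  data.frame(offset = as.integer(names(agg_ab)),
             mass = as.numeric(agg_m),
             abundance = as.numeric(agg_ab))
}

# direct (quadratic) convolution of two abundance vectors - independent of
# the package's binary-exponentiation route
oracle_convolve_ab <- function(a, b) {
  n <- length(a) + length(b) - 1
  out <- numeric(n)
  for (i in seq_along(a))
    for (j in seq_along(b))
      out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  out
}

# cached package registry (isotope patterns make loading non-trivial)
cached_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- milk_registry()
    reg
  }
})

# small single-analyte design used across simulator tests: a mass-backed
# 15 kDa protein, centroid mode for speed
tiny_form <- function(mass = 15000, code = "TEST", rf = 1e6, rt = 5) {
  proteoform(code, curated_mass = mass, expected_rt = rt,
             charges = 9:15, response_factor = rf)
}

tiny_design <- function(..., mass = 15000, rf = 1e6) {
  run_design(list(tiny_form(mass = mass, rf = rf)), concentrations = 1,
             duration = 4, rt_start = 3, rt_centers = 5, rt_sigma = 0.3,
             mode = "centroid", seed = 11, ...)
}
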