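test_that("despike leaves clean series alone and finds a lone spike", {
  x <- rep(2.5, 50)
  expect_equal(despike(x)$n_spikes, 0)
  x[25] <- 250
  ds <- despike(x)
  expect_equal(which(ds$mask), 25)
  expect_equal(ds$clean[25], 2.5)
  expect_equal(ds$clean[-25], x[-25])
})

test_that("despike warns and passes through short series", {
  expect_warning(ds <- despike(c(1, 2, 3), window = 7), "shorter")
  expect_equal(ds$clean, c(1, 2, 3))
})

test_that("despike recovers a seeded 1% spike mask with precision >= 0.95", {
  dep <- small_deployment(seed = 42)
  for (col in c("chl_fl_mg_m3", "bbp700_m1")) {
    ds <- despike(dep$records[[col]], window = 7, n_mad = 5)
    tp <- sum(ds$mask & dep$spike_mask[[col]])
    fp <- sum(ds$mask & !dep$spike_mask[[col]])
    expect_gte(tp / (tp + fp), 0.95)
  }
})

test_that("despike is idempotent", {
  dep <- small_deployment(seed = 7)
  d1 <- despike(dep$records$bbp700_m1)
  d2 <- despike(d1$clean)
  expect_identical(d2$clean, d1$clean)
  expect_equal(d2$n_spikes, 0)
})

test_that("profile splitting counts sawtooth cycles and conserves records", {
  # perfect triangle wave, 10 cycles -> 20 profiles
  one <- c(seq(0, 100, by = 5), seq(95, 5, by = -5))
  depth <- rep(one, 10)
  rec <- data.frame(depth_m = depth)
  profs <- split_profiles(rec, hysteresis = 5)
  expect_length(profs, 20)
  expect_equal(sum(vapply(profs, nrow, integer(1))), nrow(rec))
  dirs <- vapply(profs, attr, character(1), "direction")
  expect_equal(dirs, rep(c("dive", "climb"), 10))
  # monotone descent -> a single dive
  profs1 <- split_profiles(data.frame(depth_m = seq(0, 200, by = 2)))
  expect_length(profs1, 1)
  expect_equal(attr(profs1[[1]], "direction"), "dive")
})

test_that("profile splitting is robust to depth jitter under hysteresis", {
  one <- c(seq(0, 100, by = 5), seq(95, 5, by = -5))
  depth <- rep(one, 10)
  set.seed(11)
  jitter <- depth + runif(length(depth), -2, 2)
  expect_length(split_profiles(data.frame(depth_m = jitter),
                               hysteresis = 5), 20)
})

test_that("chlorophyll inversion of the 700 nm power law", {
  cf <- model_coefficients()
  A700 <- cf$bbp_table$A_bb[cf$bbp_table$wavelength_nm == 700]
  expect_equal(chl_from_bbp(A700), 1)
  expect_equal(chl_from_bbp(0.001 * 10^0.683), 10, tolerance = 1e-12)
  chl <- exp(seq(log(0.1), log(30), length.out = 40))
  expect_equal(chl_from_bbp(bbp(700, chl)), chl, tolerance = 1e-10)
  expect_error(chl_from_bbp(0), "positive")
  expect_error(chl_from_bbp(-0.001), "positive")
})

test_that("hybrid estimator switches at the inclusive threshold", {
  out <- hybrid_chl(1.5, bbp(700, 9))
  expect_equal(out$chl, 1.5)
  expect_equal(out$source, "fluorescence")
  out2 <- hybrid_chl(2.0, bbp(700, 9))
  expect_equal(out2$chl, 2.0)
  expect_equal(out2$source, "fluorescence")
  out3 <- hybrid_chl(5, bbp(700, 8))
  expect_equal(out3$chl, 8, tolerance = 1e-10)
  expect_equal(out3$source, "backscatter")
})

test_that("Barnes analysis reproduces a constant field", {
  set.seed(3)
  x <- runif(200, 0, 40); z <- runif(200, 0, 100)
  G <- barnes_grid(x, z, rep(7.25, 200),
                   along_track = seq(0, 40, by = 2),
                   depth = seq(0, 100, by = 5))
  expect_true(any(is.finite(G)))
  expect_equal(G[is.finite(G)], rep(7.25, sum(is.finite(G))),
               tolerance = 1e-9)
})

test_that("a single observation peaks at the nearest grid node", {
  xg <- seq(0, 20, by = 2); zg <- seq(0, 50, by = 5)
  G <- barnes_grid(3.4, 12, 5, xg, zg, radii = c(4, 10), passes = 1)
  # a single observation gives a flat analysis over reachable cells, so the
  # nearest node (x = 4, z = 10) attains the maximum and carries the value
  expect_equal(G[xg == 4, zg == 10], max(G, na.rm = TRUE))
  expect_equal(G[xg == 4, zg == 10], 5, tolerance = 1e-12)
  # cells beyond the cutoff stay missing
  expect_true(is.na(G[xg == 20, zg == 50]))
})

test_that("empty input yields an all-missing grid", {
  G <- barnes_grid(numeric(0), numeric(0), numeric(0),
                   seq(0, 10, 2), seq(0, 20, 5))
  expect_true(all(is.na(G)))
})

test_that("Barnes equals the brute-force oracle within 1e-9", {
  set.seed(21)
  n <- 120
  x <- runif(n, 0, 30); z <- runif(n, 0, 80)
  v <- sin(x / 6) + 0.02 * z + rnorm(n, 0, 0.05)
  xg <- seq(0, 30, by = 2); zg <- seq(0, 80, by = 5)
  for (passes in 1:2) {
    G <- barnes_grid(x, z, v, xg, zg, radii = c(6, 15), passes = passes,
                     gamma = 0.4)
    O <- barnes_oracle(x, z, v, xg, zg, radii = c(6, 15), passes = passes,
                       gamma = 0.4)
    expect_equal(G, O, tolerance = 1e-9)
  }
})

test_that("the second pass reduces the analysis error on a smooth field", {
  set.seed(5)
  n <- 400
  x <- runif(n, 0, 30); z <- runif(n, 0, 80)
  truth <- function(x, z) 2 + 0.3 * x - 0.04 * z
  xg <- seq(2, 28, by = 2); zg <- seq(5, 75, by = 5)
  Ft <- outer(xg, zg, truth)
  rms <- sapply(1:2, function(p) {
    G <- barnes_grid(x, z, truth(x, z), xg, zg, radii = c(8, 20),
                     passes = p)
    sqrt(mean((G - Ft)^2, na.rm = TRUE))
  })
  expect_lt(rms[2], rms[1])
})

test_that("cells beyond the cutoff are missing, not zero", {
  xg <- seq(0, 100, by = 2); zg <- seq(0, 20, by = 5)
  G <- barnes_grid(2, 10, 4, xg, zg, radii = c(5, 10), passes = 1)
  expect_true(is.na(G[length(xg), 1]))  # 98 km away ≫ 3 radii
  expect_false(is.na(G[2, 3]))
})

test_that("transect IOP fields equal direct per-cell model calls", {
  xg <- c(0, 2, 4); zg <- c(0, 5, 10)
  chl <- matrix(c(0.5, 1, 2, 4, 6, 8, 1, 3, NA), 3, 3)
  sal <- matrix(34.2, 3, 3); sal[3, 3] <- NA
  tr <- gridded_transect(xg, zg, list(chl = chl, salinity = sal))
  tr <- transect_iops(tr, wavelengths = c(440, 555))
  for (i in 1:3) for (j in 1:3) {
    if (is.na(chl[i, j])) {
      expect_true(is.na(tr$fields$a_440[i, j]))
      next
    }
    direct <- total_iops(c(440, 555), chl[i, j], sal[i, j])$spectra
    expect_equal(tr$fields$a_440[i, j], direct$a_total[1])
    expect_equal(tr$fields$b_555[i, j], direct$b_total[2])
    expect_equal(tr$fields$bb_440[i, j], direct$bb_total[1])
    expect_equal(tr$fields$a_nw_555[i, j], direct$a_nw[2])
  }
})

test_that("uniform chl/salinity grids give spatially uniform IOPs", {
  tr <- gridded_transect(c(0, 2), c(0, 5),
                         list(chl = matrix(2, 2, 2),
                              salinity = matrix(34, 2, 2)))
  tr <- transect_iops(tr, wavelengths = 488)
  expect_equal(length(unique(as.vector(tr$fields$a_488))), 1)
})
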