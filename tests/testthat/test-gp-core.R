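test_that("GP follows the two-wavelength contrast definition", {
  expect_equal(compute_gp(two_point_spectrum(100, 100)), 0)
  expect_equal(compute_gp(two_point_spectrum(100, 0)), 1)
  expect_equal(compute_gp(two_point_spectrum(150, 50)), 0.5)
  expect_error(compute_gp(two_point_spectrum(0, 0)),
               class = "laurdanGP_undefined_gp_error")
})

test_that("GP is scale invariant and monotone in each intensity", {
  for (c_ in c(0.1, 1, 7, 1e4)) {
    s <- two_point_spectrum(120, 80)
    scaled <- emission_spectrum(s$wavelength, s$intensity * c_, s$temperature)
    expect_equal(compute_gp(scaled), compute_gp(s))
  }
  i440 <- seq(10, 200, by = 10)
  expect_true(all(diff(vapply(i440, function(i)
    compute_gp(two_point_spectrum(i, 80)), numeric(1))) > 0))
  i490 <- seq(10, 200, by = 10)
  expect_true(all(diff(vapply(i490, function(i)
    compute_gp(two_point_spectrum(80, i)), numeric(1))) < 0))
})

test_that("strict mode demands the 440/490 grid points; interpolation is opt-in", {
  s <- emission_spectrum(c(400, 441, 489, 540), c(1, 100, 50, 1), 25)
  expect_error(compute_gp(s), class = "laurdanGP_grid_error")
  expect_no_error(compute_gp(s, interpolate = TRUE))
})

test_that("scan averaging is the pointwise mean and validates alignment", {
  s <- two_point_spectrum(100, 50)
  expect_equal(average_scans(list(s))$intensity, s$intensity)
  s3 <- emission_spectrum(s$wavelength, 3 * s$intensity, s$temperature)
  avg <- average_scans(list(s, s3))
  expect_equal(avg$intensity, 2 * s$intensity)
  expect_identical(avg$scan_index, "averaged")
  other_grid <- emission_spectrum(c(400, 440, 490, 541), s$intensity, 25)
  expect_error(average_scans(list(s, other_grid)),
               class = "laurdanGP_alignment_error")
  other_temp <- emission_spectrum(s$wavelength, s$intensity, 26)
  expect_error(average_scans(list(s, other_temp)),
               class = "laurdanGP_alignment_error")
})

test_that("averaging three scans cuts the intensity variance about threefold", {
  m <- update(condition_model("DMPC"), noise_sd = 0.05)
  truth <- synth_spectrum(update(m, noise_sd = 0), 30)
  n_trip <- 120
  raw_resid <- c()
  avg_resid <- c()
  for (i in seq_len(n_trip)) {
    scans <- lapply(1:3, function(s)
      synth_spectrum(m, 30, seed = 1000 * i + s))
    raw_resid <- c(raw_resid, scans[[1]]$intensity - truth$intensity)
    avg_resid <- c(avg_resid,
                   average_scans(scans)$intensity - truth$intensity)
  }
  ratio <- stats::var(raw_resid) / stats::var(avg_resid)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.6)
})

test_that("the pipeline averages scans before GP (order matters)", {
  # scan A: I440 = 100, I490 = 100 (GP 0); scan B: I440 = 300, I490 = 100
  # (GP 0.5). GP of the averaged spectrum is 1/3; the average of the two
  # GPs is 1/4. The acquisition contract fixes average-first.
  a <- two_point_spectrum(100, 100)
  b <- two_point_spectrum(300, 100)
  gp_avg_first <- compute_gp(average_scans(list(a, b)))
  gp_avg_last <- mean(c(compute_gp(a), compute_gp(b)))
  expect_equal(gp_avg_first, 1 / 3)
  expect_equal(gp_avg_last, 1 / 4)
  expect_false(isTRUE(all.equal(gp_avg_first, gp_avg_last)))
})

test_that("replicate aggregation computes mean and n-1 standard deviation", {
  mk <- function(i440) list(two_point_spectrum(i440, 100),
                            two_point_spectrum(i440, 300, temperature = 30))
  reps <- list(mk(100), mk(200), mk(300))
  # wrap each rep's spectra as 'averaged' singletons at two temperatures
  cur <- build_curve(reps)
  gps <- vapply(c(100, 200, 300), function(i)
    compute_gp(two_point_spectrum(i, 100)), numeric(1))
  expect_equal(cur$gp[1], mean(gps))
  expect_equal(cur$gp_sd[1], sd(gps))
  # single replicate: no dispersion column
  cur1 <- build_curve(list(mk(100)))
  expect_null(cur1$gp_sd)
  # identical replicates: zero dispersion
  cur0 <- build_curve(list(mk(150), mk(150), mk(150)))
  expect_equal(cur0$gp_sd, c(0, 0))
  # temperature misalignment across replicates is an error
  bad <- list(mk(100),
              list(two_point_spectrum(100, 100, temperature = 10),
                   two_point_spectrum(100, 300, temperature = 30)))
  expect_error(build_curve(bad), class = "laurdanGP_alignment_error")
})

test_that("gp_curve validates its invariants", {
  expect_error(gp_curve(c(1, 1, 2), c(0, 0, 0)),
               class = "laurdanGP_input_error")
  expect_error(gp_curve(1:3, c(0, 2, 0)), class = "laurdanGP_input_error")
  expect_error(gp_curve(1:3, c(0, 0)), class = "laurdanGP_input_error")
})
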