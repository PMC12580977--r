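test_that("central differences are exact for affine and quadratic GP", {
  # linear: gp = 0.5 - 0.02 T  ->  -dGP/dT = 0.02 everywhere
  tt <- 0:10
  d <- neg_derivative(gp_curve(tt, 0.5 - 0.02 * tt))
  expect_equal(d$neg_dgp_dt, rep(0.02, 11))
  # constant -> all zeros
  d0 <- neg_derivative(gp_curve(tt, rep(0.3, 11)))
  expect_equal(d0$neg_dgp_dt, rep(0, 11))
  # quadratic gp = -(T/4)^2 on 0..4: interior stencil gives exactly T/8
  tq <- 0:4
  dq <- neg_derivative(gp_curve(tq, -(tq / 4)^2))
  expect_equal(dq$neg_dgp_dt[2:4], tq[2:4] / 8)
  # endpoints are one-sided and flagged
  expect_identical(attr(dq, "endpoint"), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_error(neg_derivative(gp_curve(1:2, c(0.1, 0))),
               class = "laurdanGP_insufficient_data_error")
})

test_that("the uneven-spacing stencil divides by the full local span", {
  tt <- c(0, 1, 3, 6, 10)
  gp <- 0.9 - 0.05 * tt   # affine, so exact at any spacing
  d <- neg_derivative(gp_curve(tt, gp))
  expect_equal(d$neg_dgp_dt, rep(0.05, 5))
})

test_that("derivative-peak extraction recovers a noiseless logistic transition", {
  m <- noiseless_model("DPPC")
  tr <- find_transition(ideal_curve(m, 26:56))
  expect_equal(tr$t_m, 41)
  # off-grid transition temperature: recovered within half the grid step
  m2 <- update(m, t_m = 41.3)
  tr2 <- find_transition(ideal_curve(m2, 26:56))
  expect_lte(abs(tr2$t_m - 41.3), 0.5)
  # dense-grid argmax agrees with the analytic maximizer (= t_m) to one step
  tr3 <- find_transition(ideal_curve(m2, seq(31, 51, by = 0.01)))
  expect_lte(abs(tr3$t_m - 41.3), 0.01)
})

test_that("FWHM approaches the logistic closed form on a fine grid", {
  # closed form: full width at half maximum of the logistic derivative
  # is 2 ln(3 + 2 sqrt(2)) * width_k
  for (k in c(0.4, 1, 2.6)) {
    m <- melt_model(0.5, -0.2, 30, k)
    tr <- find_transition(ideal_curve(m, seq(30 - 15 * k, 30 + 15 * k,
                                             by = 0.01)))
    expect_equal(tr$fwhm, 2 * log(3 + 2 * sqrt(2)) * k, tolerance = 0.01)
  }
})

test_that("FWHM increases strictly with the width parameter", {
  widths <- c(0.4, 1.0, 1.8, 2.6, 3.0)
  fwhm <- vapply(widths, function(k) {
    m <- melt_model(0.55, -0.2, 30, k)
    find_transition(ideal_curve(m, seq(10, 50, by = 0.05)))$fwhm
  }, numeric(1))
  expect_true(all(diff(fwhm) > 0))
})

test_that("trapezoidal area telescopes to the GP drop across the grid", {
  # exact identity on a uniform grid for the central + one-sided scheme
  set.seed(11)
  gp <- cumsum(c(0.8, -runif(30, 0, 0.03)))
  tt <- seq_along(gp)
  d <- neg_derivative(gp_curve(tt, gp))
  area <- sum(diff(tt) * (d$neg_dgp_dt[-1] + d$neg_dgp_dt[-31]) / 2)
  expect_equal(area, gp[1] - gp[31], tolerance = 1e-12)
  # and the extracted area for a drift-free model spanning +-10 widths
  m <- noiseless_model("DMPC")
  grid <- seq(m$t_m - 10 * m$width_k, m$t_m + 10 * m$width_k, by = 0.1)
  tr <- find_transition(ideal_curve(m, grid))
  expect_equal(tr$area, ideal_gp(grid[1], m) - ideal_gp(grid[length(grid)], m),
               tolerance = 1e-6)
  # approaching the full gel-fluid plateau separation
  expect_equal(tr$area, m$gp_gel - m$gp_fluid, tolerance = 1e-3)
})

test_that("peak search handles ties, boundaries and truncation", {
  # ties at equal maxima resolve to the lowest temperature
  d <- make_derivative(1:7, c(0, 0.2, 1, 0.5, 1, 0.2, 0))
  expect_equal(find_transition(d)$t_m, 3)
  # monotone derivative: peak at the searched edge -> boundary warning
  dmono <- make_derivative(1:6, c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5))
  tr <- suppressWarnings(tryCatch(find_transition(dmono),
                                  error = function(e) e))
  if (inherits(tr, "transition_result")) {
    expect_true(any(grepl("boundary-peak", tr$warnings)))
  } else {
    expect_s3_class(tr, "laurdanGP_fwhm_error")
  }
  # truncated peak: half maximum never crossed on the high-T side
  dtrunc <- make_derivative(1:5, c(0, 0.2, 1, 0.9, 0.8))
  err <- tryCatch(find_transition(dtrunc), error = function(e) e)
  expect_s3_class(err, "laurdanGP_fwhm_error")
  expect_equal(err$partial$t_m, 3)
  # flat derivative: no transition
  expect_error(find_transition(make_derivative(1:5, rep(0, 5))),
               class = "laurdanGP_no_transition_error")
  expect_error(find_transition(gp_curve(1:10, rep(0.4, 10))),
               class = "laurdanGP_no_transition_error")
})

test_that("parabolic refinement sharpens an off-grid peak when requested", {
  m <- update(noiseless_model("DMPC"), t_m = 24.4)
  cur <- ideal_curve(m, 10:40)
  coarse <- find_transition(cur)$t_m
  refined <- find_transition(cur, refine_peak = TRUE)$t_m
  expect_equal(coarse, 24)              # grid argmax, default behaviour
  expect_lt(abs(refined - 24.4), abs(coarse - 24.4))
})

test_that("transition-temperature differences reproduce the packaged offsets", {
  grid <- 9:49
  luv <- series_to_curve(synth_series(noiseless_model("DMPC"), grid,
                                      3, 1, seed = 1))
  expect_equal(delta_tm(luv, luv), 0)
  disc <- series_to_curve(synth_series(noiseless_model("DMPC", "spMSP1D1"),
                                       grid, 3, 1, seed = 2))
  expect_equal(delta_tm(disc, luv), 5)
  expect_equal(delta_tm(luv, disc), -5)  # antisymmetric
  grid2 <- 26:58
  luv2 <- series_to_curve(synth_series(noiseless_model("DPPC"), grid2,
                                       3, 1, seed = 3))
  disc2 <- series_to_curve(synth_series(noiseless_model("DPPC", "spMSP1D1"),
                                        grid2, 3, 1, seed = 4))
  expect_equal(delta_tm(disc2, luv2), 2)
})
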