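test_that("front position finds the steepest point of the rightward front", {
  g <- build_grid(100, 1001)
  # tanh front: inflection (max |slope|) at its centre by symmetry
  s <- tanh_state(g, centre = 50, w = 5)
  expect_equal(front_position(s, g), 50, tolerance = g$dx / 2)
  # Gaussian: |slope| of exp(-(x/10)^2) is maximal at x = 10/sqrt(2);
  # independent oracle: dense-grid argmax of the numerical gradient
  sgau <- structure(list(t = 0, rho = 100 * exp(-(g$x / 10)^2),
                         v = rep(0.5, g$nx), sigma = rep(1, g$nx)),
                    class = "sim_state")
  xf <- seq(0, 30, by = 1e-4)
  oracle <- xf[which.max(abs(diff(100 * exp(-(xf / 10)^2)) / 1e-4))]
  expect_equal(oracle, 10 / sqrt(2), tolerance = 1e-3)
  expect_equal(front_position(sgau, g), oracle, tolerance = g$dx / 2)
})

test_that("flat or increasing-only profiles raise a no-front error", {
  g <- build_grid(100, 101)
  flat <- structure(list(t = 0, rho = rep(25, g$nx)), class = "sim_state")
  expect_error(front_position(flat, g), class = "gliovasc_nofront_error")
})

test_that("front speed is the least-squares slope over the late window", {
  p <- glioma_params()
  g <- build_grid(1000, 1001)
  tr <- synthetic_trajectory(seq(0, 400, 10), function(t) 10 + 0.2 * t, g, p)
  fs <- front_speed(tr)
  expect_equal(fs$speed, 0.2, tolerance = 1e-12)
  expect_lt(fs$rms_residual, 1e-9)
  # stationary profile
  tr0 <- synthetic_trajectory(seq(0, 400, 10), function(t) 60, g, p)
  expect_equal(front_speed(tr0)$speed, 0)
  # translation invariance of the fitted slope
  trs <- synthetic_trajectory(seq(0, 400, 10), function(t) 150 + 0.2 * t, g, p)
  expect_equal(front_speed(trs)$speed, fs$speed)
})

test_that("fronts near the right boundary are flagged, short windows rejected", {
  p <- glioma_params()
  g <- build_grid(100, 1001)
  trb <- synthetic_trajectory(seq(0, 400, 10), function(t) 50 + 0.2 * t, g, p)
  expect_error(front_speed(trb), class = "gliovasc_boundary_error")
  tr <- synthetic_trajectory(c(0, 150, 390, 400), function(t) 10 + 0.1 * t, g, p)
  expect_error(front_speed(tr), "fewer than 4")
})

test_that("infiltration width matches the closed-form tanh inversion", {
  g <- build_grid(200, 4001)
  w <- 5
  s <- tanh_state(g, centre = 50, w = w)
  # crossings of level*max: (1 - tanh(u))/2 = level  =>  u = atanh(1 - 2*level)
  # independent oracle: root finding on the continuous profile
  prof <- function(x) 100 * (1 - tanh((x - 50) / w)) / 2
  rmax <- prof(0)
  x80 <- uniroot(function(x) prof(x) - 0.80 * rmax, c(0, 200), tol = 1e-12)$root
  x02 <- uniroot(function(x) prof(x) - 0.02 * rmax, c(0, 200), tol = 1e-12)$root
  oracle <- x02 - x80
  expect_equal(oracle, w * (atanh(0.96) + atanh(0.6)), tolerance = 1e-4)
  expect_equal(infiltration_width(s, g), oracle, tolerance = 1e-3)
  # dimensional homogeneity: stretching x doubles the width exactly
  g2 <- build_grid(400, 8001)
  s2 <- tanh_state(g2, centre = 100, w = 2 * w)
  expect_equal(infiltration_width(s2, g2), 2 * infiltration_width(s, g),
               tolerance = 1e-3)
})

test_that("width of a sharpening step shrinks towards zero", {
  widths <- vapply(c(4, 2, 1, 0.5), function(w) {
    g <- build_grid(100, 2001)
    infiltration_width(tanh_state(g, centre = 50, w = w), g)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[length(widths)], 2)
})

test_that("width errors when a crossing lies beyond the domain", {
  g <- build_grid(60, 601)
  s <- tanh_state(g, centre = 58, w = 5)  # 2% crossing beyond x = 60
  expect_error(infiltration_width(s, g), class = "gliovasc_width_error")
})

test_that("effective rates reduce to the intrinsic rates identities", {
  p <- glioma_params(lambda1 = 2, lambda2 = 1, sigma0 = 1)
  g <- build_grid(100, 1001)
  base <- list(rho = rep(50, g$nx))
  # uniform physiological oxygen: exactly (D, b)
  st <- c(base, list(sigma = rep(p$sigma0, g$nx)))
  eff <- effective_rates(st, p, g)
  expect_equal(eff$D_eff, p$D)
  expect_equal(eff$b_eff, p$b)
  # anoxia: maximal motility D_rho = D/alpha(sigma0), zero proliferation
  st0 <- c(base, list(sigma = rep(0, g$nx)))
  eff0 <- effective_rates(st0, p, g)
  a0 <- switch_fractions(p$sigma0, p)$alpha
  expect_equal(eff0$D_eff, p$D / a0)
  expect_equal(eff0$b_eff, 0)
  # half/half split: arithmetic means (trapezoid error ~ one cell)
  sthalf <- c(base, list(sigma = c(rep(p$sigma0, 500), rep(0, 501))))
  effh <- effective_rates(sthalf, p, g)
  expect_equal(effh$D_eff, (p$D + p$D / a0) / 2, tolerance = 0.01)
  expect_equal(effh$b_eff, p$b / 2, tolerance = 0.01)
})

test_that("effective rates respond monotonically to pointwise oxygen changes", {
  p <- glioma_params()
  g <- build_grid(100, 201)
  set.seed(45)
  sig <- runif(g$nx, 0, p$sigma0)
  bump <- runif(g$nx, 0, p$sigma0 - sig)  # pointwise increase, stays in range
  e1 <- effective_rates(list(rho = rep(1, g$nx), sigma = sig), p, g)
  e2 <- effective_rates(list(rho = rep(1, g$nx), sigma = sig + bump), p, g)
  expect_lte(e2$D_eff, e1$D_eff)
  expect_gte(e2$b_eff, e1$b_eff)
})

test_that("observables bundle evaluates at the final snapshot", {
  p <- fast_params(D = 0.1, b = 0.02)
  g <- build_grid(p$L, 401)
  tr <- integrate_model(p, "I", g)
  ob <- observables(tr)
  expect_s3_class(ob, "observable_set")
  expect_equal(ob$t_eval, p$T_f)
  expect_equal(ob$D_eff, p$D)   # variant I: sigma = sigma0 everywhere
  expect_equal(ob$b_eff, p$b)
  expect_true(ob$front_speed > 0 && is.finite(ob$infiltration_width))
})
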