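test_that("switch fractions reproduce hand-evaluated values", {
  # symmetric point: f21 = f12 = 1
  sw <- switch_fractions(1.0, glioma_params(lambda1 = 2, lambda2 = 1))
  expect_equal(sw$alpha, 0.5)
  expect_equal(sw$beta, 0.5)
  # anoxia: no migratory -> proliferative switching
  sw0 <- switch_fractions(0, glioma_params(lambda1 = 3, lambda2 = 0.5))
  expect_equal(sw0$alpha, 1)
  expect_equal(sw0$beta, 0)
  # independent evaluation of (lambda1 - sigma)/((lambda1 - sigma) + lambda2*sigma)
  f21 <- 2.0 - 0.25; f12 <- 2.0 * 0.25
  expect_equal(switch_fractions(0.25, glioma_params(lambda1 = 2, lambda2 = 2))$alpha,
               f21 / (f21 + f12))   # = 1.75/2.25
})

test_that("alpha + beta = 1 exactly and both are monotone on [0, lambda1]", {
  set.seed(41)
  for (i in 1:20) {
    l1 <- runif(1, 1.1, 5); l2 <- runif(1, 0.1, 3)
    p <- glioma_params(lambda1 = l1, lambda2 = l2, sigma0 = 1)
    sig <- sort(runif(50, 0, l1))
    sw <- switch_fractions(sig, p)
    expect_identical(sw$alpha + sw$beta, rep(1, 50))
    expect_true(all(sw$alpha >= 0 & sw$alpha <= 1))
    expect_true(all(diff(sw$alpha) < 0))
    expect_true(all(diff(sw$beta) > 0))
  }
})

test_that("oxygen outside [0, lambda1] is a domain error", {
  p <- glioma_params()
  expect_error(switch_fractions(-0.01, p), class = "gliovasc_domain_error")
  expect_error(switch_fractions(p$lambda1 + 0.01, p), class = "gliovasc_domain_error")
})

test_that("normalisation recovers the intrinsic rates at physiological oxygen", {
  set.seed(42)
  for (i in 1:10) {
    s0 <- runif(1, 0.5, 2)
    p <- glioma_params(sigma0 = s0, lambda1 = s0 + runif(1, 0.5, 3),
                       lambda2 = runif(1, 0.2, 3))
    sw0 <- switch_fractions(s0, p)
    expect_equal((p$D / sw0$alpha) * sw0$alpha, p$D)
    expect_equal((p$b / sw0$beta) * sw0$beta, p$b)
    # and D_rho >= D, b_rho >= b since alpha, beta <= 1
    expect_gte(p$D / sw0$alpha, p$D)
    expect_gte(p$b / sw0$beta, p$b)
  }
})

test_that("smoothed Heaviside is a decreasing sigmoid converging to the step", {
  expect_equal(smooth_heaviside(0, 0.3), 0.5)
  expect_gte(smooth_heaviside(-10 * 0.05, 0.05), 0.9999)
  expect_lte(smooth_heaviside(+10 * 0.05, 0.05), 0.0001)
  xi <- seq(-1, 1, length.out = 101)
  expect_true(all(diff(smooth_heaviside(xi, 0.1)) < 0))
  # pointwise convergence to the sharp step as theta -> 0
  for (x in c(-0.3, -0.01, 0.02, 0.5)) {
    lim <- if (x <= 0) 1 else 0
    expect_equal(smooth_heaviside(x, 1e-4), lim, tolerance = 1e-6)
  }
  expect_error(smooth_heaviside(0, 0), "theta")
  expect_error(smooth_heaviside(0, -1), "theta")
})

test_that("Michaelis-Menten activation is bounded and has the right limits", {
  p <- glioma_params()
  set.seed(43)
  rho <- runif(50, 0, p$N); sig <- runif(50, 0, p$sigma0); v <- runif(50, 0, 1)
  m <- mm_activation(rho, sig, v, p)
  expect_true(all(m >= 0 & m <= 1))
  # v -> 0 with hypoxic cells present: activation saturates at 1
  expect_equal(mm_activation(50, 0.1, 1e-12, p), 1, tolerance = 1e-9)
  # no cells: no pro-angiogenic factor, no activation
  expect_equal(mm_activation(0, 0.1, 0.5, p), 0)
  # degenerate 0/0 point defined as 0
  expect_identical(mm_activation(0, 0.1, 0, p), 0)
})

test_that("reaction terms vanish at the healthy-tissue fixed point", {
  p <- glioma_params()
  n <- 11
  state <- list(rho = rep(0, n), v = rep(p$v0, n), sigma = rep(p$sigma0, n))
  for (variant in c("I", "II", "III")) {
    r <- reaction_terms(state, p, variant)
    expect_equal(r$rho, rep(0, n))
    expect_equal(r$v, rep(0, n))
    expect_equal(r$sigma, rep(0, n))
  }
})

test_that("glioma reaction at physiological oxygen is exactly logistic in b", {
  # the b/beta(sigma0) normalisation cancels when sigma = sigma0
  p <- glioma_params(lambda1 = 2, lambda2 = 1, sigma0 = 1)
  state <- list(rho = p$N / 2, v = p$v0, sigma = p$sigma0)
  for (variant in c("I", "II", "III")) {
    r <- reaction_terms(state, p, variant)
    expect_equal(r$rho, p$b * (p$N / 2) * (1 - 1 / 2))
  }
})

test_that("vaso-occlusion magnitude and steepness match the power law", {
  # independent arithmetic: g2 * v * rho^n = 5e-13 * 0.5 * 100^6 = 0.25 / day
  p <- glioma_params(g1 = 0, g2 = 5.0e-13, n = 6L)
  r <- reaction_terms(list(rho = 100, v = 0.5, sigma = 0.5), p, "III")
  expect_equal(r$v, -(5.0e-13 * 0.5 * 100^6))
  expect_equal(r$v, -0.25)
  # occlusion at full capacity is 2^n times that at half capacity
  rN <- reaction_terms(list(rho = p$N, v = 0.5, sigma = 0.5), p, "III")
  rH <- reaction_terms(list(rho = p$N / 2, v = 0.5, sigma = 0.5), p, "III")
  expect_equal(rN$v / rH$v, 2^6)
})

test_that("model hierarchy limits reduce reaction terms exactly", {
  set.seed(44)
  n <- 25
  p3 <- glioma_params()
  state <- list(rho = runif(n, 0, p3$N), v = runif(n, 0, 1),
                sigma = runif(n, 0, p3$sigma0))
  # Model III with g1 = g2 = 0 has Model II dynamics
  p3z <- update_params(p3, g1 = 0, g2 = 0)
  r3 <- reaction_terms(state, p3z, "III")
  r2 <- reaction_terms(state, p3z, "II")
  expect_equal(r3$rho, r2$rho)
  expect_equal(r3$sigma, r2$sigma)
  expect_equal(r3$v, rep(0, n))
  # Model II with h2 = 0 leaves sigma = sigma0 stationary and is Model I in rho
  p2z <- update_params(p3, h2 = 0)
  st0 <- list(rho = state$rho, v = rep(p3$v0, n), sigma = rep(p3$sigma0, n))
  r2z <- reaction_terms(st0, p2z, "II")
  r1 <- reaction_terms(st0, p2z, "I")
  expect_equal(r2z$sigma, rep(0, n))
  expect_equal(r2z$rho, r1$rho)
})

test_that("reaction terms reject bad variants and negative fields", {
  p <- glioma_params()
  st <- list(rho = 1, v = 0.5, sigma = 0.5)
  expect_error(reaction_terms(st, p, "IV"))
  expect_error(reaction_terms(list(rho = -1, v = 0.5, sigma = 0.5), p, "II"),
               class = "gliovasc_domain_error")
})

test_that("uniform oxygen fixed point matches its closed form and the ODE limit", {
  p <- glioma_params()
  expect_equal(homogeneous_oxygen_steady_state(0, 0.5, p), p$sigma0)
  expect_equal(homogeneous_oxygen_steady_state(100, 0, p), 0)
  # closed form at baseline consumption/supply
  sstar <- homogeneous_oxygen_steady_state(100, 0.5, p)
  expect_equal(sstar, 0.337 * 0.5 / (0.337 * 0.5 + 5.73e-3 * 100))
  # long-time limit of the uniform sigma-dynamics through the reaction terms
  rhs <- function(t, y, parms)
    list(reaction_terms(list(rho = 100, v = 0.5, sigma = y), p, "II")$sigma)
  out <- deSolve::ode(y = c(sigma = p$sigma0), times = c(0, 1e3), func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(out[2, 2]), sstar, tolerance = 1e-6)
  expect_error(homogeneous_oxygen_steady_state(0, 0, p), "degenerate")
})
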