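test_that("phase grid quadrature weights span the velocity interval", {
  g <- phase_grid(nx = 16, nxi = 24, xi_max = 6)
  expect_equal(sum(g$xi_weights), 12, tolerance = 1e-9)
  expect_true(all(g$xi_nodes != 0))
  expect_equal(range(g$x_nodes), c(0, g$L))
  expect_error(phase_grid(nxi = 17), "even")
})

test_that("maxwellian is symmetric at zero drift, linear in density, and
           recovers its moments under quadrature", {
  g <- phase_grid(nx = 2, nxi = 32, xi_max = 8)
  f0 <- maxwellian(macro_moments(1, 0, 1), g)
  expect_equal(f0, rev(f0))  # even velocity symmetry
  f2 <- maxwellian(macro_moments(2, 0, 1), g)
  expect_equal(f2 / f0, rep(2, length(f0)))
  # quadrature round trip on a xi-grid spanning +-8 sqrt(theta)
  for (pars in list(c(1.3, 0.2, 0.7), c(0.5, -0.8, 1.2))) {
    st <- uniform_maxwellian_state(g, pars[1], pars[2], pars[3])
    m <- moments_of(st)
    expect_equal(m$rho[1], pars[1], tolerance = 1e-6)
    expect_equal(m$u[1], pars[2], tolerance = 1e-6)
    expect_equal(m$theta[1], pars[3], tolerance = 1e-6)
  }
  expect_error(macro_moments(-1, 0, 1), "density")
  expect_error(macro_moments(1, 0, 0), "temperature")
})

test_that("moments transform correctly under scaling and velocity mirror", {
  set.seed(5)
  g <- phase_grid(nx = 2, nxi = 32, xi_max = 8)
  f <- random_mixture_state(g)
  m <- moments_of(f)
  doubled <- kinetic_state(g, 2 * f$values, 1)
  m2 <- moments_of(doubled)
  expect_equal(m2$rho, 2 * m$rho)
  expect_equal(m2$u, m$u)
  expect_equal(m2$theta, m$theta)
  # Gauss-Legendre nodes are symmetric, so reversing columns mirrors xi
  mirrored <- kinetic_state(g, f$values[, rev(seq_along(g$xi_nodes)),
                                        drop = FALSE], 1)
  mm <- moments_of(mirrored)
  expect_equal(mm$rho, m$rho, tolerance = 1e-12)
  expect_equal(mm$u, -m$u, tolerance = 1e-12)
  expect_equal(mm$theta, m$theta, tolerance = 1e-12)
})

test_that("global equilibrium is a fixed point of the stationary solver", {
  g <- phase_grid(nx = 32, nxi = 24)
  f <- solve_stationary_bgk(macro_moments(1, 0, 1), macro_moments(1, 0, 1),
                            tau = 0.5, grid = g)
  fm <- maxwellian(macro_moments(1, 0, 1), g)
  expect_lt(max(abs(sweep(f$values, 2, fm, "-"))), 1e-5)
  expect_lt(attr(f, "residual"), 1e-4)
})

test_that("large relaxation time recovers free streaming", {
  g <- phase_grid(nx = 32, nxi = 24)
  tau <- 1e6 * g$L / max(g$xi_nodes)
  f <- solve_stationary_bgk(macro_moments(1, 0, 0.5),
                            macro_moments(0.7, 0, 2), tau = tau, grid = g)
  fL <- maxwellian(macro_moments(1, 0, 0.5), g)
  fR <- maxwellian(macro_moments(0.7, 0, 2), g)
  pos <- g$xi_nodes > 0
  expect_lt(max(abs(sweep(f$values[, pos, drop = FALSE], 2, fL[pos], "-"))),
            1e-3)
  expect_lt(max(abs(sweep(f$values[, !pos, drop = FALSE], 2, fR[!pos], "-"))),
            1e-3)
})

test_that("coarse-grid solution agrees with a 4x-refined reference", {
  mL <- macro_moments(1, 0, 0.5); mR <- macro_moments(1, 0, 1.5)
  coarse <- solve_stationary_bgk(mL, mR, tau = 0.1,
                                 grid = phase_grid(nx = 17, nxi = 24))
  fine <- solve_stationary_bgk(mL, mR, tau = 0.1,
                               grid = phase_grid(nx = 65, nxi = 24))
  idx <- seq(1, 65, by = 4)  # coarse nodes are a subset of the fine nodes
  mc <- moments_of(coarse); mf <- moments_of(fine)
  expect_lt(max(abs(mc$rho - mf$rho[idx])), 0.08)
  expect_lt(max(abs(mc$theta - mf$theta[idx])), 0.08)
})

test_that("solver reports non-convergence with its residual history", {
  err <- tryCatch(
    solve_stationary_bgk(macro_moments(1, 0, 0.5), macro_moments(1, 0, 2),
                         tau = 0.1, grid = phase_grid(nx = 32, nxi = 24),
                         tol = 1e-14, max_iter = 5),
    error = function(e) e)
  expect_match(conditionMessage(err), "no convergence")
  expect_length(err$residual_history, 5)
})

test_that("local entropy handles plateaus, scaling and matches the
           Gaussian closed form", {
  g <- phase_grid(nx = 4, nxi = 32, xi_max = 8)
  ones <- kinetic_state(g, matrix(1, 4, 32), 1)
  expect_equal(local_entropy_profile(ones)$S, rep(0, 4))  # 1 ln 1 = 0
  # Maxwellian entropy: -rho ln rho + rho/2 ln(2 pi e theta)
  g2 <- phase_grid(nx = 2, nxi = 64, xi_max = 10)
  st <- uniform_maxwellian_state(g2, 1.3, 0.2, 0.9)
  expect_equal(local_entropy_profile(st)$S[1],
               -1.3 * log(1.3) + 1.3 * 0.5 * log(2 * pi * exp(1) * 0.9),
               tolerance = 1e-9)
  # scaling by c: each term becomes -c f (ln c + ln f)
  set.seed(9)
  f <- random_mixture_state(g)
  c0 <- 1.7
  scaled <- kinetic_state(g, c0 * f$values, 1)
  w <- g$xi_weights
  direct <- apply(f$values, 1, function(row)
    -sum(w * c0 * row * (log(c0) + log(row))))
  expect_equal(local_entropy_profile(scaled)$S, direct, tolerance = 1e-12)
})

test_that("equilibrium entropy dominates nonequilibrium entropy", {
  g <- phase_grid(nx = 2, nxi = 32, xi_max = 8)
  # at equilibrium the two coincide
  st <- uniform_maxwellian_state(g, 1, 0.3, 1)
  expect_equal(equilibrium_entropy_profile(st)$S,
               local_entropy_profile(st)$S, tolerance = 1e-6)
  # a bimodal mixture sits strictly below its equilibrium entropy
  mix <- kinetic_state(g, maxwellian(macro_moments(0.6, -1.5, 0.4), g) +
                         maxwellian(macro_moments(0.7, 1.2, 0.3), g), 1)
  expect_true(all(equilibrium_entropy_profile(mix)$S >
                    local_entropy_profile(mix)$S))
  # property: never below, up to quadrature tolerance
  set.seed(21)
  for (rep in 1:25) {
    f <- random_mixture_state(g)
    gap <- equilibrium_entropy_profile(f)$S - local_entropy_profile(f)$S
    expect_gte(min(gap), -1e-8)
  }
})

test_that("uniform relaxation follows the closed-form exponential", {
  set.seed(31)
  g <- phase_grid(nx = 2, nxi = 48, xi_max = 8)
  f0 <- random_mixture_state(g)
  expect_equal(relax_uniform(f0, T = 2, times = 0)[[1]]$values, f0$values)
  fm <- maxwellian(moments_of(f0), g)
  far <- relax_uniform(f0, T = 2, times = 2e6)[[1]]$values
  expect_lt(max(abs(sweep(far, 2, fm, "-"))), 1e-9)
  expect_error(relax_uniform(f0, T = 2, times = -1), "negative")
})

test_that("uniform relaxation conserves moments and increases entropy", {
  set.seed(13)
  g <- phase_grid(nx = 2, nxi = 48, xi_max = 10)
  for (rep in 1:20) {
    f0 <- random_mixture_state(g, u_range = c(-0.5, 0.5),
                               theta_range = c(0.6, 1.2))
    states <- relax_uniform(f0, T = 1, times = c(0, 0.2, 0.5, 1, 2, 5, 20))
    S <- vapply(states, function(s) local_entropy_profile(s)$S[1], numeric(1))
    expect_true(all(diff(S) >= -1e-9))  # H-theorem
    m0 <- moments_of(f0)
    for (s in states[c(3, 7)]) {
      m <- moments_of(s)
      expect_equal(m$rho[1], m0$rho[1], tolerance = 1e-9)
      expect_equal(m$u[1], m0$u[1], tolerance = 1e-9)
      expect_equal(m$theta[1], m0$theta[1], tolerance = 1e-9)
    }
  }
})

test_that("the age statistic integrates the entropy difference", {
  x <- seq(0, 1, length.out = 21)
  a <- entropy_profile(x, 1 + x, label = "old")
  b <- entropy_profile(x, 1 + x, label = "young")
  expect_equal(entropy_age_delta(a, b, 1), 0)
  # constant difference c over [0, L]: integral is c * L
  cst <- entropy_profile(x, (1 + x) + 0.3)
  expect_equal(entropy_age_delta(cst, b, 0.8), 0.3 * 0.8)
  # piecewise-linear difference on mismatched meshes vs fine Riemann oracle
  set.seed(17)
  xo <- sort(c(0, stats::runif(15), 1))
  xy <- sort(c(0, stats::runif(9), 1))
  So <- entropy_profile(xo, stats::runif(17, 1, 2), label = "old")
  Sy <- entropy_profile(xy, stats::runif(11, 0.5, 1.5), label = "young")
  expect_equal(entropy_age_delta(So, Sy, 0.9),
               riemann_delta(So, Sy, 0.9), tolerance = 1e-6)
  # antisymmetry under swapping old and young
  expect_equal(entropy_age_delta(So, Sy, 0.9),
               -entropy_age_delta(Sy, So, 0.9))
  expect_error(entropy_age_delta(So, Sy, 1.5), "does not cover")
})

test_that("structural state validates bin shapes and timescale", {
  v <- array(stats::runif(24), c(2, 3, 4))
  s <- structural_state(v, v * 0.5, T = 1e8)
  expect_s3_class(s, "structural_state")
  expect_error(structural_state(v, array(1, c(2, 3, 2)), 1), "shape")
  expect_error(structural_state(v, v, T = -1), "T must be")
})
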