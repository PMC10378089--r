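# Shared builders for randomized test cases. All randomness is drawn under
# an explicit seed inside each test.

# random strictly positive density profile over n compartments
random_profile <- function(n, label = "") {
  density_profile(seq_len(n), stats::runif(n, 0.05, 2), label = label)
}

# single-node kinetic state: mixture of two Maxwellians with moderate
# parameters, well resolved by the velocity quadrature; narrow the ranges
# (and widen the grid) where a test needs quadrature-exact moments
random_mixture_state <- function(grid, T = 1, u_range = c(-1, 1),
                                 theta_range = c(0.6, 1.5)) {
  m1 <- macro_moments(stats::runif(1, 0.4, 1.5),
                      stats::runif(1, u_range[1], u_range[2]),
                      stats::runif(1, theta_range[1], theta_range[2]))
  m2 <- macro_moments(stats::runif(1, 0.4, 1.5),
                      stats::runif(1, u_range[1], u_range[2]),
                      stats::runif(1, theta_range[1], theta_range[2]))
  kinetic_state(grid, maxwellian(m1, grid) + maxwellian(m2, grid), T)
}

# build a full-slab state from one Maxwellian repeated at every x node
uniform_maxwellian_state <- function(grid, rho = 1, u = 0, theta = 1, T = 1) {
  fm <- maxwellian(macro_moments(rho, u, theta), grid)
  kinetic_state(grid,
                matrix(fm, length(grid$x_nodes), length(grid$xi_nodes),
                       byrow = TRUE), T)
}

# fine midpoint-Riemann integral of the linearly interpolated difference
# S_old - S_young over [0, L]; the independent oracle for the age integral
riemann_delta <- function(S_old, S_young, L, n = 1e5) {
  mid <- (seq_len(n) - 0.5) * L / n
  d <- stats::approx(S_old$x_nodes, S_old$S, mid)$y -
    stats::approx(S_young$x_nodes, S_young$S, mid)$y
  sum(d) * L / n
}
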