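#' Phase-space grid for the kinetic model
#'
#' Discretization of the one-dimensional phase space \eqn{(x, \xi)}:
#' spatial depth \eqn{x \in [0, L]} (0 = basal layer, \eqn{L} = surface)
#' and velocity \eqn{\xi} on a symmetric Gauss-Legendre quadrature grid.
#' All quantities are dimensionless.
#'
#' An even number of velocity nodes is required: symmetric Gauss-Legendre
#' rules with even order have no node at \eqn{\xi = 0}, along which the
#' stationary transport characteristic degenerates.
#'
#' @param nx number of spatial nodes (uniformly spaced), >= 2.
#' @param L slab thickness, > 0.
#' @param nxi number of velocity nodes, even, >= 4.
#' @param xi_max velocity cut-off; nodes span \eqn{[-\xi_{max}, \xi_{max}]}.
#' @return Object of class `phase_grid` with elements `x_nodes`,
#'   `xi_nodes`, `xi_weights` (summing to \eqn{2\xi_{max}}), `L`.
#' @examples
#' g <- phase_grid(nx = 16, nxi = 16)
#' sum(g$xi_weights)  # 16: the length of the velocity interval
#' @export
phase_grid <- function(nx = 64, L = 1, nxi = 32, xi_max = 8) {
  if (nx < 2) stop("phase_grid: need at least 2 spatial nodes", call. = FALSE)
  if (L <= 0) stop("phase_grid: L must be positive", call. = FALSE)
  if (nxi < 4 || nxi %% 2 != 0)
    stop("phase_grid: nxi must be an even integer >= 4 (avoids a node at xi = 0)",
         call. = FALSE)
  gl <- pracma::gaussLegendre(nxi, -xi_max, xi_max)
  structure(list(x_nodes = seq(0, L, length.out = nx),
                 xi_nodes = gl$x, xi_weights = gl$w, L = L),
            class = "phase_grid")
}

#' Macroscopic moments (density, mean velocity, temperature)
#'
#' Hydrodynamic moments per spatial node; the parameters of the local
#' Maxwellian. Scalars are accepted for a single node.
#'
#' @param rho density, strictly positive.
#' @param u mean velocity.
#' @param theta temperature, strictly positive.
#' @return Object of class `macro_moments`.
#' @export
macro_moments <- function(rho, u = 0, theta = 1) {
  n <- max(length(rho), length(u), length(theta))
  rho <- rep_len(as.numeric(rho), n)
  u <- rep_len(as.numeric(u), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("macro_moments: density must be finite and > 0", call. = FALSE)
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("macro_moments: temperature must be finite and > 0", call. = FALSE)
  structure(list(rho = rho, u = u, theta = theta), class = "macro_moments")
}

#' Local equilibrium (Maxwellian) distribution
#'
#' The 1-D Maxwellian determined by local moments,
#' \deqn{f_M(\xi) = \frac{\rho}{\sqrt{2\pi\theta}}
#'       \exp\!\left(-\frac{(\xi-u)^2}{2\theta}\right).}
#' Among all distributions sharing \eqn{(\rho, u, \theta)} it maximizes
#' the Boltzmann entropy \eqn{-\int f \log f\, d\xi}.
#'
#' @param m a [macro_moments] object (one or several nodes).
#' @param grid a [phase_grid].
#' @return If `m` holds one node, a numeric vector of \eqn{f_M} over
#'   `grid$xi_nodes`; otherwise a matrix (nodes x velocities).
#' @export
maxwellian <- function(m, grid) {
  stopifnot(inherits(m, "macro_moments"), inherits(grid, "phase_grid"))
  xi <- grid$xi_nodes
  fm <- t(vapply(seq_along(m$rho), function(i) {
    m$rho[i] / sqrt(2 * pi * m$theta[i]) *
      exp(-(xi - m$u[i])^2 / (2 * m$theta[i]))
  }, numeric(length(xi))))
  if (length(m$rho) == 1L) drop(fm) else fm
}

#' Kinetic state on a phase grid
#'
#' Container for a discrete distribution function \eqn{f(x_i, \xi_j)}
#' together with its grid and relaxation time (\eqn{\tau} for the fast
#' metabolic scale, or the long structural timescale \eqn{T} — the same
#' relaxation operator serves both).
#'
#' @param grid a [phase_grid].
#' @param values numeric matrix, `length(x_nodes)` rows by
#'   `length(xi_nodes)` columns, all entries finite and >= 0. A single
#'   vector is accepted for a one-node grid.
#' @param relaxation_time positive relaxation time.
#' @return Object of class `kinetic_state`.
#' @export
kinetic_state <- function(grid, values, relaxation_time = 1) {
  stopifnot(inherits(grid, "phase_grid"))
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  if (nrow(values) != length(grid$x_nodes) && nrow(values) != 1L)
    stop("kinetic_state: row count must match spatial nodes", call. = FALSE)
  if (ncol(values) != length(grid$xi_nodes))
    stop("kinetic_state: column count must match velocity nodes", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("kinetic_state: values must be finite and non-negative", call. = FALSE)
  if (!is.numeric(relaxation_time) || relaxation_time <= 0)
    stop("kinetic_state: relaxation time must be > 0", call. = FALSE)
  structure(list(grid = grid, values = values,
                 relaxation_time = relaxation_time),
            class = "kinetic_state")
}

#' Moments of a kinetic state
#'
#' Velocity-space quadrature moments per spatial node:
#' \eqn{\rho = \int f\,d\xi}, \eqn{u = \rho^{-1}\int \xi f\,d\xi},
#' \eqn{\theta = \rho^{-1}\int (\xi-u)^2 f\,d\xi}.
#'
#' @param f a [kinetic_state].
#' @return A [macro_moments] object over the state's spatial nodes.
#' @export
moments_of <- function(f) {
  stopifnot(inherits(f, "kinetic_state"))
  w <- f$grid$xi_weights
  xi <- f$grid$xi_nodes
  rho <- as.numeric(f$values %*% w)
  if (any(rho <= 0))
    stop("moments_of: zero quadrature density at spatial node ",
         which(rho <= 0)[1L], call. = FALSE)
  u <- as.numeric(f$values %*% (w * xi)) / rho
  theta <- vapply(seq_along(rho), function(i)
    sum(w * (xi - u[i])^2 * f$values[i, ]) / rho[i], numeric(1))
  macro_moments(rho, u, theta)
}

#' Local entropy profile over depth
#'
#' Container for a depth-resolved entropy curve \eqn{S(x)} with the slab
#' thickness it refers to; the object integrated by [entropy_age_delta()].
#'
#' @param x_nodes increasing numeric depth coordinates.
#' @param S entropy values per node.
#' @param L thickness (defaults to `max(x_nodes)`).
#' @param label free text, e.g. `"young"`.
#' @return Object of class `entropy_profile`.
#' @export
entropy_profile <- function(x_nodes, S, L = max(x_nodes), label = "") {
  x_nodes <- as.numeric(x_nodes); S <- as.numeric(S)
  if (length(x_nodes) != length(S))
    stop("entropy_profile: x and S differ in length", call. = FALSE)
  if (length(x_nodes) > 1L && any(diff(x_nodes) <= 0))
    stop("entropy_profile: x nodes must be strictly increasing", call. = FALSE)
  if (!is.finite(L) || L <= 0)
    stop("entropy_profile: thickness L must be > 0", call. = FALSE)
  structure(list(x_nodes = x_nodes, S = S, L = L,
                 label = as.character(label)[1L]),
            class = "entropy_profile")
}

#' Nonequilibrium local entropy of a kinetic state
#'
#' The Boltzmann entropy moment evaluated per spatial node,
#' \deqn{S(x) = -\int f \ln f \, d\xi
#'   \approx -\sum_j w_j f(x, \xi_j) \ln f(x, \xi_j),}
#' with the convention \eqn{0 \ln 0 = 0}.
#'
#' @param f a [kinetic_state].
#' @param label label for the returned profile.
#' @return An [entropy_profile] over the state's spatial nodes.
#' @export
local_entropy_profile <- function(f, label = "") {
  stopifnot(inherits(f, "kinetic_state"))
  w <- f$grid$xi_weights
  S <- apply(f$values, 1, function(row) {
    nz <- row > 0
    -sum(w[nz] * row[nz] * log(row[nz]))
  })
  x <- if (nrow(f$values) == 1L) f$grid$x_nodes[1L] else f$grid$x_nodes
  entropy_profile(x, S, L = f$grid$L, label = label)
}

#' Equilibrium local entropy of a kinetic state
#'
#' Entropy of the Maxwellian sharing each node's moments: the "line of
#' death" against the nonequilibrium "line of life". Because the
#' Maxwellian maximizes \eqn{-\int f \ln f} at fixed
#' \eqn{(\rho, u, \theta)}, this profile dominates
#' [local_entropy_profile()] pointwise (up to quadrature tolerance); a
#' living, nonequilibrium state sits strictly below it.
#'
#' @param f a [kinetic_state].
#' @param label label for the returned profile.
#' @return An [entropy_profile] of the nodewise-equilibrium entropy.
#' @export
equilibrium_entropy_profile <- function(f, label = "equilibrium") {
  stopifnot(inherits(f, "kinetic_state"))
  m <- moments_of(f)
  fm <- maxwellian(m, f$grid)
  if (is.vector(fm)) fm <- matrix(fm, nrow = 1)
  feq <- kinetic_state(f$grid, fm[seq_len(nrow(f$values)), , drop = FALSE],
                       f$relaxation_time)
  local_entropy_profile(feq, label = label)
}

#' Stationary BGK transport solve between two walls
#'
#' Solves the stationary kinetic equation
#' \deqn{\xi \frac{\partial f}{\partial x} = \frac{f_M[f] - f}{\tau}}
#' on the slab \eqn{[0, L]} by first-order upwind sweeps alternated with
#' self-consistent moment/Maxwellian updates, under inflow boundary
#' conditions: particles entering at \eqn{x = 0} (those with \eqn{\xi > 0})
#' carry the left wall's Maxwellian, those entering at \eqn{x = L}
#' (\eqn{\xi < 0}) the right wall's. The same operator, run with the long
#' structural relaxation time \eqn{T}, describes stationary structural
#' turnover on the lifetime scale.
#'
#' Iteration: sweep, then blend `relax` of the sweep result with
#' `1 - relax` of the previous iterate, until the max-norm change drops
#' below `tol`.
#'
#' @param left_boundary,right_boundary single-node [macro_moments] of the
#'   injected Maxwellians at \eqn{x = 0} and \eqn{x = L}.
#' @param tau relaxation time, > 0.
#' @param grid a [phase_grid].
#' @param tol convergence tolerance on the max-norm iterate change.
#' @param max_iter iteration cap.
#' @param relax under-relaxation factor in (0, 1].
#' @return A [kinetic_state] with attributes `iterations` (count),
#'   `residual` (max-norm of the discrete equation at the solution) and
#'   `residual_history` (per-iteration max change).
#' @examples
#' g <- phase_grid(nx = 24, nxi = 16)
#' f <- solve_stationary_bgk(macro_moments(1, 0, 1), macro_moments(1, 0, 1),
#'                           tau = 0.5, grid = g)
#' attr(f, "iterations")
#' @export
solve_stationary_bgk <- function(left_boundary, right_boundary, tau, grid,
                                 tol = 1e-8, max_iter = 10000, relax = 0.9) {
  stopifnot(inherits(left_boundary, "macro_moments"),
            inherits(right_boundary, "macro_moments"),
            inherits(grid, "phase_grid"))
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  x <- grid$x_nodes; xi <- grid$xi_nodes
  nx <- length(x); nxi <- length(xi)
  fL <- maxwellian(left_boundary, grid)
  fR <- maxwellian(right_boundary, grid)
  pos <- xi > 0; neg <- xi < 0
  # initial guess: linear blend of the two wall Maxwellians
  s <- (x - x[1L]) / (x[nx] - x[1L])
  f <- outer(1 - s, fL) + outer(s, fR)
  hist <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fm <- maxwellian(moments_of(kinetic_state(grid, f, tau)), grid)
    fs <- f
    fs[1L, pos] <- fL[pos]
    for (i in 2:nx) {
      a <- xi[pos] / (x[i] - x[i - 1L])
      fs[i, pos] <- (a * fs[i - 1L, pos] + fm[i, pos] / tau) / (a + 1 / tau)
    }
    fs[nx, neg] <- fR[neg]
    for (i in (nx - 1L):1L) {
      a <- -xi[neg] / (x[i + 1L] - x[i])
      fs[i, neg] <- (a * fs[i + 1L, neg] + fm[i, neg] / tau) / (a + 1 / tau)
    }
    fnew <- relax * fs + (1 - relax) * f
    delta <- max(abs(fnew - f))
    hist <- c(hist, delta)
    f <- fnew
    if (delta < tol) break
    if (iter >= max_iter) {
      err <- simpleError(paste0("solve_stationary_bgk: no convergence in ",
                                max_iter, " iterations (last change ",
                                format(delta), ")"))
      err$residual_history <- hist
      stop(err)
    }
  }
  out <- kinetic_state(grid, f, tau)
  attr(out, "iterations") <- iter
  attr(out, "residual") <- bgk_residual(out, fL, fR)
  attr(out, "residual_history") <- hist
  out
}

# Max-norm residual of the discrete upwind stationary equation.
bgk_residual <- function(state, fL, fR) {
  g <- state$grid; f <- state$values
  x <- g$x_nodes; xi <- g$xi_nodes
  nx <- length(x); tau <- state$relaxation_time
  fm <- maxwellian(moments_of(state), g)
  pos <- xi > 0; neg <- xi < 0
  res <- 0
  for (i in 2:nx) {
    dfdx <- (f[i, pos] - f[i - 1L, pos]) / (x[i] - x[i - 1L])
    res <- max(res, abs(xi[pos] * dfdx - (fm[i, pos] - f[i, pos]) / tau))
  }
  for (i in 1:(nx - 1L)) {
    dfdx <- (f[i + 1L, neg] - f[i, neg]) / (x[i + 1L] - x[i])
    res <- max(res, abs(xi[neg] * dfdx - (fm[i, neg] - f[i, neg]) / tau))
  }
  res
}

#' Spatially uniform BGK relaxation (closed form)
#'
#' Relaxation of a distribution toward the Maxwellian of its own initial
#' moments at rate \eqn{1/T}:
#' \deqn{\frac{\partial f}{\partial t} = \frac{f_M - f}{T}, \qquad
#'       f(t) = f_M + (f_0 - f_M)\, e^{-t/T}.}
#' Since BGK relaxation conserves \eqn{(\rho, u, \theta)}, the target
#' \eqn{f_M} is constant along the trajectory and the exponential form is
#' exact. Entropy is non-decreasing along the trajectory (H-theorem), so
#' this is the elementary model of slow structural degradation toward
#' equilibrium on the lifetime scale \eqn{T}.
#'
#' @param f0 initial [kinetic_state] (one node or many; applied nodewise).
#' @param T relaxation timescale, > 0.
#' @param times non-decreasing vector of non-negative times.
#' @return A list of [kinetic_state]s, one per requested time.
#' @export
relax_uniform <- function(f0, T, times) {
  stopifnot(inherits(f0, "kinetic_state"))
  if (!is.numeric(T) || T <= 0) stop("relax_uniform: T must be > 0", call. = FALSE)
  times <- as.numeric(times)
  if (any(times < 0)) stop("relax_uniform: negative time", call. = FALSE)
  if (is.unsorted(times)) stop("relax_uniform: times must be non-decreasing",
                               call. = FALSE)
  fm <- maxwellian(moments_of(f0), f0$grid)
  if (is.vector(fm)) fm <- matrix(fm, nrow = 1)
  lapply(times, function(t) {
    kinetic_state(f0$grid, fm + (f0$values - fm) * exp(-t / T), T)
  })
}

#' Integrated entropy difference between old and young profiles
#'
#' The tissue-age statistic
#' \deqn{\Delta S = \int_0^{L_{old}} \left(S_{old}(x) - S_{young}(x)\right) dx,}
#' evaluated by the trapezoid rule after linear interpolation of both
#' profiles onto the union of their nodes within \eqn{[0, L_{old}]}.
#' Positive \eqn{\Delta S} means the old tissue carries more local entropy
#' over its (thinner) depth than the young tissue did.
#'
#' @param S_old,S_young [entropy_profile]s covering \eqn{[0, L_{old}]}.
#' @param L_old upper integration limit; defaults to `S_old$L`.
#' @return The integral, a single number.
#' @export
entropy_age_delta <- function(S_old, S_young, L_old = S_old$L) {
  stopifnot(inherits(S_old, "entropy_profile"),
            inherits(S_young, "entropy_profile"))
  if (!is.finite(L_old) || L_old <= 0)
    stop("entropy_age_delta: L_old must be > 0", call. = FALSE)
  for (p in list(S_old, S_young)) {
    if (min(p$x_nodes) > 0 || max(p$x_nodes) < L_old)
      stop("entropy_age_delta: profile '", p$label,
           "' does not cover [0, ", format(L_old), "]", call. = FALSE)
  }
  xs <- sort(unique(c(0, L_old,
                      S_old$x_nodes[S_old$x_nodes <= L_old],
                      S_young$x_nodes[S_young$x_nodes <= L_old])))
  xs <- xs[xs >= 0 & xs <= L_old]
  d <- stats::approx(S_old$x_nodes, S_old$S, xs)$y -
    stats::approx(S_young$x_nodes, S_young$S, xs)$y
  sum(diff(xs) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Structural distribution state on the lifetime scale
#'
#' Container for a coarse "structural" distribution
#' \eqn{f_T(t_T, x_T, e_T)} — the density of tissue elements binned over
#' slow time, coordinate and energy — together with its equilibrium
#' counterpart \eqn{f_{MT}} and the degradation timescale \eqn{T}. The
#' energy axis is carried as a passive binning dimension; relaxation
#' dynamics over the structural state reuse the kinetic operators
#' ([relax_uniform()], [solve_stationary_bgk()] run with
#' `relaxation_time = T`).
#'
#' @param values non-negative array of \eqn{f_T} over
#'   (time bin, coordinate bin, energy bin).
#' @param equilibrium array of \eqn{f_{MT}}, same shape.
#' @param T degradation timescale, > 0.
#' @return Object of class `structural_state`.
#' @export
structural_state <- function(values, equilibrium, T) {
  values <- as.array(values); equilibrium <- as.array(equilibrium)
  if (!identical(dim(values), dim(equilibrium)))
    stop("structural_state: value arrays must share bin shape", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("structural_state: values must be finite and non-negative",
         call. = FALSE)
  if (!is.numeric(T) || T <= 0)
    stop("structural_state: T must be > 0", call. = FALSE)
  structure(list(values = values, equilibrium = equilibrium, T = T),
            class = "structural_state")
}
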