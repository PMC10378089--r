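#' Configuration of the epithelial aging simulation
#'
#' The simulation abstracts aging skin as a row of independent
#' compartments ("cell columns"), each subject to two processes on widely
#' separated timescales: a fast chaotic one — many metabolic acts that
#' perturb the local cell density multiplicatively — and a slow systematic
#' one, the thinning of the tissue with age.
#'
#' The defaults define the reference study conditions: 40 compartments,
#' relative metabolic fluctuation 0.1 per step, absolute thinning 0.002
#' per step with a slow step every iteration, 500 iterations, snapshots
#' every 10 iterations. The fast/slow separation of real tissue (of order
#' \eqn{N = T/\tau \sim 3\times10^7} metabolic times per lifetime) is
#' represented at desk scale by the small per-step thinning rate;
#' `slow_every` lets the separation be widened explicitly.
#'
#' @param n_compartments number of compartments, >= 1.
#' @param n_iterations number of fast iterations, >= 1.
#' @param noise_amplitude relative metabolic fluctuation per step, in
#'   `[0, 1)`.
#' @param thinning_rate mean density lost per slow step, >= 0.
#' @param slow_every fast steps per slow (thinning) step, >= 1.
#' @param snapshot_every record a snapshot every this many iterations.
#' @param floor positive lower clamp on densities.
#' @param seed integer RNG seed.
#' @param kl_base log base of the divergence series.
#' @param kl_mode `"normalized"` (default; non-negative, shape-sensitive)
#'   or `"raw"` divergence (see [kl_divergence()]).
#' @return Object of class `aging_sim_config`.
#' @export
aging_sim_config <- function(n_compartments = 40, n_iterations = 500,
                             noise_amplitude = 0.1, thinning_rate = 0.002,
                             slow_every = 1, snapshot_every = 10,
                             floor = 1e-12, seed = 1,
                             kl_base = 10, kl_mode = c("normalized", "raw")) {
  kl_mode <- match.arg(kl_mode)
  stopifnot(n_compartments >= 1, n_iterations >= 1,
            noise_amplitude >= 0, thinning_rate >= 0,
            slow_every >= 1, snapshot_every >= 1, floor > 0, kl_base > 1)
  if (noise_amplitude >= 1)
    stop("aging_sim_config: noise_amplitude must be < 1 ",
         "(multiplicative factors must stay positive)", call. = FALSE)
  structure(list(n_compartments = as.integer(n_compartments),
                 n_iterations = as.integer(n_iterations),
                 noise_amplitude = noise_amplitude,
                 thinning_rate = thinning_rate,
                 slow_every = as.integer(slow_every),
                 snapshot_every = as.integer(snapshot_every),
                 floor = floor, seed = as.integer(seed),
                 kl_base = kl_base, kl_mode = kl_mode),
            class = "aging_sim_config")
}

#' Smooth young-age density profile
#'
#' The initial, smooth "young" density over the compartments: constant 1
#' by default, optionally with a gentle cosine modulation (relative
#' amplitude at most 0.05) for a less featureless baseline.
#'
#' @param config an [aging_sim_config].
#' @param cosine_amplitude relative modulation amplitude in `[0, 0.05]`;
#'   0 gives the flat profile.
#' @return A [density_profile] labelled `"young"`.
#' @export
init_young_profile <- function(config, cosine_amplitude = 0) {
  stopifnot(inherits(config, "aging_sim_config"))
  if (cosine_amplitude < 0 || cosine_amplitude > 0.05)
    stop("init_young_profile: cosine_amplitude must lie in [0, 0.05]",
         call. = FALSE)
  n <- config$n_compartments
  v <- rep(1, n)
  if (cosine_amplitude > 0 && n > 1)
    v <- 1 + cosine_amplitude * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  density_profile(seq_len(n), v, label = "young", floor = config$floor)
}

#' One fast metabolic fluctuation step
#'
#' Each compartment's density is independently multiplied by
#' \eqn{1 + \epsilon}, \eqn{\epsilon \sim U(-a, +a)}, then clamped at the
#' profile floor. The factors have mean 1, so each value is unchanged in
#' expectation: metabolism roughens the profile without draining it.
#' Draws come from R's global RNG stream; seed it (or run through
#' [simulate_epithelium()], which does) for reproducibility.
#'
#' @param q a [density_profile].
#' @param noise_amplitude relative fluctuation amplitude `a`, in `[0, 1)`.
#' @return The perturbed [density_profile].
#' @export
metabolic_step <- function(q, noise_amplitude) {
  stopifnot(inherits(q, "density_profile"))
  if (noise_amplitude < 0)
    stop("metabolic_step: amplitude must be >= 0", call. = FALSE)
  if (noise_amplitude >= 1)
    stop("metabolic_step: amplitude must be < 1 ",
         "(factors must stay positive)", call. = FALSE)
  if (noise_amplitude == 0) return(q)
  eps <- stats::runif(length(q$values), -noise_amplitude, noise_amplitude)
  q$values <- pmax(q$values * (1 + eps), q$floor)
  q
}

#' One slow thinning step
#'
#' Subtracts an absolute decrement from every compartment, clamped at the
#' floor: the systematic loss of cell-column height with age. The mean
#' density strictly decreases whenever any compartment sits above the
#' floor and the rate is positive.
#'
#' @param q a [density_profile].
#' @param thinning_rate absolute decrement, >= 0.
#' @return The thinned [density_profile].
#' @export
thinning_step <- function(q, thinning_rate) {
  stopifnot(inherits(q, "density_profile"))
  if (thinning_rate < 0)
    stop("thinning_step: rate must be >= 0", call. = FALSE)
  q$values <- pmax(q$values - thinning_rate, q$floor)
  q
}

#' Run the compartment aging simulation
#'
#' Starting from the smooth young profile, applies [metabolic_step()]
#' every iteration and [thinning_step()] every `slow_every` iterations,
#' recording density snapshots and the Kullback-Leibler divergence of
#' each snapshot against the young baseline, together with the derived
#' age trajectory \eqn{|D_t - 1|}. Fully reproducible from the config
#' seed.
#'
#' @param config an [aging_sim_config].
#' @return Object of class `sim_trajectory`: a list with `baseline` (the
#'   young [density_profile]), `snapshots` (list of profiles),
#'   `iterations` (iteration index of each snapshot, starting at 0),
#'   `kl_series`, `dev_series`, `seed`, `config`.
#' @examples
#' traj <- simulate_epithelium(aging_sim_config(n_iterations = 50, seed = 7))
#' plot(traj$iterations, traj$dev_series, type = "l",
#'      xlab = "iteration", ylab = "|D - 1|")
#' @export
simulate_epithelium <- function(config = aging_sim_config()) {
  stopifnot(inherits(config, "aging_sim_config"))
  set.seed(config$seed)
  baseline <- init_young_profile(config)
  q <- baseline
  rec_at <- unique(c(0L, seq.int(config$snapshot_every, config$n_iterations,
                                 by = config$snapshot_every),
                     config$n_iterations))
  snapshots <- vector("list", length(rec_at))
  snapshots[[1L]] <- baseline
  k <- 2L
  for (t in seq_len(config$n_iterations)) {
    q <- metabolic_step(q, config$noise_amplitude)
    if (t %% config$slow_every == 0L)
      q <- thinning_step(q, config$thinning_rate)
    if (k <= length(rec_at) && t == rec_at[k]) {
      snap <- q
      snap$label <- sprintf("iteration %d", t)
      snapshots[[k]] <- snap
      k <- k + 1L
    }
  }
  kl <- vapply(snapshots, function(s)
    suppressWarnings(kl_divergence(baseline, s, base = config$kl_base,
                                   mode = config$kl_mode)),
    numeric(1))
  structure(list(baseline = baseline, snapshots = snapshots,
                 iterations = rec_at, kl_series = kl,
                 dev_series = deviation_from_unity(kl),
                 seed = config$seed, config = config),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf(paste0("sim_trajectory: %d compartments, %d iterations, ",
                     "%d snapshots\n  final KL (base %g, %s) = %.4g, ",
                     "final |D - 1| = %.4g\n"),
              x$config$n_compartments, x$config$n_iterations,
              length(x$snapshots), x$config$kl_base, x$config$kl_mode,
              x$kl_series[length(x$kl_series)],
              x$dev_series[length(x$dev_series)]))
  invisible(x)
}

#' Schematic young/old entropy-versus-depth profiles
#'
#' Generates the textbook picture of entropy across the epidermis for two
#' ages: entropy rises from a basal-layer baseline toward a common
#' maximum at the surface (a dead, fully disordered cell), the old tissue
#' is thinner (\eqn{L_{old} < L_{young}}), starts from a higher baseline,
#' and fluctuates more. Noise is additive, uniform in amplitude, and
#' seeded; the old profile is clipped from below by the young one on
#' their common support so the age ordering holds pointwise.
#'
#' This is an illustrative generator of the qualitative picture, not a
#' model of measured epidermal entropy.
#'
#' @param L_young,L_old tissue thicknesses, `L_old < L_young`.
#' @param base_young,base_old basal-layer entropy baselines,
#'   `base_old > base_young`.
#' @param fluct_young,fluct_old additive noise amplitudes,
#'   `fluct_old >= fluct_young >= 0`.
#' @param S_max common surface entropy (the dead-cell maximum),
#'   greater than both baselines.
#' @param n nodes per profile.
#' @param shape exponent of the monotone rise `(x/L)^shape`.
#' @param seed integer RNG seed.
#' @return A list with [entropy_profile]s `young` and `old`.
#' @export
generate_entropy_schematic <- function(L_young = 1, L_old = 0.8,
                                       base_young = 0.2, base_old = 0.5,
                                       fluct_young = 0.02, fluct_old = 0.08,
                                       S_max = 1, n = 100, shape = 2,
                                       seed = 1) {
  if (L_old >= L_young)
    stop("generate_entropy_schematic: need L_old < L_young", call. = FALSE)
  if (base_old <= base_young)
    stop("generate_entropy_schematic: need base_old > base_young", call. = FALSE)
  if (fluct_young < 0 || fluct_old < fluct_young)
    stop("generate_entropy_schematic: need fluct_old >= fluct_young >= 0",
         call. = FALSE)
  if (S_max <= base_old)
    stop("generate_entropy_schematic: S_max must exceed both baselines",
         call. = FALSE)
  set.seed(seed)
  curve <- function(L, base, fluct, label) {
    x <- seq(0, L, length.out = n)
    S <- base + (S_max - base) * (x / L)^shape
    if (fluct > 0) S <- S + stats::runif(n, -fluct, fluct)
    entropy_profile(x, S, L = L, label = label)
  }
  young <- curve(L_young, base_young, fluct_young, "young")
  old <- curve(L_old, base_old, fluct_old, "old")
  # enforce the age ordering on the common support [0, L_old]
  y_at_old <- stats::approx(young$x_nodes, young$S, old$x_nodes)$y
  old$S <- pmax(old$S, y_at_old)
  list(young = young, old = old)
}
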