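#' Compartment density profile
#'
#' A `density_profile` holds the spatial density of cells over an ordered
#' set of compartments: the object compared by [kl_divergence()] when a
#' "young" baseline profile is held against an "old", roughened one.
#'
#' Densities may legitimately reach zero locally (hollows and wrinkles in a
#' tissue surface), which would break ratio-based divergences; values are
#' therefore clamped from below at a small positive `floor` before any
#' logarithm is taken.
#'
#' @param positions numeric vector of compartment coordinates, strictly
#'   increasing, or a character vector of labels (kept as given).
#' @param values numeric vector of non-negative densities, same length as
#'   `positions`.
#' @param label free-text tag, e.g. `"young"` or `"old"`.
#' @param floor small positive constant; values below it are raised to it.
#' @return An object of class `density_profile`: a list with elements
#'   `positions`, `values` (floor-clamped), `label` and `floor`.
#' @examples
#' young <- density_profile(1:5, rep(1, 5), label = "young")
#' old   <- density_profile(1:5, c(1, 0.4, 0.9, 0.2, 0.7), label = "old")
#' kl_divergence(young, old)
#' @export
density_profile <- function(positions, values, label = "", floor = 1e-12) {
  if (length(values) < 1L)
    stop("density_profile: need at least one compartment", call. = FALSE)
  if (length(positions) != length(values))
    stop("density_profile: positions and values differ in length", call. = FALSE)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("density_profile: values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("density_profile: negative density at compartment ",
         which(values < 0)[1L], call. = FALSE)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("density_profile: floor must be a single positive number", call. = FALSE)
  if (is.numeric(positions)) {
    positions <- as.numeric(positions)
    if (length(positions) > 1L && any(diff(positions) <= 0))
      stop("density_profile: numeric positions must be strictly increasing",
           call. = FALSE)
  }
  if (any(values < floor)) {
    warning("density_profile: ", sum(values < floor),
            " value(s) clamped at floor ", format(floor))
    values <- pmax(values, floor)
  }
  structure(list(positions = positions, values = values,
                 label = as.character(label)[1L], floor = floor),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile '%s': %d compartments, mean density %.4g\n",
              x$label, length(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.density_profile <- function(x) length(x$values)

# Accept either a density_profile or a bare numeric vector of densities.
as_density_values <- function(p) {
  if (inherits(p, "density_profile")) p$values
  else if (is.numeric(p)) as.numeric(p)
  else stop("expected a density_profile or a numeric vector", call. = FALSE)
}

#' Occupation-count vector
#'
#' Non-negative integer occupation numbers \eqn{n_i} over cells, the input
#' of [combinatorial_entropy()].
#'
#' @param counts vector of non-negative integers.
#' @return Object of class `count_vector` with elements `counts` and
#'   `total` (\eqn{N = \sum n_i}).
#' @export
count_vector <- function(counts) {
  if (length(counts) < 1L)
    stop("count_vector: empty count vector", call. = FALSE)
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("count_vector: counts must be non-negative integers", call. = FALSE)
  structure(list(counts = counts, total = sum(counts)), class = "count_vector")
}

#' Discrete statistical entropy
#'
#' Shannon/Boltzmann entropy of a discrete distribution,
#' \deqn{H = -\sum_i p_i \log_b p_i,}
#' with the convention \eqn{0 \log 0 = 0}. A regular, concentrated
#' distribution (e.g. a sinus heart rhythm) has lower entropy than an
#' irregular, chaotic one; entropy is maximal (\eqn{\log_b n}) for the
#' uniform distribution over \eqn{n} states.
#'
#' @param p a [density_profile] or numeric vector of non-negative weights.
#' @param base logarithm base, > 1. Default `exp(1)` (nats).
#' @param normalize if `TRUE` (default) `p` is rescaled to sum to one;
#'   if `FALSE`, `p` must already sum to 1 within `1e-9`.
#' @return Entropy in log-`base` units, a single number in
#'   \eqn{[0, \log_b n]} for a normalized length-\eqn{n} input.
#' @examples
#' discrete_entropy(rep(0.25, 4), base = 2)  # 2 bits
#' discrete_entropy(c(1, 0, 0))              # 0
#' @export
discrete_entropy <- function(p, base = exp(1), normalize = TRUE) {
  v <- as_density_values(p)
  check_log_base(base)
  if (any(v < 0))
    stop("discrete_entropy: invalid distribution (negative entry)", call. = FALSE)
  s <- sum(v)
  if (s <= 0)
    stop("discrete_entropy: invalid distribution (all entries zero)", call. = FALSE)
  if (normalize) {
    v <- v / s
  } else if (abs(s - 1) > 1e-9) {
    stop("discrete_entropy: input sums to ", format(s),
         ", not 1 (use normalize = TRUE)", call. = FALSE)
  }
  nz <- v > 0
  -sum(v[nz] * log(v[nz], base = base))
}

#' Kullback-Leibler divergence between two density profiles
#'
#' Relative entropy of a reference ("young") profile `p` against a later
#' ("old") profile `q`:
#' \deqn{D(p \| q) = \sum_{x} p(x) \log_b \frac{p(x)}{q(x)}.}
#'
#' Two evaluation modes are provided because the divergence can be read
#' either over probabilities or over raw densities:
#' \describe{
#'   \item{`"normalized"`}{both profiles are rescaled to sum to one before
#'     the sum is taken; the result is then \eqn{\ge 0}, and zero exactly
#'     when the normalized profiles coincide (Gibbs' inequality).}
#'   \item{`"raw"`}{the literal sum over unnormalized densities; it may be
#'     negative, and it is the reading under which a single density ratio
#'     of \eqn{10^9} contributes \eqn{\log_{10} = 9} to the divergence —
#'     the order-of-magnitude scale of lifetime degradation in mammals.}
#' }
#'
#' The default base is 10, matching that order-of-magnitude usage; any
#' base > 1 may be requested. `q` values are clamped at the profile floor
#' before the ratio is formed (with a warning), so surface hollows of zero
#' density do not produce infinities.
#'
#' @param p,q [density_profile]s (or numeric vectors) of equal length;
#'   `p` is the baseline, `q` the comparison profile.
#' @param base logarithm base, > 1; default 10.
#' @param mode `"normalized"` (default) or `"raw"`.
#' @param floor clamping floor applied to bare numeric inputs; profiles
#'   carry their own.
#' @return The divergence, a single number (in log-`base` units).
#' @examples
#' kl_divergence(c(0.7, 0.3), c(0.5, 0.5), base = 2)
#' kl_divergence(1, 1e-9, mode = "raw")   # 9: nine orders of magnitude
#' @export
kl_divergence <- function(p, q, base = 10,
                          mode = c("normalized", "raw"), floor = 1e-12) {
  mode <- match.arg(mode)
  check_log_base(base)
  pv <- as_density_values(p)
  qv <- as_density_values(q)
  if (length(pv) != length(qv))
    stop("kl_divergence: profiles differ in length (", length(pv), " vs ",
         length(qv), ")", call. = FALSE)
  qfloor <- if (inherits(q, "density_profile")) q$floor else floor
  bad <- qv <= 0 & pv > 0
  if (any(bad))
    stop("kl_divergence: q is zero where p > 0 at compartment ",
         which(bad)[1L], call. = FALSE)
  if (any(qv < qfloor)) {
    warning("kl_divergence: ", sum(qv < qfloor),
            " q value(s) clamped at floor ", format(qfloor))
    qv <- pmax(qv, qfloor)
  }
  if (mode == "normalized") {
    if (sum(pv) <= 0 || sum(qv) <= 0)
      stop("kl_divergence: cannot normalize an all-zero profile", call. = FALSE)
    pv <- pv / sum(pv)
    qv <- qv / sum(qv)
  }
  nz <- pv > 0
  sum(pv[nz] * log(pv[nz] / qv[nz], base = base))
}

#' Combinatorial (multiplicity) entropy
#'
#' Natural logarithm of the multinomial multiplicity
#' \eqn{W = N! / \prod_i n_i!} of a set of occupation numbers — the number
#' of microscopic arrangements consistent with the given macroscopic
#' occupation. Computed through `lgamma`, so large \eqn{N} does not
#' overflow. \eqn{\ln W = 0} when all items sit in one cell (full
#' cooperative order) and is maximal for equal occupation; its growth
#' tracks the loss of cooperative connection between parts of a system.
#'
#' @param c a [count_vector] or vector of non-negative integer counts.
#' @return \eqn{\ln W}, in natural-log units.
#' @examples
#' combinatorial_entropy(c(5, 0, 0))  # 0
#' combinatorial_entropy(c(2, 2))     # log(6)
#' @export
combinatorial_entropy <- function(c) {
  if (!inherits(c, "count_vector")) c <- count_vector(c)
  if (c$total < 1)
    stop("combinatorial_entropy: total count must be at least 1", call. = FALSE)
  lgamma(c$total + 1) - sum(lgamma(c$counts + 1))
}

#' Absolute deviation of a divergence series from unity
#'
#' Elementwise \eqn{|D_t - 1|} of a Kullback-Leibler series — the
#' trajectory statistic whose growth over iterations marks progressive
#' tissue aging in the compartment simulation.
#'
#' @param series numeric vector of divergence values.
#' @return Numeric vector of the same length, \eqn{|D_t - 1|}.
#' @export
deviation_from_unity <- function(series) {
  if (length(series) < 1L)
    stop("deviation_from_unity: empty series", call. = FALSE)
  abs(as.numeric(series) - 1)
}

check_log_base <- function(base) {
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base) || base <= 1)
    stop("log base must be a single number > 1", call. = FALSE)
  invisible(base)
}
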