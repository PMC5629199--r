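#' Two-dimensional model potential of Gaussian wells
#'
#' Builds a rugged 2-D energy surface as a sum of attractive Gaussian wells,
#' \eqn{U(x) = -\sum_w A_w \exp(-|x - c_w|^2 / 2\sigma_w^2) +
#' \kappa |x - c_0|^2 / 2}, with an optional harmonic confinement term. A
#' designated start well and target well define the benchmark transition.
#'
#' @param wells Data frame with columns `x`, `y`, `depth` (well depth, > 0,
#'   energy units) and `width` (length units, > 0).
#' @param confinement List with `x`, `y`, `kappa` (set `kappa = 0` to
#'   disable).
#' @param start_well,target_well Row indices into `wells`.
#' @param target_radius Hit radius around the target well's center.
#' @return A `potential2d` object.
#' @export
potential2d <- function(wells, confinement = list(x = 0, y = 0, kappa = 0),
                        start_well = 1L, target_well = 2L,
                        target_radius = 1) {
  stopifnot(all(c("x", "y", "depth", "width") %in% names(wells)),
            all(wells$width > 0), start_well != target_well)
  structure(list(wells = as.data.frame(wells), confinement = confinement,
                 start_well = as.integer(start_well),
                 target_well = as.integer(target_well),
                 target_radius = target_radius),
            class = "potential2d")
}

#' Default rugged two-deep-well benchmark surface
#'
#' A chain of six deep metastable wells (12 kT, width 0.6) along the
#' diagonal from (10, 10) to the origin, a jittered 4x4 lattice of shallow
#' wells (about 1-1.5 kT, width 0.8) for off-path ruggedness, and a weak
#' harmonic confinement (kappa = 0.1) centred at (5, 5). The benchmark
#' transition runs from the top-right well to the origin well (hit radius
#' 1): inter-well barriers of roughly 9-11 kT make a full unguided
#' traversal take far longer than a single 300,000-step trajectory, while
#' the metastable stepping stones let adaptive reseeding ratchet along the
#' chain one escape at a time. The endpoint wells are one kT deeper (12 kT)
#' than the intermediates (11 kT). Deterministic for a fixed seed.
#'
#' @param seed Seed for the shallow-well jitter.
#' @return A `potential2d`.
#' @export
default_potential <- function(seed = 2026L) {
  jit <- with_seed(seed, list(
    dx = stats::runif(16, -0.6, 0.6), dy = stats::runif(16, -0.6, 0.6),
    depth = stats::runif(16, 1, 1.5)))
  grid <- expand.grid(x = c(2, 4, 6, 8), y = c(2, 4, 6, 8))
  shallow <- data.frame(x = grid$x + jit$dx, y = grid$y + jit$dy,
                        depth = jit$depth, width = 0.8)
  chain <- data.frame(x = c(10, 0, 2, 4, 6, 8), y = c(10, 0, 2, 4, 6, 8),
                      depth = c(12, 12, 11, 11, 11, 11), width = 0.6)
  potential2d(rbind(chain, shallow),
              confinement = list(x = 5, y = 5, kappa = 0.1),
              start_well = 1L, target_well = 2L, target_radius = 1)
}

#' Evaluate a 2-D potential and its analytic gradient
#'
#' @param p A `potential2d`.
#' @param x Numeric 2-vector.
#' @return List with `energy` and `gradient` (2-vector).
#' @export
potential_eval <- function(p, x) {
  stopifnot(length(x) == 2L, all(is.finite(x)))
  w <- p$wells
  dx <- x[1L] - w$x; dy <- x[2L] - w$y
  e <- w$depth * exp(-(dx^2 + dy^2) / (2 * w$width^2))
  energy <- -sum(e)
  grad <- c(sum(e * dx / w$width^2), sum(e * dy / w$width^2))
  k <- p$confinement$kappa
  if (k > 0) {
    cx <- x - c(p$confinement$x, p$confinement$y)
    energy <- energy + 0.5 * k * sum(cx^2)
    grad <- grad + k * cx
  }
  list(energy = energy, gradient = grad)
}

#' Integrator parameters for overdamped Brownian dynamics
#'
#' @param D Diffusion coefficient (length^2 / time); `D = 0` gives the
#'   degenerate noiseless, driftless particle (constant trajectory).
#' @param dt Timestep (time).
#' @param kT Thermal energy (energy units of the potential).
#' @param steps Steps per trajectory.
#' @param seed Integer RNG seed.
#' @return A `brownian_params` list.
#' @export
brownian_params <- function(D = 1, dt = 0.01, kT = 1, steps = 300000L,
                            seed = 1L) {
  stopifnot(D >= 0, dt > 0, kT > 0, steps >= 1)
  structure(list(D = D, dt = dt, kT = kT, steps = as.integer(steps),
                 seed = as.integer(seed)),
            class = "brownian_params")
}

wells_matrix <- function(p)
  as.matrix(p$wells[, c("x", "y", "depth", "width")])

conf_vector <- function(p)
  c(p$confinement$x, p$confinement$y, p$confinement$kappa)

#' Integrate a Brownian trajectory by Euler-Maruyama
#'
#' \eqn{x_{t+1} = x_t - (D \Delta t / kT)\,\nabla U(x_t) +
#' \sqrt{2 D \Delta t}\,\xi_t} with standard 2-D Gaussian noise. The
#' trajectory is deterministic for a fixed seed. Integration aborts with an
#' instability error if the particle leaves a generous guard box
#' (|coordinate| > 1000 times the domain scale), which indicates a timestep
#' too large for the surface.
#'
#' @param p A `potential2d`.
#' @param bp A [brownian_params()].
#' @param x0 Start position (default: the start well's center).
#' @param stop_at_target Truncate the trajectory at the first frame inside
#'   the target radius.
#' @param thin Store every `thin`-th frame (hit detection still runs every
#'   step).
#' @return A `brownian_trajectory`: `traj` ((stored frames) x 2 matrix),
#'   `hit_step` (integration step of first target entry, NA if never), `bp`.
#' @export
simulate_brownian <- function(p, bp, x0 = NULL, stop_at_target = FALSE,
                              thin = 1L) {
  if (is.null(x0))
    x0 <- as.numeric(p$wells[p$start_well, c("x", "y")])
  tgt <- c(as.numeric(p$wells[p$target_well, c("x", "y")]),
           p$target_radius)
  domain <- max(1, max(abs(wells_matrix(p)[, 1:2])))
  res <- with_seed(bp$seed,
    brownian_run_cpp(wells_matrix(p), conf_vector(p), bp$D, bp$dt, bp$kT,
                     bp$steps, as.numeric(x0), tgt, stop_at_target,
                     as.integer(thin), 1000 * domain))
  structure(list(traj = res$traj,
                 hit_step = if (res$hit_step < 0) NA_integer_
                            else res$hit_step,
                 bp = bp),
            class = "brownian_trajectory")
}

#' Read a potential definition from a YAML config
#'
#' Expected keys: `wells` (list of `{x, y, depth, width}`), optional
#' `confinement` (`{x, y, kappa}`), `start_well`, `target_well`,
#' `target_radius`.
#'
#' @param path Path to a YAML file.
#' @return A `potential2d`.
#' @export
read_potential <- function(path) {
  cfg <- yaml::read_yaml(path)
  wells <- do.call(rbind, lapply(cfg$wells, as.data.frame))
  conf <- if (is.null(cfg$confinement)) list(x = 0, y = 0, kappa = 0)
          else cfg$confinement
  potential2d(wells, confinement = conf,
              start_well = if (is.null(cfg$start_well)) 1L else cfg$start_well,
              target_well = if (is.null(cfg$target_well)) 2L
                            else cfg$target_well,
              target_radius = if (is.null(cfg$target_radius)) 1
                              else cfg$target_radius)
}
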