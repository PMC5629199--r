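#' Single kinetic Monte Carlo transition
#'
#' Applies the cumulative-sum rule to one row of a transition matrix: with
#' running sums \eqn{S_n = \sum_{j \le n} p_{ij}}, a uniform variate
#' \eqn{u \in [S_n, S_{n+1})} selects state \eqn{n+1} (1-based here; the
#' first state with positive probability is selected when u = 0).
#'
#' @param tmat Row-stochastic transition matrix.
#' @param state Current state (1-based).
#' @param u Uniform variate in `[0, 1)`.
#' @return Next state (1-based).
#' @export
kmc_step <- function(tmat, state, u) {
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)")
  row <- tmat[state, ]
  if (abs(sum(row) - 1) > 1e-9)
    stop("matrix error: row ", state, " sums to ", sum(row),
         ", not 1 within 1e-9")
  s <- cumsum(row)
  j <- which(u < s)[1L]
  if (is.na(j)) j <- length(row)
  j
}

## Deterministic per-trajectory substream seed: a fixed multiplicative hash
## of (seed, index) so ensembles are reproducible and order-independent.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483563) + 1L
}

#' Kinetic Monte Carlo trajectory ensemble
#'
#' Generates `n_traj` independent state-to-state trajectories from a
#' transition matrix. Each trajectory uses its own RNG substream derived
#' from `seed` and the trajectory index, so the ensemble is reproducible
#' and independent of launch order. With a stop set, trajectories truncate
#' on first entry and the summary reports first-passage statistics in units
#' of the lag time tau (frames).
#'
#' @param tmat Row-stochastic transition matrix.
#' @param start Start state (1-based).
#' @param n_traj Number of trajectories.
#' @param n_steps Maximum steps per trajectory.
#' @param stop_set Optional integer vector of absorbing target states.
#' @param seed Integer seed.
#' @return A `kmc_ensemble` list: `trajectories` (list of 1-based state
#'   vectors), `hit_times` (frames to stop-set entry, NA when not reached)
#'   and `summary` (hit fraction, mean/median hit time).
#' @export
kmc_ensemble <- function(tmat, start, n_traj, n_steps, stop_set = NULL,
                         seed = 1L) {
  stopifnot(n_traj >= 1, n_steps >= 1)
  check_stochastic(tmat)
  if (!is.null(stop_set) && start %in% stop_set)
    stop("degenerate input: start state is in the stop set")
  stop0 <- if (is.null(stop_set)) integer(0) else as.integer(stop_set) - 1L
  trajs <- vector("list", n_traj)
  hit <- rep(NA_real_, n_traj)
  for (t in seq_len(n_traj)) {
    states <- with_seed(derive_seed(seed, t),
                        kmc_run_cpp(tmat, start - 1L, n_steps, stop0)) + 1L
    trajs[[t]] <- states
    if (length(stop0) > 0L && states[length(states)] %in% stop_set)
      hit[t] <- length(states) - 1L
  }
  frac <- mean(!is.na(hit))
  structure(list(
    trajectories = trajs, hit_times = hit, start = start,
    stop_set = stop_set, seed = seed,
    summary = list(hit_fraction = frac,
                   mean_hit_time = if (frac > 0) mean(hit, na.rm = TRUE)
                                   else NA_real_,
                   median_hit_time = if (frac > 0)
                     stats::median(hit, na.rm = TRUE) else NA_real_)),
    class = "kmc_ensemble")
}

#' @export
print.kmc_ensemble <- function(x, ...) {
  cat("kmc_ensemble:", length(x$trajectories), "trajectories from state",
      x$start, "\n")
  if (!is.null(x$stop_set))
    cat("  hit fraction ", x$summary$hit_fraction,
        ", mean first-passage ", x$summary$mean_hit_time, " tau\n", sep = "")
  invisible(x)
}

#' Analytic mean first-passage times to an absorbing set
#'
#' Fundamental-matrix solution: with Q the transition matrix restricted to
#' the transient states, the expected steps to absorption solve
#' `(I - Q) m = 1`.
#'
#' @param tmat Row-stochastic transition matrix.
#' @param stop_set Target (absorbing) states, 1-based.
#' @return Named vector of expected hitting times (frames) for every
#'   transient state.
#' @export
mfpt_analytic <- function(tmat, stop_set) {
  trans <- setdiff(seq_len(nrow(tmat)), stop_set)
  q <- tmat[trans, trans, drop = FALSE]
  m <- solve(diag(length(trans)) - q, rep(1, length(trans)))
  stats::setNames(m, trans)
}

check_stochastic <- function(tmat, tol = 1e-9) {
  if (!is.matrix(tmat) || nrow(tmat) != ncol(tmat))
    stop("transition matrix must be square")
  if (any(tmat < -tol) || any(tmat > 1 + tol))
    stop("transition probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(tmat) - 1) > tol)
  if (length(bad) > 0L)
    stop("matrix error: row(s) ", paste(bad, collapse = ", "),
         " do not sum to 1 within ", tol)
  invisible(TRUE)
}
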