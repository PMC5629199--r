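#' Configuration of an adaptive sampling run
#'
#' @param n_traj Number N of parallel trajectories per round.
#' @param traj_len Length S of each trajectory (lag units or integration
#'   steps, the sampler's native time unit).
#' @param n_rounds Number R of sampling rounds.
#' @param k Number of clusters used for seed selection.
#' @param strategy One of `"random"`, `"lowest_count"`, `"max_score"`,
#'   `"min_score"`, `"min_target_distance"`.
#' @param seed Integer seed; all round, trajectory and clustering streams
#'   derive from it.
#' @param pool `"cumulative"` clusters all frames sampled so far (default),
#'   `"round"` only the last round's frames.
#' @param frame_filter Optional predicate `function(frames) -> logical`
#'   marking frames to keep for clustering (e.g. excluding frames whose
#'   inter-monomer center-of-mass distance exceeds 50 Angstrom); filtered
#'   frames still count toward simulation time.
#' @return An `adaptive_config` list.
#' @export
adaptive_config <- function(n_traj = 10L, traj_len = 50L, n_rounds = 30L,
                            k = 10L, strategy = "min_score", seed = 1L,
                            pool = c("cumulative", "round"),
                            frame_filter = NULL) {
  stopifnot(n_traj >= 1, traj_len >= 1, n_rounds >= 1, k >= 1)
  strategy <- match.arg(strategy, c("random", "lowest_count", "max_score",
                                    "min_score", "min_target_distance"))
  structure(list(n_traj = as.integer(n_traj), traj_len = as.integer(traj_len),
                 n_rounds = as.integer(n_rounds), k = as.integer(k),
                 strategy = strategy, seed = as.integer(seed),
                 pool = match.arg(pool), frame_filter = frame_filter),
            class = "adaptive_config")
}

#' Seed selection from clustered frames
#'
#' Implements the reseeding criteria: `max_score` / `min_score` pick one
#' random member from each of the n_seeds best-scoring clusters
#' (`min_target_distance` is `min_score` applied to a distance-to-target
#' score); `lowest_count` picks from the n_seeds least populated clusters;
#' `random` draws clusters uniformly without replacement. Ties are broken
#' by cluster index. If fewer clusters than seeds exist, clusters are drawn
#' with replacement after a warning. Uses the caller's RNG stream.
#'
#' @param cluster_members List mapping cluster -> integer vector of member
#'   frame indices.
#' @param strategy Strategy name (see [adaptive_config()]).
#' @param n_seeds Number of seeds to return.
#' @param scores Per-cluster guidance score (score strategies).
#' @param counts Per-cluster population (default: member counts).
#' @return Integer vector of selected frame indices (one per chosen
#'   cluster).
#' @export
select_seeds <- function(cluster_members, strategy, n_seeds,
                         scores = NULL, counts = NULL) {
  nc <- length(cluster_members)
  if (nc == 0L) stop("no clusters to select from")
  if (is.null(counts))
    counts <- vapply(cluster_members, length, integer(1L))
  order_idx <- switch(strategy,
    random = sample.int(nc),
    lowest_count = order(counts, seq_len(nc)),
    max_score = {
      if (is.null(scores)) stop("max_score strategy needs cluster scores")
      order(-scores, seq_len(nc))
    },
    min_score = ,
    min_target_distance = {
      if (is.null(scores)) stop(strategy, " strategy needs cluster scores")
      order(scores, seq_len(nc))
    },
    stop("unknown strategy: ", strategy))
  if (n_seeds > nc) {
    warning("fewer clusters (", nc, ") than seeds (", n_seeds,
            "); sampling clusters with replacement")
    chosen <- c(order_idx, sample.int(nc, n_seeds - nc, replace = TRUE))
  } else {
    chosen <- order_idx[seq_len(n_seeds)]
  }
  vapply(chosen, function(cl) {
    mem <- cluster_members[[cl]]
    mem[sample.int(length(mem), 1L)]
  }, numeric(1L))
}

#' Run an adaptive sampling experiment
#'
#' The engine behind every protocol comparison: each round launches
#' `n_traj` trajectories of length `traj_len` from the current seeds using
#' the sampler adapter, tests the target at every generated frame, pools
#' the frames sampled so far, clusters them into `k` microstates and
#' applies the seeding strategy to pick the next round's start points. The
#' run stops at the first target hit (first-passage semantics) or after
#' `n_rounds` rounds.
#'
#' Total simulation time is accounted as (fully completed trajectories x
#' traj_len) + the hitting trajectory's frames up to and including the hit.
#'
#' @param sampler A sampler adapter, e.g. [msm_sampler()] or
#'   [brownian_sampler()].
#' @param cfg An [adaptive_config()].
#' @return An `adaptive_result`: `hit` (logical), `hit_round`, `hit_traj`,
#'   `total_time`, `budget` (n_traj x traj_len x n_rounds), `rounds` (per
#'   round: seeds used and mean guidance score), `history` (per-round list
#'   of point sequences, e.g. discrete trajectories for an MSM sampler).
#' @export
adaptive_run <- function(sampler, cfg) {
  N <- cfg$n_traj; S <- cfg$traj_len; R <- cfg$n_rounds
  seeds <- rep(list(sampler$start), N)
  pool_frames <- NULL; pool_scores <- numeric(0); pool_points <- list()
  history <- vector("list", R)
  rounds <- list()
  completed <- 0
  for (r in seq_len(R)) {
    round_traj <- vector("list", N)
    round_start_idx <- length(pool_points) + 1L
    for (t in seq_len(N)) {
      res <- sampler$run(seeds[[t]], S, derive_seed(cfg$seed,
                                                    (r - 1L) * N + t))
      round_traj[[t]] <- res$points
      if (!is.na(res$hit_time)) {
        history[[r]] <- round_traj[seq_len(t)]
        return(structure(list(
          hit = TRUE, hit_round = r, hit_traj = t,
          total_time = completed * S + res$hit_time,
          budget = as.numeric(N) * S * R,
          rounds = rounds, history = history[seq_len(r)], cfg = cfg),
          class = "adaptive_result"))
      }
      completed <- completed + 1
      pool_frames <- rbind(pool_frames, res$frames)
      pool_scores <- c(pool_scores, res$scores)
      pool_points <- c(pool_points, res$points)
    }
    history[[r]] <- round_traj
    if (r == R) break
    if (cfg$pool == "round") {
      idx <- round_start_idx:length(pool_points)
      frames <- pool_frames[idx, , drop = FALSE]
      scores <- pool_scores[idx]
      points <- pool_points[idx]
    } else {
      frames <- pool_frames; scores <- pool_scores; points <- pool_points
    }
    if (!is.null(cfg$frame_filter)) {
      keep <- cfg$frame_filter(frames)
      if (sum(keep) >= 1L) {
        frames <- frames[keep, , drop = FALSE]
        scores <- scores[keep]
        points <- points[keep]
      }
    }
    k_eff <- min(cfg$k, nrow(unique(frames)))
    cl <- cluster_kmeans(frames, k_eff,
                         seed = derive_seed(cfg$seed, 1000000L + r),
                         iter_max = 30L)
    members <- split(seq_along(cl$labels), factor(cl$labels,
                                                  levels = seq_len(k_eff)))
    members <- members[vapply(members, length, integer(1L)) > 0L]
    cl_scores <- vapply(members, function(m) mean(scores[m]), numeric(1L))
    cl_counts <- vapply(members, length, integer(1L))
    sel <- with_seed(derive_seed(cfg$seed, 2000000L + r),
                     select_seeds(members, cfg$strategy, N,
                                  scores = cl_scores, counts = cl_counts))
    seeds <- lapply(sel, function(i) points[[i]])
    rounds[[r]] <- list(round = r, n_frames_pooled = nrow(frames),
                        mean_score = mean(scores),
                        best_score = if (sampler$score_direction == "min")
                          min(cl_scores) else max(cl_scores))
  }
  structure(list(hit = FALSE, hit_round = NA_integer_,
                 hit_traj = NA_integer_,
                 total_time = as.numeric(N) * S * R,
                 budget = as.numeric(N) * S * R,
                 rounds = rounds, history = history, cfg = cfg),
            class = "adaptive_result")
}

#' @export
print.adaptive_result <- function(x, ...) {
  if (x$hit)
    cat("adaptive_result: target hit in round", x$hit_round,
        "(trajectory", x$hit_traj, ") after total time", x$total_time, "\n")
  else
    cat("adaptive_result: target not reached within budget",
        x$budget, "\n")
  invisible(x)
}

#' Sampler adapter over a Markov state model
#'
#' Wraps kinetic Monte Carlo on a transition matrix as a sampler for
#' [adaptive_run()]. Frames are the per-state values of `feature` (a
#' clustering coordinate); guidance scores are the per-state values of
#' `score` (a delta-SEC-like quantity or a distance-to-target proxy).
#'
#' @param tmat Row-stochastic transition matrix.
#' @param start Start state (1-based).
#' @param target_states Target state set (1-based).
#' @param score Per-state guidance score.
#' @param feature Per-state clustering coordinate (default: the score).
#' @param score_direction `"min"` if low scores indicate proximity to the
#'   target, `"max"` otherwise.
#' @return A sampler adapter list.
#' @export
msm_sampler <- function(tmat, start, target_states, score,
                        feature = score, score_direction = "min") {
  check_stochastic(tmat)
  feature <- as.numeric(feature); score <- as.numeric(score)
  target0 <- as.integer(target_states) - 1L
  list(
    start = as.integer(start),
    score_direction = score_direction,
    run = function(seed_point, len, stream_seed) {
      if (as.integer(seed_point) %in% target_states)
        return(list(frames = matrix(feature[seed_point], ncol = 1L),
                    scores = score[seed_point],
                    points = list(as.integer(seed_point)),
                    hit_time = 0))
      states <- with_seed(stream_seed,
                          kmc_run_cpp(tmat, as.integer(seed_point) - 1L,
                                      len, target0)) + 1L
      hit <- states[length(states)] %in% target_states
      list(frames = matrix(feature[states], ncol = 1L),
           scores = score[states],
           points = as.list(states),
           hit_time = if (hit) length(states) - 1L else NA_real_)
    })
}

#' Sampler adapter over 2-D Brownian dynamics
#'
#' Wraps the Euler-Maruyama integrator as a sampler for [adaptive_run()].
#' Frames are particle positions stored every `thin` steps (the target test
#' still runs at every integration step); the guidance score is the
#' distance to the target well's center, so guided runs use the
#' `min_target_distance` strategy.
#'
#' @param p A `potential2d`.
#' @param bp Base [brownian_params()] (its `steps` and `seed` are
#'   overridden per call).
#' @param thin Frame-storage stride.
#' @return A sampler adapter list.
#' @export
brownian_sampler <- function(p, bp = brownian_params(), thin = 10L) {
  tgt <- as.numeric(p$wells[p$target_well, c("x", "y")])
  list(
    start = as.numeric(p$wells[p$start_well, c("x", "y")]),
    score_direction = "min",
    run = function(seed_point, len, stream_seed) {
      bp2 <- brownian_params(D = bp$D, dt = bp$dt, kT = bp$kT,
                             steps = len, seed = stream_seed)
      tr <- simulate_brownian(p, bp2, x0 = seed_point,
                              stop_at_target = TRUE, thin = thin)
      frames <- tr$traj
      list(frames = frames,
           scores = sqrt((frames[, 1L] - tgt[1L])^2 +
                           (frames[, 2L] - tgt[2L])^2),
           points = lapply(seq_len(nrow(frames)),
                           function(i) frames[i, ]),
           hit_time = if (is.na(tr$hit_step)) NA_real_
                      else as.numeric(tr$hit_step))
    })
}

#' First-passage-time grid over protocol parameters
#'
#' Reproduces the sampling-strategy comparison experiments: for every cell
#' of a (trajectory length S, count) grid it measures the total simulation
#' time to first reach the target, under one of three protocols. `serial`
#' runs `count` independent trajectories of length S with no reseeding;
#' `random_adaptive` and `guided_adaptive` run `n_traj` parallel
#' trajectories for `count` rounds of length S, reseeding randomly or by
#' the sampler's guidance score. Each cell reports the median total time
#' over `replicates` independent repeats, with non-reached runs entering
#' the median as the sentinel `Inf`.
#'
#' @param sampler A sampler adapter.
#' @param protocol `"serial"`, `"random_adaptive"` or `"guided_adaptive"`.
#' @param S_values Trajectory lengths.
#' @param count_values Trajectory counts (serial) or round counts
#'   (adaptive).
#' @param replicates Repeats per cell.
#' @param seed Integer seed.
#' @param n_traj Parallel trajectories per adaptive round.
#' @param k Clusters for adaptive reseeding.
#' @param frame_filter Passed to [adaptive_config()].
#' @return An `fpt_grid` data frame: `S`, `count`, `median_total_time`,
#'   `hit_fraction`, `replicates`.
#' @export
fpt_grid <- function(sampler, protocol = c("serial", "random_adaptive",
                                           "guided_adaptive"),
                     S_values, count_values, replicates = 3L, seed = 1L,
                     n_traj = 10L, k = 100L, frame_filter = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(length(S_values) > 0L, length(count_values) > 0L)
  rows <- list()
  cell_id <- 0L
  for (S in S_values) for (cnt in count_values) {
    cell_id <- cell_id + 1L
    times <- vapply(seq_len(replicates), function(rep) {
      run_protocol(sampler, protocol, S, cnt,
                   seed = derive_seed(seed, cell_id * 10000L + rep),
                   n_traj = n_traj, k = k,
                   frame_filter = frame_filter)$total_time_or_inf
    }, numeric(1L))
    rows[[cell_id]] <- data.frame(
      S = S, count = cnt,
      median_total_time = stats::median(times),
      hit_fraction = mean(is.finite(times)),
      replicates = replicates)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fpt_grid", class(out))
  out
}

## Dispatch one protocol realization; returns the adaptive_result plus the
## sentinel-coded total time.
run_protocol <- function(sampler, protocol, S, count, seed, n_traj = 10L,
                         k = 100L, frame_filter = NULL) {
  cfg <- switch(protocol,
    serial = adaptive_config(n_traj = count, traj_len = S, n_rounds = 1L,
                             k = 1L, strategy = "random", seed = seed),
    random_adaptive = adaptive_config(n_traj = n_traj, traj_len = S,
                                      n_rounds = count, k = k,
                                      strategy = "random", seed = seed,
                                      frame_filter = frame_filter),
    guided_adaptive = adaptive_config(
      n_traj = n_traj, traj_len = S, n_rounds = count, k = k,
      strategy = if (sampler$score_direction == "min") "min_score"
                 else "max_score",
      seed = seed, frame_filter = frame_filter))
  res <- adaptive_run(sampler, cfg)
  res$total_time_or_inf <- if (res$hit) res$total_time else Inf
  res
}

#' Paired strategy comparison on one system
#'
#' Runs the serial, random-adaptive and guided-adaptive protocols
#' `replicates` times each under paired seeds (replicate r of every
#' protocol shares a seed base) with equal total sampling budgets, and
#' summarizes median total time to target per strategy together with a
#' sign test of guided vs serial.
#'
#' @param sampler A sampler adapter.
#' @param S Trajectory length per round.
#' @param n_rounds Rounds for the adaptive protocols; the serial protocol
#'   gets the same budget as n_traj trajectories of length S x n_rounds.
#' @param n_traj Parallel trajectories.
#' @param k Clusters. Keep `k` larger than `n_traj`: when every cluster
#'   receives a seed, the seeding strategies become indistinguishable.
#' @param replicates Paired replicates.
#' @param seed Integer seed.
#' @return A `strategy_comparison`: per-strategy total-time vectors,
#'   medians, hit fractions, and `sign_test_p` (one-sided, guided < serial).
#' @export
compare_strategies <- function(sampler, S = 50L, n_rounds = 30L,
                               n_traj = 10L, k = 25L, replicates = 20L,
                               seed = 1L) {
  protos <- c("serial", "random_adaptive", "guided_adaptive")
  times <- sapply(protos, function(p) {
    vapply(seq_len(replicates), function(rep) {
      # serial spends the same budget in n_traj unbroken trajectories
      if (p == "serial")
        run_protocol(sampler, p, S * n_rounds, n_traj,
                     seed = derive_seed(seed, rep))$total_time_or_inf
      else
        run_protocol(sampler, p, S, n_rounds,
                     seed = derive_seed(seed, rep),
                     n_traj = n_traj, k = k)$total_time_or_inf
    }, numeric(1L))
  })
  colnames(times) <- protos
  gu <- times[, "guided_adaptive"]; se <- times[, "serial"]
  wins <- sum(gu < se); ties <- sum(gu == se)
  n_eff <- replicates - ties
  p_sign <- if (n_eff == 0L) 1
            else stats::pbinom(wins - 1L, n_eff, 0.5, lower.tail = FALSE)
  structure(list(
    times = times,
    medians = apply(times, 2L, stats::median),
    hit_fractions = apply(times, 2L, function(x) mean(is.finite(x))),
    sign_test_p = p_sign, replicates = replicates),
    class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("strategy_comparison over", x$replicates, "paired replicates\n")
  cat("  median total time:",
      paste(names(x$medians), signif(x$medians, 4L), collapse = ", "),
      "\n")
  cat("  hit fractions:",
      paste(names(x$hit_fractions), x$hit_fractions, collapse = ", "), "\n")
  cat("  sign test guided < serial: p =", signif(x$sign_test_p, 3L), "\n")
  invisible(x)
}

#' Center-of-mass distance frame filter
#'
#' Returns a frame-filter predicate excluding frames whose inter-monomer
#' center-of-mass distance (a designated feature column) exceeds a cutoff,
#' the rule used when clustering association trajectories (default cutoff
#' 50 Angstrom).
#'
#' @param cutoff Distance cutoff.
#' @param column Feature column holding the COM distance; `NULL` means the
#'   Euclidean norm over all feature columns.
#' @return A predicate `function(frames) -> logical`.
#' @export
com_distance_filter <- function(cutoff = 50, column = NULL) {
  function(frames) {
    d <- if (is.null(column)) sqrt(rowSums(frames^2))
         else frames[, column]
    d <= cutoff
  }
}
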