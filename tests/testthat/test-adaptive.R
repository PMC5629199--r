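test_that("seed selection follows each strategy's ordering", {
  members <- list(c(1L, 2L), c(3L, 4L, 5L), c(6L))
  scores <- c(1.0, 2.0, 3.0)
  counts <- c(7L, 2L, 5L)

  set.seed(1)
  top2 <- select_seeds(members, "max_score", 2L, scores = scores)
  expect_true(top2[1L] %in% members[[3L]])  # best-scoring cluster first
  expect_true(top2[2L] %in% members[[2L]])

  set.seed(1)
  low1 <- select_seeds(members, "lowest_count", 1L, counts = counts)
  expect_true(low1 %in% members[[2L]])

  set.seed(1)
  min1 <- select_seeds(members, "min_score", 1L, scores = scores)
  expect_true(min1 %in% members[[1L]])

  r1 <- ecsampler:::with_seed(5L, select_seeds(members, "random", 2L))
  r2 <- ecsampler:::with_seed(5L, select_seeds(members, "random", 2L))
  expect_identical(r1, r2)

  set.seed(2)
  expect_warning(sel <- select_seeds(members, "random", 5L),
                 "with replacement")
  expect_length(sel, 5L)
  expect_error(select_seeds(members, "max_score", 1L), "needs cluster")
})

test_that("degenerate adaptive runs terminate as contracted", {
  gl <- generate_guided_landscape(20L, seed = 2L)
  sam_hit <- msm_sampler(gl$model$tmat, start = gl$target,
                         target_states = gl$target, score = gl$score)
  # start in the target: hit in round 1 with zero extra time
  expect_error(adaptive_run(sam_hit, adaptive_config(seed = 1L)), NA)
  res0 <- adaptive_run(sam_hit, adaptive_config(n_traj = 2L, traj_len = 5L,
                                                n_rounds = 2L, seed = 1L))
  expect_true(res0$hit)
  expect_equal(res0$hit_round, 1L)
  expect_equal(res0$total_time, 0)

  # identity dynamics never reach the target: budget sentinel
  frozen <- msm_sampler(diag(20L), start = 1L, target_states = 20L,
                        score = gl$score)
  res1 <- suppressWarnings(
    adaptive_run(frozen, adaptive_config(n_traj = 3L, traj_len = 10L,
                                         n_rounds = 4L, k = 2L, seed = 1L)))
  expect_false(res1$hit)
  expect_equal(res1$total_time, 3 * 10 * 4)
  expect_equal(res1$budget, 120)
})

test_that("time accounting decomposes into completed plus partial work", {
  fx <- generate_msm(funnel_chain_spec(n_states = 25L, barrier = 3))
  sam <- msm_sampler(fx$model$tmat, start = fx$spec$start,
                     target_states = fx$spec$target, score = fx$coordinate,
                     feature = fx$coordinate)
  res <- suppressWarnings(
    adaptive_run(sam, adaptive_config(n_traj = 5L, traj_len = 40L,
                                      n_rounds = 60L, k = 5L,
                                      strategy = "min_score", seed = 12L)))
  expect_true(res$hit)
  completed <- (res$hit_round - 1L) * 5L + (res$hit_traj - 1L)
  partial <- res$total_time - completed * 40L
  expect_gte(partial, 0)
  expect_lte(partial, 40L)
  # the hitting trajectory really ends in the target
  last_traj <- res$history[[res$hit_round]][[res$hit_traj]]
  expect_equal(last_traj[[length(last_traj)]], fx$spec$target)
})

test_that("determinism: identical seeds give identical runs", {
  gl <- generate_guided_landscape(25L, seed = 5L)
  sam <- msm_sampler(gl$model$tmat, start = gl$start,
                     target_states = gl$target, score = gl$score)
  cfg <- adaptive_config(n_traj = 4L, traj_len = 25L, n_rounds = 10L,
                         k = 4L, strategy = "min_score", seed = 99L)
  r1 <- suppressWarnings(adaptive_run(sam, cfg))
  r2 <- suppressWarnings(adaptive_run(sam, cfg))
  expect_identical(r1$total_time, r2$total_time)
  expect_identical(r1$history, r2$history)
})

test_that("guidance beats random seeding on the funnel fixture", {
  gl <- generate_guided_landscape(40L, seed = 8L)
  sam <- msm_sampler(gl$model$tmat, start = gl$start,
                     target_states = gl$target, score = gl$score,
                     feature = gl$coordinate)
  times <- suppressWarnings(sapply(1:10, function(rep) {
    g <- ecsampler:::run_protocol(sam, "guided_adaptive", 40L, 25L,
                                  seed = rep, n_traj = 8L, k = 20L)
    r <- ecsampler:::run_protocol(sam, "random_adaptive", 40L, 25L,
                                  seed = rep, n_traj = 8L, k = 20L)
    c(g$total_time_or_inf, r$total_time_or_inf)
  }))
  expect_lte(stats::median(times[1L, ]), stats::median(times[2L, ]))
})

test_that("MSMs built from adaptive rounds remove the seeding bias", {
  fx <- generate_msm(funnel_chain_spec(n_states = 10L, barrier = 1.5))
  sam <- msm_sampler(fx$model$tmat, start = 1L,
                     target_states = integer(0),  # free exploration
                     score = fx$coordinate, feature = fx$coordinate)
  res <- suppressWarnings(
    adaptive_run(sam, adaptive_config(n_traj = 8L, traj_len = 250L,
                                      n_rounds = 20L, k = 6L,
                                      strategy = "lowest_count",
                                      seed = 42L)))
  expect_false(res$hit)
  dtrajs <- lapply(unlist(res$history, recursive = FALSE),
                   function(tr) unlist(tr))
  m <- estimate_reversible(count_and_trim(dtrajs, lag = 1L))
  expect_equal(length(m$pi), 10L)
  expect_lt(max(abs(m$pi - fx$model$pi)), 0.05)
  expect_lt(max(abs(m$tmat - fx$model$tmat)), 0.1)
})

test_that("the fpt grid accounts hits and sentinels per cell", {
  # two-state chain that always leaves the start: hit at the first step
  flip <- matrix(c(0, 1, 0, 1), 2L, byrow = TRUE)
  sam <- msm_sampler(flip, start = 1L, target_states = 2L, score = c(1, 0))
  grid <- fpt_grid(sam, "serial", S_values = c(1L, 3L),
                   count_values = c(2L, 4L), replicates = 2L, seed = 1L)
  expect_s3_class(grid, "fpt_grid")
  expect_equal(nrow(grid), 4L)
  expect_true(all(grid$hit_fraction == 1))
  # first trajectory hits after one step: no completed trajectories before
  expect_true(all(grid$median_total_time == 1))

  # an unreachable target leaves the sentinel in every cell
  frozen <- msm_sampler(diag(2L), start = 1L, target_states = 2L,
                        score = c(1, 0))
  grid2 <- suppressWarnings(
    fpt_grid(frozen, "serial", S_values = 2L, count_values = 2L,
             replicates = 2L, seed = 1L))
  expect_true(all(is.infinite(grid2$median_total_time)))
  expect_true(all(grid2$hit_fraction == 0))
})

test_that("the frame filter excludes far frames from clustering only", {
  filt <- com_distance_filter(cutoff = 50)
  frames <- matrix(c(10, 0, 60, 0, 30, 40), ncol = 2L, byrow = TRUE)
  expect_equal(filt(frames), c(TRUE, FALSE, TRUE))
  filt2 <- com_distance_filter(cutoff = 5, column = 1L)
  expect_equal(filt2(frames), c(FALSE, FALSE, FALSE))
})
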