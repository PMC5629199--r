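test_that("k-means clustering is deterministic and separates blobs", {
  set.seed(1)
  blob1 <- matrix(stats::rnorm(60, 0, 0.1), ncol = 1L)
  blob2 <- matrix(stats::rnorm(60, 10, 0.1), ncol = 1L)
  x <- rbind(blob1, blob2)
  cl <- cluster_kmeans(x, 2L, seed = 4L)
  expect_length(unique(cl$labels[1:60]), 1L)
  expect_length(unique(cl$labels[61:120]), 1L)
  expect_false(cl$labels[1L] == cl$labels[61L])

  cl2 <- cluster_kmeans(x, 2L, seed = 4L)
  expect_identical(cl$labels, cl2$labels)

  pts <- matrix(c(0, 5, 9), ncol = 1L)
  cl3 <- cluster_kmeans(pts, 3L, seed = 1L)
  expect_length(unique(cl3$labels), 3L)  # zero within-cluster variance

  expect_error(cluster_kmeans(pts, 10L), "cardinality")
})

test_that("sliding-window counting and ergodic trimming are exact", {
  # states 0,0,1,1,0 in 0-based notation
  cm <- count_and_trim(c(1L, 1L, 2L, 2L, 1L), lag = 1L)
  expect_equal(cm$counts, matrix(c(1, 1, 1, 1), 2L, 2L))
  expect_equal(cm$active_set, 1:2)

  # absorbing never-exited state falls out of the active set
  cm2 <- count_and_trim(c(1L, 2L, 3L), lag = 1L)
  expect_false(3L %in% cm2$active_set)

  expect_error(count_and_trim(c(1L, 2L, 1L), lag = 3L), "lag")

  # total sliding counts = len - lag per trajectory
  set.seed(2)
  d <- sample(1:3, 50, TRUE)
  cm3 <- count_and_trim(list(d, d), lag = 5L)
  expect_lte(sum(cm3$counts), 2 * (50 - 5))
})

test_that("reversible MLE reproduces symmetric-count closed form", {
  m <- estimate_reversible(matrix(c(2, 1, 1, 2), 2L, 2L))
  expect_equal(m$tmat, matrix(c(2, 1, 1, 2) / 3, 2L, 2L), tolerance = 1e-10)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-10)
  expect_error(estimate_reversible(diag(c(3, 4))), "connected")
})

test_that("reversible MLE satisfies detailed balance and beats naive estimates", {
  loglik <- function(tmat, C) sum(C[C > 0] * log(tmat[C > 0]))
  for (seed in 1:4) {
    set.seed(seed)
    C <- matrix(stats::rpois(16, 5), 4L, 4L) + 1
    m <- estimate_reversible(C)
    db <- outer(m$pi, rep(1, 4)) * m$tmat
    expect_lt(max(abs(db - t(db))), 1e-10)
    expect_equal(rowSums(m$tmat), rep(1, 4), tolerance = 1e-12)
    # likelihood no worse than row-normalizing the symmetrized counts
    naive <- (C + t(C)) / 2
    naive <- naive / rowSums(naive)
    expect_gte(loglik(m$tmat, C), loglik(naive, C) - 1e-9)
  }
})

test_that("stationary distributions solve pi T = pi", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2L, 2L, byrow = TRUE)
  expect_equal(stationary_distribution(T2), c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  # doubly stochastic -> uniform
  T3 <- matrix(c(0.5, 0.3, 0.2, 0.2, 0.5, 0.3, 0.3, 0.2, 0.5), 3L,
               byrow = TRUE)
  expect_equal(stationary_distribution(T3), rep(1 / 3, 3L),
               tolerance = 1e-12)

  # eigensolve agrees with power iteration
  m <- random_reversible_tmat(5L, seed = 8L)
  p <- rep(1 / 5, 5L)
  for (i in 1:2000) p <- propagate(p, m$tmat, 1L)
  expect_equal(stationary_distribution(m$tmat), p, tolerance = 1e-10)

  expect_error(stationary_distribution(diag(2)), "reducible")
})

test_that("implied timescales follow -tau / log(lambda)", {
  # two-state chain, off-diagonals 0.1 and 0.2: lambda_2 = 0.7
  C <- matrix(c(900, 100, 200, 800), 2L, byrow = TRUE)
  m <- estimate_reversible(C)
  expect_equal(m$tmat, matrix(c(0.9, 0.1, 0.2, 0.8), 2L, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(m$timescales[1L], -1 / log(0.7), tolerance = 1e-9)

  # slower chains have longer timescales (identity limit grows)
  slow <- estimate_reversible(matrix(c(990, 10, 20, 980), 2L, byrow = TRUE))
  expect_gt(slow$timescales[1L], m$timescales[1L])

  # recovery from simulated trajectories of a known chain
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2L, byrow = TRUE)
  ens <- kmc_ensemble(T2, 1L, n_traj = 4L, n_steps = 50000L, seed = 31L)
  its <- implied_timescales(ens$trajectories, lags = c(1L, 2L),
                            n_timescales = 1L)
  expect_equal(its["1", 1L], -1 / log(0.7), tolerance = 0.1)
  expect_equal(its["2", 1L], -2 / log(0.7^2), tolerance = 0.1)
})

test_that("stepwise propagation equals the matrix-power form", {
  m <- random_reversible_tmat(4L, seed = 5L)
  p0 <- c(1, 0, 0, 0)
  tk <- diag(4L)
  for (i in 1:7) tk <- tk %*% m$tmat
  expect_equal(propagate(p0, m$tmat, 7L), as.numeric(p0 %*% tk),
               tolerance = 1e-14)
})

test_that("tICA finds the slow coordinate and ignores rotations", {
  set.seed(12)
  n <- 4000L
  slow <- as.numeric(stats::arima.sim(list(ar = 0.99), n))
  fast <- stats::rnorm(n)
  x <- cbind(slow, fast)
  tp <- tica_project(x, lag = 10L, n_components = 2L)
  v <- attr(tp, "components")[, 1L]
  cosine <- abs(v[1L]) / sqrt(sum(v^2))
  expect_gt(cosine, 0.99)

  th <- 0.5
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  tp_rot <- tica_project(x %*% rot, lag = 10L, n_components = 2L)
  expect_equal(attr(tp, "eigenvalues"), attr(tp_rot, "eigenvalues"),
               tolerance = 1e-8)

  expect_error(tica_project(x, lag = 10L, n_components = 5L), "exceeds")
  expect_error(tica_project(x[1:5, ], lag = 10L), "lag")
})

test_that("Chapman-Kolmogorov holds on simulated funnel trajectories", {
  fx <- generate_msm(funnel_chain_spec(n_states = 3L, barrier = 1))
  ens <- kmc_ensemble(fx$model$tmat, 1L, n_traj = 4L, n_steps = 30000L,
                      seed = 77L)
  t1 <- estimate_reversible(count_and_trim(ens$trajectories, 1L))
  t2 <- estimate_reversible(count_and_trim(ens$trajectories, 2L))
  prop <- t1$tmat %*% t1$tmat
  expect_equal(prop, t2$tmat, tolerance = 0.05)
})

test_that("discrete trajectories round-trip through the text format", {
  path <- tempfile()
  writeLines(c("0 0 1 2 1", "1 1 0"), path)
  d <- read_dtrajs(path, base = 0L)
  expect_equal(d[[1L]], c(1L, 1L, 2L, 3L, 2L))
  expect_equal(d[[2L]], c(2L, 2L, 1L))
})
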