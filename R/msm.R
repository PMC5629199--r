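#' k-means clustering with deterministic k-means++ seeding
#'
#' Clusters feature frames into k microstates. Initial centers are chosen
#' by the k-means++ rule under the given seed, refined by Lloyd iterations,
#' and every frame is finally assigned to its nearest center with ties
#' broken toward the lowest center index, so labels are fully reproducible.
#'
#' @param features Frames x d numeric matrix (or a `feature_trajectory`).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations.
#' @return List with `labels` (1-based per frame) and `centers` (k x d).
#' @export
cluster_kmeans <- function(features, k, seed = 1L, iter_max = 100L) {
  if (inherits(features, "feature_trajectory")) features <- features$data
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) stop("cardinality error: k = ", k, " exceeds ", n, " frames")
  centers <- with_seed(seed, kmeanspp_init(features, k))
  if (k > 1L && nrow(unique(centers)) == k) {
    fit <- suppressWarnings(stats::kmeans(features, centers = centers,
                                          iter.max = iter_max,
                                          algorithm = "Lloyd"))
    centers <- fit$centers
  }
  d2 <- sq_dist(features, centers)
  labels <- max.col(-d2, ties.method = "first")
  list(labels = labels, centers = centers)
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (c in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[c] <- sample.int(n, 1L, prob = p)
      d2c <- rowSums((x - matrix(x[idx[c], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, d2c)
    }
  }
  x[idx, , drop = FALSE]
}

sq_dist <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

#' Count transitions at a lag time and trim to the ergodic core
#'
#' Sliding-window transition counts: every frame t with t + lag inside the
#' trajectory contributes one count from state(t) to state(t + lag). The
#' count graph is then restricted to its largest strongly connected
#' component (the active set), which makes maximum-likelihood estimation
#' well posed.
#'
#' @param dtrajs A 1-based integer vector or list of such vectors.
#' @param lag Lag time in frames (>= 1, shorter than every trajectory).
#' @param n_states Optional total number of states (default: max label).
#' @return A `count_model`: `counts` (restricted count matrix),
#'   `active_set` (original 1-based labels of the retained states), `lag`.
#' @export
count_and_trim <- function(dtrajs, lag = 1L, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lens <- vapply(dtrajs, length, integer(1L))
  if (lag < 1L || any(lag >= lens))
    stop("lag error: lag must satisfy 1 <= lag < length of every trajectory")
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, numeric(1L)))
  C <- matrix(0, n_states, n_states)
  for (d in dtrajs) {
    from <- d[seq_len(length(d) - lag)]
    to <- d[(lag + 1L):length(d)]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # largest SCC among states with any counts; ties -> lowest member index
  sizes <- tabulate(comp$membership, comp$no)
  seen <- which(rowSums(C) + colSums(C) > 0)
  cand <- unique(comp$membership[seen])
  best <- cand[order(-sizes[cand],
                     vapply(cand, function(m)
                       min(which(comp$membership == m)), numeric(1L)))][1L]
  active <- unname(which(comp$membership == best))
  counts <- C[active, active, drop = FALSE]
  dimnames(counts) <- NULL
  structure(list(counts = counts,
                 active_set = active, lag = as.integer(lag),
                 mode = "sliding"),
            class = "count_model")
}

#' Reversible maximum-likelihood transition matrix
#'
#' Estimates the transition matrix maximizing the trajectory likelihood
#' under the detailed-balance constraint pi_i T_ij = pi_j T_ji, by the
#' standard fixed-point iteration on the unnormalized symmetric flux
#' x_ij = (c_ij + c_ji) / (c_i / x_i + c_j / x_j). Converged when the
#' stationary distribution changes by less than `tol` between sweeps.
#'
#' @param cm A `count_model` from [count_and_trim()], or a raw count matrix
#'   already restricted to a connected state set.
#' @param tol Convergence tolerance on pi (default 1e-10).
#' @param max_iter Iteration cap.
#' @return An `msmodel`: `tmat` (row-stochastic), `pi` (stationary
#'   distribution), `lag`, `active_set`, `timescales` (implied timescales
#'   at this lag).
#' @export
estimate_reversible <- function(cm, tol = 1e-10, max_iter = 1e6) {
  if (inherits(cm, "count_model")) {
    C <- cm$counts; lag <- cm$lag; active <- cm$active_set
  } else {
    C <- as.matrix(cm); lag <- 1L; active <- seq_len(nrow(C))
  }
  n <- nrow(C)
  if (n < 2L) stop("need at least 2 connected states")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("count matrix is not restricted to a connected active set")
  cs <- C + t(C)
  ci <- rowSums(C)
  x <- cs / sum(cs)                      # initial symmetric estimate
  xi <- rowSums(x)
  pi_old <- xi / sum(xi)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- outer(ci / xi, ci / xi, "+")
    x <- cs / denom
    x[cs == 0] <- 0
    xi <- rowSums(x)
    pi_new <- xi / sum(xi)
    if (max(abs(pi_new - pi_old)) < tol) { converged <- TRUE; break }
    pi_old <- pi_new
  }
  if (!converged)
    stop("reversible estimation did not converge; residual ",
         format(max(abs(pi_new - pi_old))))
  tmat <- x / xi
  pi <- pi_new
  new_msmodel(tmat, pi, lag, active)
}

new_msmodel <- function(tmat, pi, lag, active_set) {
  stopifnot(max(abs(rowSums(tmat) - 1)) < 1e-12)
  ts <- timescales_from_tmat(tmat, pi, lag)
  structure(list(tmat = tmat, pi = pi, lag = lag, active_set = active_set,
                 timescales = ts),
            class = "msmodel")
}

#' @export
print.msmodel <- function(x, ...) {
  cat("msmodel:", nrow(x$tmat), "states, lag", x$lag, "frames\n")
  cat("  slowest implied timescales:",
      paste(signif(utils::head(x$timescales, 3L), 4L), collapse = ", "),
      "\n")
  invisible(x)
}

## Eigenvalues of a reversible T via the symmetric conjugate
## D^{1/2} T D^{-1/2}; real by construction.
reversible_eigen <- function(tmat, pi) {
  s <- sqrt(pi)
  sym <- tmat * outer(s, 1 / s)         # S_ij = s_i T_ij / s_j
  eigen((sym + t(sym)) / 2, symmetric = TRUE)
}

timescales_from_tmat <- function(tmat, pi, lag) {
  ev <- sort(reversible_eigen(tmat, pi)$values, decreasing = TRUE)
  ev <- ev[-1L]                          # drop the stationary eigenvalue
  ts <- rep(NA_real_, length(ev))
  ok <- ev > 0 & ev < 1
  ts[ok] <- -lag / log(ev[ok])
  ts
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of eigenvalue 1, normalized to sum 1.
#'
#' @param tmat Row-stochastic, irreducible transition matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(tmat) {
  check_stochastic(tmat)
  g <- igraph::graph_from_adjacency_matrix((tmat > 0) * 1,
                                           mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("irreducibility error: transition matrix is reducible")
  e <- eigen(t(tmat))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  if (any(v < -1e-12)) stop("stationary eigenvector has negative entries")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Implied timescales across lag times
#'
#' For each lag, counts transitions, estimates the reversible transition
#' matrix and converts its eigenvalues to relaxation timescales
#' \eqn{t_i = -\tau / \ln \lambda_i}. Non-positive eigenvalues yield NA
#' (undefined process at that lag).
#'
#' @param dtrajs Discrete trajectory (vector) or list thereof.
#' @param lags Integer vector of lags (frames).
#' @param n_timescales How many of the slowest timescales to report.
#' @return Matrix lags x timescales (rows named by lag).
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 5L) {
  out <- matrix(NA_real_, length(lags), n_timescales,
                dimnames = list(lags, paste0("t", seq_len(n_timescales) + 1L)))
  for (r in seq_along(lags)) {
    m <- estimate_reversible(count_and_trim(dtrajs, lags[r]))
    ts <- m$timescales
    out[r, ] <- ts[seq_len(min(n_timescales, length(ts)))][
      seq_len(n_timescales)]
  }
  out
}

#' Propagate a state distribution k lag times forward
#'
#' Evolves a row probability vector p under the transition matrix,
#' p(t0 + k tau) = p(t0) T(tau)^k, by k successive vector-matrix products.
#'
#' @param p Initial probability row vector.
#' @param tmat Transition matrix.
#' @param k Number of lag steps.
#' @return Probability vector after k steps.
#' @export
propagate <- function(p, tmat, k) {
  p <- matrix(p, nrow = 1L)
  for (i in seq_len(k)) p <- p %*% tmat
  as.numeric(p)
}

#' Time-lagged independent component analysis (tICA)
#'
#' Finds the slowest linear collective coordinates of a feature trajectory
#' by solving the generalized eigenproblem C_tau v = lambda C_0 v, where
#' C_0 is the instantaneous covariance and C_tau the symmetrized
#' time-lagged covariance. The instantaneous covariance is regularized by
#' adding 1e-10 x trace/d to its diagonal.
#'
#' @param features Frames x d matrix, a `feature_trajectory`, or a list of
#'   such matrices (multiple trajectories).
#' @param lag Lag in frames.
#' @param n_components Number of slow components to keep.
#' @return A `feature_trajectory` with the projected coordinates plus
#'   attributes `eigenvalues` and `components` (d x n_components).
#' @export
tica_project <- function(features, lag, n_components = 2L) {
  if (inherits(features, "feature_trajectory")) features <- features$data
  blocks <- if (is.list(features)) lapply(features, as.matrix)
            else list(as.matrix(features))
  d <- ncol(blocks[[1L]])
  if (n_components > d) stop("n_components exceeds feature dimension")
  if (any(vapply(blocks, nrow, integer(1L)) <= lag))
    stop("lag must be shorter than every trajectory")
  mu <- colMeans(do.call(rbind, blocks))
  c0 <- matrix(0, d, d); ct <- matrix(0, d, d); n_pairs <- 0
  for (b in blocks) {
    x <- sweep(b, 2L, mu)
    n <- nrow(x)
    x0 <- x[seq_len(n - lag), , drop = FALSE]
    xt <- x[(lag + 1L):n, , drop = FALSE]
    c0 <- c0 + (t(x0) %*% x0 + t(xt) %*% xt) / 2
    ct <- ct + t(x0) %*% xt
    n_pairs <- n_pairs + (n - lag)
  }
  c0 <- c0 / n_pairs
  ct <- (ct + t(ct)) / (2 * n_pairs)
  eps <- 1e-10 * sum(diag(c0)) / d
  c0 <- c0 + diag(eps, d)
  # whiten with C0^{-1/2}, then ordinary symmetric eigenproblem
  e0 <- eigen(c0, symmetric = TRUE)
  if (min(e0$values) <= 0)
    stop("rank error: instantaneous covariance singular after regularization")
  w <- e0$vectors %*% diag(1 / sqrt(e0$values), d) %*% t(e0$vectors)
  es <- eigen(w %*% ct %*% w, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)[seq_len(n_components)]
  comps <- w %*% es$vectors[, ord, drop = FALSE]
  proj <- do.call(rbind, lapply(blocks,
                                function(b) sweep(b, 2L, mu) %*% comps))
  colnames(proj) <- paste0("tic", seq_len(n_components))
  out <- structure(list(data = proj, labels = colnames(proj),
                        frame_interval = 1),
                   class = "feature_trajectory")
  attr(out, "eigenvalues") <- es$values[ord]
  attr(out, "components") <- comps
  out
}

#' Read discrete trajectories from a plain-text file
#'
#' One whitespace-separated integer state sequence per line.
#'
#' @param path File path.
#' @param base Index base used in the file (0 or 1); returned trajectories
#'   are always 1-based.
#' @return List of 1-based integer vectors.
#' @export
read_dtrajs <- function(path, base = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trajectories in ", path)
  lapply(lines, function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1L]]) + (1L - as.integer(base)))
}
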