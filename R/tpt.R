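#' Forward and backward committors between two state sets
#'
#' The forward committor q+ of a state is the probability of reaching the
#' sink set B before the source set A. It solves the boundary-value linear
#' system sum_j T_ij q+_j = q+_i on intermediate states with q+ = 0 on A
#' and q+ = 1 on B. The backward committor q- solves the analogous system
#' on the time-reversed chain T~_ij = pi_j T_ji / pi_i.
#'
#' @param m An `msmodel` (or a list with `tmat` and `pi`).
#' @param A,B Disjoint, non-empty 1-based state sets.
#' @return List with `q_minus` and `q_plus` vectors over all states.
#' @export
committors <- function(m, A, B) {
  tmat <- m$tmat; pi <- m$pi
  n <- nrow(tmat)
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0L || length(B) == 0L) stop("A and B must be non-empty")
  if (length(intersect(A, B)) > 0L) stop("A and B must be disjoint")
  if (any(c(A, B) < 1L) || any(c(A, B) > n))
    stop("A and B must index states of the model")
  q_plus <- solve_committor(tmat, A, B)
  trev <- t(tmat * pi) / pi              # reversed chain rows
  q_minus <- solve_committor(trev, B, A) # reach A before B, backwards
  list(q_minus = q_minus, q_plus = q_plus)
}

solve_committor <- function(tmat, zero_set, one_set) {
  n <- nrow(tmat)
  q <- numeric(n)
  q[one_set] <- 1
  inter <- setdiff(seq_len(n), c(zero_set, one_set))
  if (length(inter) > 0L) {
    lhs <- diag(length(inter)) - tmat[inter, inter, drop = FALSE]
    rhs <- tmat[inter, one_set, drop = FALSE] %*% rep(1, length(one_set))
    sol <- tryCatch(solve(lhs, rhs),
                    error = function(e)
                      stop("connectivity error: committor system singular"))
    q[inter] <- as.numeric(sol)
  }
  pmin(pmax(q, 0), 1)
}

#' Reactive flux network between source and sink
#'
#' Gross reactive flux f_ij = pi_i q-_i T_ij q+_j (i != j); net flux
#' F_ij = max(0, f_ij - f_ji). The total net flux out of A equals the total
#' into B.
#'
#' @param m An `msmodel`.
#' @param A,B Source and sink state sets.
#' @return A `flux_network`: `gross`, `net`, `q_minus`, `q_plus`, `A`, `B`,
#'   `total_flux`.
#' @export
net_flux <- function(m, A, B) {
  qq <- committors(m, A, B)
  tmat <- m$tmat; pi <- m$pi
  f <- outer(pi * qq$q_minus, qq$q_plus) * tmat
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(net[A, setdiff(seq_len(nrow(tmat)), A), drop = FALSE])
  structure(list(gross = f, net = net, q_minus = qq$q_minus,
                 q_plus = qq$q_plus, A = A, B = B, total_flux = total),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("flux_network:", nrow(x$net), "states, total A->B net flux",
      signif(x$total_flux, 6L), "\n")
  invisible(x)
}

#' Top transition pathways by iterative widest-path decomposition
#'
#' Repeatedly finds the maximum-bottleneck (widest) path from the source to
#' the sink on the net-flux network with a Dijkstra-style max-min search,
#' records it with its bottleneck flux, subtracts that flux along the path,
#' and continues until k paths are found or the residual A->B flux drops
#' below `tol`. Ties between equal-bottleneck paths are broken by fewer
#' hops, then by lexicographic state order.
#'
#' @param fn A `flux_network`.
#' @param k Maximum number of pathways.
#' @param tol Residual-flux stopping threshold.
#' @return List of `list(path = states, flux = bottleneck)`, strongest
#'   first; empty (with a message) if A and B are not flux-connected.
#' @export
top_pathways <- function(fn, k = 5L, tol = 1e-12) {
  stopifnot(k >= 1)
  net <- fn$net
  out <- list()
  for (iter in seq_len(k)) {
    wp <- widest_path(net, fn$A, fn$B)
    if (is.null(wp) || wp$bottleneck < tol) break
    out[[length(out) + 1L]] <- list(path = wp$path, flux = wp$bottleneck)
    for (e in seq_len(length(wp$path) - 1L))
      net[wp$path[e], wp$path[e + 1L]] <-
        net[wp$path[e], wp$path[e + 1L]] - wp$bottleneck
  }
  if (length(out) == 0L) message("no net-flux connectivity from A to B")
  out
}

## Dijkstra variant maximizing the minimum edge capacity along the path.
## Ties on bottleneck width are broken by fewer hops, then by visiting
## lower-numbered states first.
widest_path <- function(cap, A, B) {
  n <- nrow(cap)
  width <- rep(-Inf, n); hops <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  width[A] <- Inf; hops[A] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & width > -Inf)
    if (length(cand) == 0L) break
    u <- cand[order(-width[cand], hops[cand], cand)][1L]
    if (u %in% B) {
      path <- u
      while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
      return(list(path = path, bottleneck = width[u]))
    }
    done[u] <- TRUE
    for (v in which(cap[u, ] > 0)) {
      if (done[v]) next
      w <- min(width[u], cap[u, v])
      if (w > width[v] ||
          (w == width[v] && hops[u] + 1 < hops[v])) {
        width[v] <- w; hops[v] <- hops[u] + 1; prev[v] <- u
      }
    }
  }
  NULL
}
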