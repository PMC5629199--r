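#' Specification of a funnel-like benchmark Markov chain
#'
#' A 1-D nearest-neighbour chain over a quartic double-well energy profile
#' E(x) = 16 B x^2 (1 - x)^2 (x the scaled state coordinate), with wells at
#' the start and target states and a barrier of height B (in kT, i.e.
#' log-probability units) between them. Transition probabilities follow the
#' Metropolis rule on this profile, so the chain is reversible by
#' construction and its stationary law is exactly the Boltzmann weight of
#' the profile.
#'
#' @param n_states Number of states (>= 3).
#' @param barrier Barrier height B in kT.
#' @param start,target Start and target states (default: the two ends).
#' @param seed Seed recorded in the spec (used by ruggedness options).
#' @return A `funnel_chain_spec` list.
#' @export
funnel_chain_spec <- function(n_states = 50L, barrier = 6,
                              start = 1L, target = n_states, seed = 1L) {
  stopifnot(n_states >= 3L, start != target)
  structure(list(n_states = as.integer(n_states), barrier = barrier,
                 start = as.integer(start), target = as.integer(target),
                 seed = as.integer(seed)),
            class = "funnel_chain_spec")
}

funnel_energy <- function(n_states, barrier) {
  x <- (seq_len(n_states) - 1) / (n_states - 1)
  16 * barrier * x^2 * (1 - x)^2
}

#' Generate a funnel-chain Markov state model with known answers
#'
#' @param spec A [funnel_chain_spec()].
#' @param ruggedness Standard deviation of optional random energy
#'   perturbations added to the profile (0 = smooth double well).
#' @return List: `model` (an `msmodel` whose stationary distribution is the
#'   exact Boltzmann law of the energy profile), `energy`, `coordinate`
#'   (a distance-to-target proxy, strictly decreasing toward the target),
#'   `spec`.
#' @export
generate_msm <- function(spec, ruggedness = 0) {
  n <- spec$n_states
  e <- funnel_energy(n, spec$barrier)
  if (ruggedness > 0)
    e <- e + with_seed(spec$seed, stats::rnorm(n, 0, ruggedness))
  tmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > n) next
      tmat[i, j] <- 0.5 * min(1, exp(-(e[j] - e[i])))
    }
    tmat[i, i] <- 1 - sum(tmat[i, ])
  }
  pi <- exp(-(e - min(e)))
  pi <- pi / sum(pi)
  coord <- abs(seq_len(n) - spec$target)
  list(model = new_msmodel(tmat, pi, 1L, seq_len(n)),
       energy = e, coordinate = coord, spec = spec)
}

#' Generate a guided-sampling landscape fixture
#'
#' A funnel chain together with a per-state guidance score that emulates a
#' delta-SEC-like reaction coordinate: a monotone transform of the distance
#' to the target plus Gaussian noise, so guidance is informative but
#' imperfect. The generator retries noise draws (derived deterministically
#' from the seed) until the score's Spearman correlation with the forward
#' committor to the target is at most -0.8, which the monotone backbone
#' guarantees to exist.
#'
#' @param n_states Number of states (>= 10).
#' @param seed Integer seed.
#' @param noise_sd Noise amplitude relative to the score range.
#' @return List: `model`, `score` (per state), `target` (state set),
#'   `start`, `committor_spearman` (achieved correlation), `coordinate`.
#' @export
generate_guided_landscape <- function(n_states = 50L, seed = 1L,
                                      noise_sd = 0.1) {
  stopifnot(n_states >= 10L)
  fx <- generate_msm(funnel_chain_spec(n_states = n_states, seed = seed))
  qq <- committors(fx$model, A = fx$spec$start, B = fx$spec$target)
  base <- fx$coordinate / max(fx$coordinate)
  for (try in 0:100) {
    noise <- if (noise_sd > 0)
      with_seed(derive_seed(seed, try), stats::rnorm(n_states, 0, noise_sd))
    else numeric(n_states)
    score <- base + noise
    rho <- stats::cor(score, qq$q_plus, method = "spearman")
    if (rho <= -0.8) break
  }
  list(model = fx$model, score = score, target = fx$spec$target,
       start = fx$spec$start, committor_spearman = rho,
       coordinate = fx$coordinate)
}

helix_chain <- function(n_res, chain, origin, cb_offset = c(0, 0, 1.5)) {
  # straight CA trace with 3.8 A spacing plus a CB pseudo side chain
  rows <- list()
  for (i in seq_len(n_res)) {
    ca <- origin + c(3.8 * (i - 1), 0, 0)
    cb <- ca + cb_offset
    rows[[length(rows) + 1L]] <- data.frame(
      elety = c("CA", "CB"), resid = "ALA", chain = chain,
      resno = c(i, i), insert = "", o = 1,
      x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

rigid_transform <- function(atom, angles, shift) {
  rx <- angles[1]; ry <- angles[2]; rz <- angles[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3)
  m <- as.matrix(atom[, c("x", "y", "z")])
  ctr <- colMeans(m)
  m2 <- sweep(sweep(m, 2L, ctr) %*% t(Rz %*% Ry %*% Rx), 2L,
              ctr + shift, "+")
  atom$x <- m2[, 1L]; atom$y <- m2[, 2L]; atom$z <- m2[, 3L]
  atom
}

#' Generate a toy two-chain complex with a consistent coupling table
#'
#' Two rigid toy chains (CA/CB only) in a native side-by-side pose, an
#' inter-chain coupling table listing residue pairs in contact in that
#' pose, and decoy poses obtained by random rigid displacement of the
#' partner chain. By construction (asserted on the output) the native pose
#' has the minimal sum of coupled-pair distances among all emitted poses.
#'
#' @param n_residues_per_chain Residues per chain (>= 3).
#' @param n_decoys Number of decoy poses.
#' @param seed Integer seed.
#' @return List: `native` (`ec_structure`, chains A and B), `decoys` (list
#'   of `ec_structure`), `couplings` (`coupling_set` of inter-chain pairs),
#'   `spec` (the [distance_spec()] used for scoring).
#' @export
generate_toy_complex <- function(n_residues_per_chain = 6L, n_decoys = 10L,
                                 seed = 1L) {
  stopifnot(n_residues_per_chain >= 3L)
  a <- helix_chain(n_residues_per_chain, "A", c(0, 0, 0))
  b <- helix_chain(n_residues_per_chain, "B", c(0, 6, 0))
  native <- new_structure(rbind(a, b), source = "toy_native")
  n_pairs <- min(5L, n_residues_per_chain)
  rec <- data.frame(chain_i = "A", residue_i = seq_len(n_pairs),
                    chain_j = "B", residue_j = seq_len(n_pairs),
                    score = seq(0.9, 0.5, length.out = n_pairs),
                    stringsAsFactors = FALSE)
  cs <- new_coupling_set(rec, selection = NULL, source = "toy_complex")
  spec <- distance_spec(mode = "CA")
  sec_native <- sum(pair_distances(native, cs, spec))
  decoys <- vector("list", n_decoys)
  for (d in seq_len(n_decoys)) {
    for (try in 0:100) {
      par <- with_seed(derive_seed(seed, d * 1000L + try), list(
        ang = stats::runif(3, -pi, pi),
        dir = stats::rnorm(3),
        mag = stats::runif(1, 10, 60)))
      shift <- par$dir / sqrt(sum(par$dir^2)) * par$mag
      cand <- new_structure(rbind(a, rigid_transform(b, par$ang, shift)),
                            source = sprintf("toy_decoy_%02d", d))
      if (sum(pair_distances(cand, cs, spec)) > sec_native) break
    }
    decoys[[d]] <- cand
  }
  list(native = native, decoys = decoys, couplings = cs, spec = spec)
}

#' Write a coupling set to CSV in the pipeline's input dialects
#'
#' @param cs A `coupling_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coupling_csv <- function(cs, path) {
  rec <- cs$records
  if (all(is.na(rec$chain_i))) {
    utils::write.csv(data.frame(i = rec$residue_i, j = rec$residue_j,
                                score = rec$score),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(chain_i = rec$chain_i, i = rec$residue_i,
                                chain_j = rec$chain_j, j = rec$residue_j,
                                score = rec$score),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write / read a transition matrix as headerless CSV
#'
#' @param tmat Row-stochastic matrix.
#' @param path CSV path.
#' @return `write_tmatrix`: `path` invisibly; `read_tmatrix`: the matrix.
#' @export
write_tmatrix <- function(tmat, path) {
  utils::write.table(tmat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_tmatrix
#' @export
read_tmatrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  check_stochastic(m)
  m
}
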