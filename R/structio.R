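#' Read a PDB structure
#'
#' Parses a PDB file (via bio3d) into a light-weight `ec_structure` object.
#' Only the first MODEL is kept. Where alternate locations exist for the
#' same atom, the highest-occupancy altloc is retained (ties: first in file
#' order).
#'
#' @param path Path to a PDB file.
#' @return An `ec_structure`: list with an `atom` data frame (`elety`,
#'   `resid`, `chain`, `resno`, `insert`, `o`, `x`, `y`, `z`, file order
#'   preserved) and the source path.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty structure: no ATOM/HETATM records in ", path)
  # keep the best altloc per atom identity
  key <- paste(at$elety, at$chain, at$resno, at$insert, at$resid)
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- rep(TRUE, nrow(at))
  for (dup_key in unique(key[duplicated(key)])) {
    rows <- which(key == dup_key)
    best <- rows[which.max(occ[rows])]
    keep[setdiff(rows, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  atom <- data.frame(elety = at$elety, resid = at$resid,
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     resno = at$resno,
                     insert = ifelse(is.na(at$insert), "", at$insert),
                     o = occ[keep],
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  rownames(atom) <- NULL
  new_structure(atom, source = path)
}

new_structure <- function(atom, source = "") {
  stopifnot(all(is.finite(atom$x)), all(is.finite(atom$y)),
            all(is.finite(atom$z)))
  structure(list(atom = atom, source = source), class = "ec_structure")
}

#' @export
print.ec_structure <- function(x, ...) {
  cat("ec_structure:", nrow(x$atom), "atoms,",
      length(unique(paste(x$atom$chain, x$atom$resno, x$atom$insert))),
      "residues, chains:",
      paste(unique(x$atom$chain), collapse = " "), "\n")
  invisible(x)
}

#' Write an `ec_structure` to a PDB file
#'
#' @param s An `ec_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(s, path) {
  a <- s$atom
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
    a[, c("x", "y", "z")]))), resno = a$resno, resid = a$resid,
    chain = a$chain, elety = a$elety, o = a$o, insert = a$insert)
  invisible(path)
}

#' Distance-measurement specification for coupled pairs
#'
#' @param mode `"CA"` for alpha-carbon distances or `"closest_heavy"` for
#'   the minimum over all heavy-atom pairs of the two residues.
#' @param chain_intra Chain label used to resolve records without chain
#'   labels (intra-chain coupling tables); defaults to the structure's first
#'   chain.
#' @param offset Integer added to coupling residue indices before mapping
#'   onto the chain's resolved residues (coupling tables index the model
#'   sequence, which may be shifted relative to the structure).
#' @return A `distance_spec` list.
#' @export
distance_spec <- function(mode = c("CA", "closest_heavy"),
                          chain_intra = NULL, offset = 0L) {
  structure(list(mode = match.arg(mode), chain_intra = chain_intra,
                 offset = as.integer(offset)),
            class = "distance_spec")
}

## Resolved residues of a chain: unique (resno, insert) in file order.
chain_residues <- function(s, chain) {
  a <- s$atom[s$atom$chain == chain, , drop = FALSE]
  unique(paste(a$resno, a$insert, sep = "_"))
}

## Atom rows for the k-th resolved residue of `chain` (1-based k).
residue_atoms <- function(s, chain, k) {
  res <- chain_residues(s, chain)
  if (k < 1L || k > length(res)) return(NULL)
  a <- s$atom
  a[a$chain == chain &
      paste(a$resno, a$insert, sep = "_") == res[k], , drop = FALSE]
}

#' Distances between coupled residue pairs in a structure
#'
#' Maps each coupling record onto the structure (coupling index k is the
#' k-th resolved residue of the chain, plus any offset in the spec) and
#' returns the Euclidean distance per pair, in the coupling set's order.
#'
#' @param s An `ec_structure`.
#' @param pairs A `coupling_set`.
#' @param spec A [distance_spec()].
#' @return Numeric vector of distances (Angstrom), one per coupling record.
#' @export
pair_distances <- function(s, pairs, spec = distance_spec()) {
  stopifnot(inherits(s, "ec_structure"), inherits(pairs, "coupling_set"))
  rec <- pairs$records
  default_chain <- if (is.null(spec$chain_intra))
    s$atom$chain[1L] else spec$chain_intra
  ch_i <- ifelse(is.na(rec$chain_i), default_chain, rec$chain_i)
  ch_j <- ifelse(is.na(rec$chain_j), default_chain, rec$chain_j)
  out <- numeric(nrow(rec))
  missing <- character(0)
  for (r in seq_len(nrow(rec))) {
    ai <- residue_atoms(s, ch_i[r], rec$residue_i[r] + spec$offset)
    aj <- residue_atoms(s, ch_j[r], rec$residue_j[r] + spec$offset)
    if (is.null(ai) || nrow(ai) == 0L)
      missing <- c(missing, paste0(ch_i[r], ":", rec$residue_i[r]))
    if (is.null(aj) || nrow(aj) == 0L)
      missing <- c(missing, paste0(ch_j[r], ":", rec$residue_j[r]))
    if (length(missing) > 0L) next
    out[r] <- residue_pair_distance(ai, aj, spec$mode)
  }
  if (length(missing) > 0L)
    stop("cannot resolve residue(s) in structure: ",
         paste(unique(missing), collapse = ", "))
  out
}

residue_pair_distance <- function(ai, aj, mode) {
  if (mode == "CA") {
    pi_ <- ai[ai$elety == "CA", c("x", "y", "z"), drop = FALSE]
    pj <- aj[aj$elety == "CA", c("x", "y", "z"), drop = FALSE]
    if (nrow(pi_) == 0L || nrow(pj) == 0L)
      stop("residue lacks a CA atom for CA-mode distances")
    sqrt(sum((as.numeric(pi_[1L, ]) - as.numeric(pj[1L, ]))^2))
  } else {
    heavy <- function(a) !grepl("^H", sub("^[0-9]+", "", a$elety))
    mi <- as.matrix(ai[heavy(ai), c("x", "y", "z"), drop = FALSE])
    mj <- as.matrix(aj[heavy(aj), c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(mi^2), rowSums(mj^2), "+") - 2 * mi %*% t(mj)
    sqrt(max(0, min(d2)))
  }
}

#' RMSD after optimal rigid-body superposition
#'
#' Selects matched atoms from both structures, superposes them by
#' least-squares (Kabsch) and returns the root-mean-square deviation.
#'
#' @param a,b `ec_structure` objects.
#' @param selection Character vector of atom names to match (default
#'   `"CA"`), or `"backbone"` for N, CA, C, O.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b, selection = "CA") {
  if (identical(selection, "backbone")) selection <- c("N", "CA", "C", "O")
  xa <- a$atom[a$atom$elety %in% selection, c("x", "y", "z"), drop = FALSE]
  xb <- b$atom[b$atom$elety %in% selection, c("x", "y", "z"), drop = FALSE]
  if (nrow(xa) != nrow(xb))
    stop("selection error: ", nrow(xa), " vs ", nrow(xb), " matched atoms")
  if (nrow(xa) < 2L) stop("need at least 2 matched atoms for superposition")
  kabsch_rmsd(as.matrix(xa), as.matrix(xb))
}

## Kabsch superposition RMSD via SVD of the cross-covariance, with the
## usual determinant correction to exclude reflections; rank-deficient
## (collinear/planar) selections are handled by the SVD directly.
kabsch_rmsd <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  a <- sweep(xa, 2L, ca); b <- sweep(xb, 2L, cb)
  s <- svd(t(b) %*% a)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((b %*% rot - a)^2)))
}

#' Backbone RMSD between two PDB files over their shared residues
#'
#' Convention used for comparing two crystal forms of the same protein:
#' residues are matched by identical (chain, residue number, insertion
#' code); for every shared residue possessing all four backbone atoms
#' (N, CA, C, O) in both files those atoms are paired, and the Kabsch
#' superposition RMSD over the paired atoms is returned. Engineered
#' insertions or extra chains present in only one file drop out of the
#' intersection automatically.
#'
#' @param path_a,path_b Paths to the two PDB files.
#' @return Backbone RMSD in Angstrom.
#' @export
backbone_rmsd <- function(path_a, path_b) {
  sa <- read_pdb(path_a)
  sb <- read_pdb(path_b)
  bb <- c("N", "CA", "C", "O")
  pick <- function(s) {
    a <- s$atom[s$atom$elety %in% bb, , drop = FALSE]
    a$res_key <- paste(a$chain, a$resno, a$insert)
    complete <- names(which(tapply(a$elety, a$res_key,
                                   function(e) all(bb %in% e))))
    a[a$res_key %in% complete, , drop = FALSE]
  }
  aa <- pick(sa); ab <- pick(sb)
  shared <- intersect(unique(aa$res_key), unique(ab$res_key))
  if (length(shared) < 3L)
    stop("fewer than 3 shared backbone-complete residues between ",
         path_a, " and ", path_b)
  key_a <- paste(aa$res_key, aa$elety)
  key_b <- paste(ab$res_key, ab$elety)
  want <- as.vector(outer(shared, bb, paste))
  ma <- aa[match(want, key_a), c("x", "y", "z")]
  mb <- ab[match(want, key_b), c("x", "y", "z")]
  kabsch_rmsd(as.matrix(ma), as.matrix(mb))
}

#' Featurize a sequence of structures
#'
#' Converts a list of conformations into a frames-by-features matrix under
#' one of three schemes: `dihedral` (phi, psi and chi1 backbone/side-chain
#' torsions encoded as sin/cos pairs), `reciprocal_distance` (1/d over a
#' set of atom pairs) or `com_basis` (the partner chain's center-of-mass
#' displacement from the base chain expressed in an orthonormal basis built
#' by Gram-Schmidt from three anchor alpha-carbons of the base chain, so
#' the feature co-rotates with the complex).
#'
#' @param trajs List of `ec_structure` conformations (constant topology).
#' @param scheme One of `"dihedral"`, `"reciprocal_distance"`, `"com_basis"`.
#' @param params Scheme parameters. `reciprocal_distance`: `pairs`, a
#'   two-column matrix of atom row indices (default: all CA-CA pairs).
#'   `com_basis`: `base_chain`, `partner_chain`, and `anchors`, three
#'   residue numbers on the base chain.
#' @param frame_interval Time per frame, recorded in the result.
#' @return A `feature_trajectory`: list with `data` (frames x features),
#'   `labels` and `frame_interval`.
#' @export
featurize <- function(trajs, scheme = c("dihedral", "reciprocal_distance",
                                        "com_basis"),
                      params = list(), frame_interval = 1) {
  scheme <- match.arg(scheme)
  stopifnot(length(trajs) > 0L)
  rows <- switch(scheme,
    dihedral = lapply(trajs, dihedral_features),
    reciprocal_distance = lapply(trajs, recip_dist_features, params = params),
    com_basis = lapply(trajs, com_basis_features, params = params))
  labels <- attr(rows[[1L]], "labels")
  data <- do.call(rbind, lapply(rows, as.numeric))
  if (any(!is.finite(data))) stop("non-finite feature values produced")
  colnames(data) <- labels
  structure(list(data = data, labels = labels,
                 frame_interval = frame_interval),
            class = "feature_trajectory")
}

## Torsion angle (degrees) of four points, standard atan2 convention.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

chi1_gamma <- c("CG", "CG1", "OG", "OG1", "SG")

dihedral_features <- function(s) {
  a <- s$atom
  res_key <- unique(paste(a$chain, a$resno, a$insert, sep = "_"))
  get_atom <- function(rk, name) {
    rows <- which(paste(a$chain, a$resno, a$insert, sep = "_") == rk &
                    a$elety == name)
    if (length(rows) == 0L) return(NULL)
    as.numeric(a[rows[1L], c("x", "y", "z")])
  }
  vals <- numeric(0); labels <- character(0)
  for (k in seq_along(res_key)) {
    rk <- res_key[k]
    n <- get_atom(rk, "N"); ca <- get_atom(rk, "CA"); cc <- get_atom(rk, "C")
    if (is.null(n) || is.null(ca) || is.null(cc))
      stop("featurization error: residue ", rk, " lacks backbone atoms")
    if (k > 1L) {
      cprev <- get_atom(res_key[k - 1L], "C")
      if (!is.null(cprev)) {
        phi <- dihedral_angle(cprev, n, ca, cc) * pi / 180
        vals <- c(vals, sin(phi), cos(phi))
        labels <- c(labels, paste0(c("sin_phi_", "cos_phi_"), rk))
      }
    }
    if (k < length(res_key)) {
      nnext <- get_atom(res_key[k + 1L], "N")
      if (!is.null(nnext)) {
        psi <- dihedral_angle(n, ca, cc, nnext) * pi / 180
        vals <- c(vals, sin(psi), cos(psi))
        labels <- c(labels, paste0(c("sin_psi_", "cos_psi_"), rk))
      }
    }
    cb <- get_atom(rk, "CB")
    gamma <- NULL
    for (g in chi1_gamma) {
      gamma <- get_atom(rk, g)
      if (!is.null(gamma)) break
    }
    if (!is.null(cb) && !is.null(gamma)) {
      chi <- dihedral_angle(n, ca, cb, gamma) * pi / 180
      vals <- c(vals, sin(chi), cos(chi))
      labels <- c(labels, paste0(c("sin_chi1_", "cos_chi1_"), rk))
    }
  }
  if (length(vals) == 0L) stop("no dihedral features could be built")
  attr(vals, "labels") <- labels
  vals
}

recip_dist_features <- function(s, params) {
  a <- s$atom
  pairs <- params$pairs
  if (is.null(pairs)) {
    ca <- which(a$elety == "CA")
    if (length(ca) < 2L) stop("need at least two CA atoms")
    pairs <- t(utils::combn(ca, 2L))
  }
  m <- as.matrix(a[, c("x", "y", "z")])
  d <- sqrt(rowSums((m[pairs[, 1L], , drop = FALSE] -
                       m[pairs[, 2L], , drop = FALSE])^2))
  if (any(d == 0)) stop("coincident atoms give an infinite reciprocal distance")
  vals <- 1 / d
  attr(vals, "labels") <- paste0("rd_", pairs[, 1L], "_", pairs[, 2L])
  vals
}

com_basis_features <- function(s, params) {
  base <- params$base_chain; partner <- params$partner_chain
  anchors <- params$anchors
  if (is.null(base) || is.null(partner) || length(anchors) != 3L)
    stop("com_basis needs base_chain, partner_chain and three anchor residues")
  a <- s$atom
  anchor_xyz <- t(vapply(anchors, function(rn) {
    row <- which(a$chain == base & a$resno == rn & a$elety == "CA")
    if (length(row) == 0L)
      stop("featurization error: no CA for anchor residue ", base, ":", rn)
    as.numeric(a[row[1L], c("x", "y", "z")])
  }, numeric(3L)))
  v1 <- anchor_xyz[2L, ] - anchor_xyz[1L, ]
  v2 <- anchor_xyz[3L, ] - anchor_xyz[1L, ]
  if (sqrt(sum(v1^2)) < 1e-8) stop("degenerate basis: coincident anchors")
  e1 <- v1 / sqrt(sum(v1^2))
  w2 <- v2 - sum(v2 * e1) * e1
  if (sqrt(sum(w2^2)) < 1e-8)
    stop("degenerate basis: collinear anchor residues")
  e2 <- w2 / sqrt(sum(w2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  com <- function(chain) {
    m <- a[a$chain == chain, c("x", "y", "z"), drop = FALSE]
    if (nrow(m) == 0L) stop("no atoms on chain ", chain)
    colMeans(as.matrix(m))
  }
  dvec <- com(partner) - com(base)
  vals <- as.numeric(rbind(e1, e2, e3) %*% dvec)
  attr(vals, "labels") <- c("com_b1", "com_b2", "com_b3")
  vals
}
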