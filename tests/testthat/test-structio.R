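test_that("PDB reading keeps the first model and best altloc", {
  s <- read_pdb(write_mini_pdb())
  expect_s3_class(s, "ec_structure")
  expect_equal(nrow(s$atom), 10L)

  s2 <- read_pdb(write_mini_pdb(models = 2L))
  expect_equal(nrow(s2$atom), 10L)
  expect_lt(max(s2$atom$x), 50)  # model 2 lives at x ~ 100

  s3 <- read_pdb(write_mini_pdb(altloc = TRUE))
  n1 <- s3$atom[s3$atom$elety == "N" & s3$atom$resno == 1, ]
  expect_equal(nrow(n1), 1L)
  expect_equal(n1$x, 0)          # occupancy 0.6 copy, not the 0.4 one
})

test_that("coupled-pair distances are Euclidean and mode-consistent", {
  s <- ca_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  cs <- read_coupling_table(
    write_coupling_fixture(data.frame(i = 1, j = 2, score = 1)))
  expect_equal(pair_distances(s, cs), 5.0)

  same <- ca_structure(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(pair_distances(same, cs), 0)

  # closest-heavy can only shorten distances relative to CA-CA
  tc <- generate_toy_complex(n_residues_per_chain = 4L, n_decoys = 1L,
                             seed = 3L)
  d_ca <- pair_distances(tc$native, tc$couplings, distance_spec("CA"))
  d_ch <- pair_distances(tc$native, tc$couplings,
                         distance_spec("closest_heavy"))
  expect_true(all(d_ch <= d_ca + 1e-12))

  bad <- read_coupling_table(
    write_coupling_fixture(data.frame(i = 1, j = 99, score = 1)))
  expect_error(pair_distances(s, bad), "A:99")
})

test_that("superposition RMSD is rigid-invariant and symmetric", {
  set.seed(7)
  xyz <- matrix(stats::rnorm(15, sd = 5), ncol = 3L)
  a <- ca_structure(xyz)
  expect_equal(superpose_rmsd(a, a), 0, tolerance = 1e-8)

  shift <- ca_structure(sweep(xyz, 2L, c(1, 1, 1), "+"))
  expect_equal(superpose_rmsd(a, shift), 0, tolerance = 1e-8)

  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L)
  b <- ca_structure(matrix(stats::rnorm(15, sd = 5), ncol = 3L))
  b_rot <- ca_structure(as.matrix(b$atom[, c("x", "y", "z")]) %*% rot)
  expect_equal(superpose_rmsd(a, b), superpose_rmsd(a, b_rot),
               tolerance = 1e-6)
  expect_equal(superpose_rmsd(a, b), superpose_rmsd(b, a),
               tolerance = 1e-6)

  expect_error(superpose_rmsd(a, ca_structure(xyz[1:3, ])), "selection")
})

test_that("two-point superposition gives the centroid-aligned deviation", {
  a <- ca_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0), c(2, 0, 0)))
  b <- ca_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 0, 0), c(4, 0, 0)))
  # centred pairs are +-1 vs +-2 along one axis -> every deviation is 1
  expect_equal(superpose_rmsd(a, b), 1.0, tolerance = 1e-6)
})

test_that("delta-SEC from structures is invariant under rigid motion", {
  tc <- generate_toy_complex(n_residues_per_chain = 5L, n_decoys = 1L,
                             seed = 2L)
  ref_d <- pair_distances(tc$native, tc$couplings, tc$spec)
  moved <- ecsampler:::new_structure(
    ecsampler:::rigid_transform(tc$native$atom, c(0.3, -1.1, 2.0),
                                c(12, -7, 5)))
  mov_d <- pair_distances(moved, tc$couplings, tc$spec)
  expect_equal(delta_sec(mov_d, ref_d)$delta_sec, 0, tolerance = 1e-12)
})

test_that("dihedral featurization encodes torsions as sin/cos", {
  s <- read_pdb(write_mini_pdb())
  ft <- featurize(list(s, s), scheme = "dihedral")
  expect_equal(nrow(ft$data), 2L)
  expect_identical(ft$data[1L, ], ft$data[2L, ])
  expect_true(all(abs(ft$data) <= 1 + 1e-12))
  # a planar zig-zag backbone puts psi of residue 1 at 180 degrees
  psi_cols <- grep("psi", ft$labels)
  expect_gt(length(psi_cols), 0L)
  # sin^2 + cos^2 = 1 for every encoded angle
  sins <- ft$data[1L, seq(1L, ncol(ft$data), 2L)]
  coss <- ft$data[1L, seq(2L, ncol(ft$data), 2L)]
  expect_equal(sins^2 + coss^2, rep(1, length(sins)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("reciprocal distances are positive and monotone in distance", {
  near <- ca_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  far <- ca_structure(rbind(c(0, 0, 0), c(8, 0, 0)))
  f_near <- featurize(list(near), "reciprocal_distance")
  f_far <- featurize(list(far), "reciprocal_distance")
  expect_equal(as.numeric(f_near$data), 0.5)
  expect_equal(as.numeric(f_far$data), 0.125)
  expect_true(all(f_near$data > 0))
})

test_that("center-of-mass basis features co-rotate with the complex", {
  base <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  mk <- function(partner_shift) {
    a <- ca_structure(base, chain = "A")$atom
    b <- ca_structure(sweep(base, 2L, partner_shift, "+"), chain = "B")$atom
    b$resno <- b$resno  # same numbering on its own chain
    ecsampler:::new_structure(rbind(a, b))
  }
  params <- list(base_chain = "A", partner_chain = "B", anchors = 1:3)
  # partner displaced along the first basis vector (a2 - a1 = +x) by 10
  s <- mk(c(10, 0, 0))
  ft <- featurize(list(s), "com_basis", params)
  expect_equal(as.numeric(ft$data), c(10, 0, 0), tolerance = 1e-10)

  # rigid rotation + translation of the whole complex leaves features fixed
  moved <- ecsampler:::new_structure(
    ecsampler:::rigid_transform(s$atom, c(1.2, 0.4, -0.9), c(3, -8, 2)))
  ft2 <- featurize(list(moved), "com_basis", params)
  expect_equal(as.numeric(ft2$data), as.numeric(ft$data), tolerance = 1e-8)

  collinear <- ecsampler:::new_structure(rbind(
    ca_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "A")$atom,
    ca_structure(base, "B")$atom))
  expect_error(featurize(list(collinear), "com_basis", params), "collinear")
})
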