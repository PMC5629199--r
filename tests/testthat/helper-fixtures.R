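# Shared test fixtures, all generated in code.

write_coupling_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal hand-written PDB: two ALA residues (backbone + CB), one chain.
# Optionally a second MODEL (shifted) and an altloc pair on atom 1.
write_mini_pdb <- function(path = tempfile(fileext = ".pdb"),
                           models = 1L, altloc = FALSE) {
  atom_line <- function(serial, name, alt, resno, x, y, z, occ) {
    sprintf("ATOM  %5d %-4s%1sALA A%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
            serial, paste0(" ", name), alt, resno, x, y, z, occ,
            substr(name, 1L, 1L))
  }
  res <- function(resno, x0, serial0) {
    c(atom_line(serial0,     "N",  " ", resno, x0 + 0.0, 0, 0, 1),
      atom_line(serial0 + 1L, "CA", " ", resno, x0 + 1.5, 0, 0, 1),
      atom_line(serial0 + 2L, "C",  " ", resno, x0 + 2.5, 1, 0, 1),
      atom_line(serial0 + 3L, "O",  " ", resno, x0 + 2.5, 2, 0, 1),
      atom_line(serial0 + 4L, "CB", " ", resno, x0 + 1.5, -1.5, 0, 1))
  }
  body <- c(res(1, 0, 1), res(2, 4, 6))
  if (altloc) {
    body <- c(atom_line(1, "N", "A", 1, 0, 0, 0, 0.6),
              atom_line(1, "N", "B", 1, 9, 9, 9, 0.4),
              body[-1L])
  }
  lines <- if (models > 1L) {
    shifted <- c(res(1, 100, 1), res(2, 104, 6))
    c("MODEL        1", body, "ENDMDL",
      "MODEL        2", shifted, "ENDMDL", "END")
  } else c(body, "END")
  writeLines(lines, path)
  path
}

# ec_structure built directly from coordinates: one CA atom per residue.
ca_structure <- function(xyz, chain = "A") {
  xyz <- matrix(xyz, ncol = 3L)
  atom <- data.frame(elety = "CA", resid = "ALA", chain = chain,
                     resno = seq_len(nrow(xyz)), insert = "", o = 1,
                     x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                     stringsAsFactors = FALSE)
  ecsampler:::new_structure(atom)
}

# Random reversible transition matrix from a random symmetric count matrix.
random_reversible_tmat <- function(n, seed) {
  counts <- ecsampler:::with_seed(seed, {
    m <- matrix(stats::rpois(n * n, 8) + 1, n, n)
    m + t(m)
  })
  estimate_reversible(counts)
}

# All simple paths from any state in A to any state in B on a capacity
# matrix, with their bottleneck capacities (test oracle, exhaustive).
enumerate_paths <- function(cap, A, B) {
  n <- nrow(cap)
  out <- list()
  walk <- function(path, width) {
    u <- path[length(path)]
    if (u %in% B) {
      out[[length(out) + 1L]] <<- list(path = path, width = width)
      return()
    }
    for (v in which(cap[u, ] > 0)) {
      if (v %in% path || (v %in% A)) next
      walk(c(path, v), min(width, cap[u, v]))
    }
  }
  for (a in A) walk(a, Inf)
  out
}
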