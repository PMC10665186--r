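# Fixtures are built in code at test time; nothing is read from disk except
# files these helpers write into tempdir().

# straight synthetic chain of n CA atoms along +z, offset laterally
make_chain_model <- function(n = 10, chains = "A", offsets = list(c(0, 0))) {
  rows <- do.call(rbind, lapply(seq_along(chains), function(i) {
    data.frame(chain = chains[i], resno = seq_len(n), atom = "CA",
               x = offsets[[i]][1], y = offsets[[i]][2],
               z = (seq_len(n) - 1) * 1.5)
  }))
  atom_model(rows$chain, rows$resno, rows$atom, rows$x, rows$y, rows$z)
}

write_min_pdb <- function(path, dup = FALSE) {
  lines <- c(
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      14.000  15.000  16.000  1.00  0.00           C")
  # a third atom with a fresh serial but a repeated (chain, resno, atom)
  if (dup) lines <- c(lines, sub("A   2", "A   1",
                                 sub("ATOM      2", "ATOM      3", lines[2])))
  writeLines(c(lines, "END"), path)
  path
}

write_min_star <- function(path, with_angles = TRUE) {
  cols <- c("_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3")
  rows <- c("10.0 20.0 30.0", "1.5 2.5 3.5")
  if (with_angles) {
    cols <- c(cols, "_rlnAngleRot #4", "_rlnAngleTilt #5", "_rlnAnglePsi #6")
    rows <- c("10.0 20.0 30.0 15.0 90.0 -45.0", "1.5 2.5 3.5 0.0 10.0 20.0")
  }
  writeLines(c("data_particles", "", "loop_", cols, rows), path)
  path
}

# random particle table for duplicate-removal / symmetry tests
random_particles <- function(n, extent = 300, seed = 42) {
  set.seed(seed)
  data.frame(filament_id = "F1", segment_index = seq_len(n),
             x_A = runif(n, 0, extent), y_A = runif(n, 0, extent),
             z_A = runif(n, 0, extent),
             rot_deg = runif(n, -180, 180),
             tilt_deg = runif(n, 0, 180), psi_deg = runif(n, -180, 180),
             score = runif(n), stringsAsFactors = FALSE)
}

# brute-force duplicate removal oracle: full distance matrix, same greedy
# keep rule, written independently of the package internals
dedup_bruteforce <- function(records, min_dist, keep = "best-score") {
  pos <- as.matrix(records[, c("x_A", "y_A", "z_A")])
  D <- as.matrix(dist(pos))
  ord <- if (keep == "best-score") order(-records$score) else seq_len(nrow(pos))
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(D[i, kept] >= min_dist)) kept <- c(kept, i)
  }
  records[sort(kept), , drop = FALSE]
}

# arc length of y = A sin(2 pi x / lambda) over [0, X] by adaptive quadrature
sine_arclen_quadrature <- function(A, lambda, X) {
  k <- 2 * pi / lambda
  stats::integrate(function(x) sqrt(1 + (A * k * cos(k * x))^2), 0, X,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(normalize_angle(a - b))), tol)
}
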