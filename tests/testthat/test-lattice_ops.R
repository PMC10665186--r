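straight_trace <- function(len = 100, id = "F1") {
  filament_trace(id, cbind(0, 0, seq(0, len, length.out = 11)))
}

test_that("resampling places records at exact arc positions", {
  p <- resample_trace(straight_trace(100), spacing = 18)
  expect_equal(nrow(p), 6)
  expect_equal(p$z_A, seq(0, 90, by = 18))
  expect_true(all(is.na(p$rot_deg)))          # spin undefined from tangent
  expect_equal(unique(p$tilt_deg), 0)         # tangent is +z

  # quarter circle of radius R: consecutive arc separations equal spacing
  R <- 200
  th <- seq(0, pi / 2, length.out = 5000)
  qc <- filament_trace("arc", cbind(R * cos(th), R * sin(th), 0))
  s <- 15
  pq <- resample_trace(qc, s)
  ang <- atan2(pq$y_A, pq$x_A)
  arc_pos <- R * ang
  expect_lt(max(abs(diff(arc_pos) - s)), 1e-6 * s + 1e-4)

  short <- resample_trace(straight_trace(100), spacing = 130)
  expect_equal(nrow(short), 1)
  expect_match(attr(short, "flag"), "shorter")
  expect_error(resample_trace(straight_trace(100), 0), "positive")
})

test_that("axial shift walks the trace and accounts for drops", {
  tr <- straight_trace(1000)
  rec <- data.frame(filament_id = "F1", segment_index = 1,
                    x_A = 0, y_A = 0, z_A = 0,
                    rot_deg = 0, tilt_deg = 0, psi_deg = 0)
  sh <- axial_shift(rec, list(F1 = tr), delta = 430, direction = "Z-ward")
  expect_equal(c(sh$x_A, sh$y_A, sh$z_A), c(0, 0, 430))
  expect_equal(attr(sh, "dropped"), 0)

  # anchor 200 A from the trace end: a 430 A shift exits and is dropped
  rec2 <- rec; rec2$z_A <- 800
  sh2 <- axial_shift(rec2, list(F1 = tr), 430, "Z-ward")
  expect_equal(nrow(sh2), 0)
  expect_equal(attr(sh2, "dropped"), 1)

  expect_error(axial_shift(rec, list(OTHER = tr), 430), "F1")
})

test_that("axial shift measures arc length on curved traces", {
  R <- 500
  th <- seq(0, pi, length.out = 20000)
  # helix-like bend in 3D
  tr <- filament_trace("C1", cbind(R * cos(th), R * sin(th), 300 * th))
  rec <- data.frame(filament_id = "C1", segment_index = 1,
                    x_A = R, y_A = 0, z_A = 0,
                    rot_deg = NA, tilt_deg = 0, psi_deg = 0)
  sh <- axial_shift(rec, list(C1 = tr), 430, "Z-ward")
  s0 <- sarcgeom:::trace_project(tr, c(R, 0, 0))
  s1 <- sarcgeom:::trace_project(tr, c(sh$x_A, sh$y_A, sh$z_A))
  expect_equal(s1 - s0, 430, tolerance = 1e-6 * 430)

  # +delta then -delta returns interior anchors to their positions
  back <- axial_shift(sh, list(C1 = tr), 430, "M-ward")
  expect_lt(max(abs(c(back$x_A - rec$x_A, back$y_A - rec$y_A,
                      back$z_A - rec$z_A))), 1e-4)
})

test_that("round-trip shifting is exact on straight traces", {
  tr <- straight_trace(2000)
  recs <- data.frame(filament_id = "F1", segment_index = 1:5,
                     x_A = 0, y_A = 0, z_A = c(500, 700, 900, 1100, 1300),
                     rot_deg = 0, tilt_deg = 0, psi_deg = 0)
  there <- axial_shift(recs, list(F1 = tr), 430, "Z-ward")
  back <- axial_shift(there, list(F1 = tr), 430, "M-ward")
  expect_lt(max(abs(back$z_A - recs$z_A)), 1e-6)
})

test_that("duplicate removal matches the brute-force reference", {
  two <- random_particles(2)
  two$x_A <- c(0, 6); two$y_A <- c(0, 8); two$z_A <- 0   # 10 A apart
  kept <- remove_duplicates(two, min_dist = 50)
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "removed"), 1)

  spread <- random_particles(20, extent = 5000, seed = 3)
  expect_equal(nrow(remove_duplicates(spread, min_dist = 10)), 20)

  recs <- random_particles(500, extent = 400, seed = 17)
  for (md in c(20, 45)) {
    mine <- remove_duplicates(recs, min_dist = md, keep = "best-score")
    oracle <- dedup_bruteforce(recs, min_dist = md, keep = "best-score")
    expect_equal(mine$segment_index, oracle$segment_index)
    # postcondition asserted on every run: min pairwise distance >= min_dist
    expect_gte(min(dist(mine[, c("x_A", "y_A", "z_A")])), md)
  }
  expect_error(remove_duplicates(recs, -1), "positive")
})

test_that("symmetry expansion: helical, Cn, Dn", {
  rec <- data.frame(filament_id = "F1", segment_index = 1,
                    x_A = 130, y_A = 0, z_A = 0,
                    rot_deg = 0, tilt_deg = 0, psi_deg = 0)
  hel <- symmetry_op("helical", rise = 430, twist = 0)
  e1 <- expand_symmetry(rec, hel, n_copies = 4)
  expect_equal(e1$z_A, c(0, 430, 860, 1290))
  expect_equal(unique(round(atan2(e1$y_A, e1$x_A), 9)), 0)  # phi unchanged

  helt <- symmetry_op("helical", rise = 430, twist = 120)
  e2 <- expand_symmetry(rec, helt, n_copies = 3)
  phis <- normalize_angle(atan2(e2$y_A, e2$x_A) * 180 / pi)
  expect_equal(sort(round(phis %% 360, 6)), c(0, 120, 240))

  c3 <- symmetry_op("Cn", n = 3)
  e3 <- expand_symmetry(rec, c3)
  expect_equal(nrow(e3), 3)                   # triples counts exactly

  expect_error(symmetry_op("Dn", n = 3), "perp_axis")
  d3 <- symmetry_op("Dn", n = 3, perp_axis = c(1, 0, 0))
  e4 <- expand_symmetry(rec, d3)
  expect_equal(nrow(e4), 6)
  expect_setequal(round(e4$z_A, 9), 0)        # flip through z = 0 plane
  expect_error(symmetry_op("helical", rise = 0, twist = 0), "nonzero")
})

test_that("C3 and helical expansions commute", {
  recs <- random_particles(4, extent = 200, seed = 8)
  c3 <- symmetry_op("Cn", n = 3)
  hel <- symmetry_op("helical", rise = 430, twist = 40)
  a <- expand_symmetry(expand_symmetry(recs, c3), hel, n_copies = 3)
  b <- expand_symmetry(expand_symmetry(recs, hel, n_copies = 3), c3)
  key <- function(d) {
    m <- round(as.matrix(d[, c("x_A", "y_A", "z_A")]), 9)
    sort(apply(m, 1, paste, collapse = ","))
  }
  expect_identical(key(a), key(b))
})

test_that("expanded orientations compose with the symmetry rotation", {
  rec <- data.frame(filament_id = "F1", segment_index = 1,
                    x_A = 130, y_A = 0, z_A = 0,
                    rot_deg = 10, tilt_deg = 30, psi_deg = 20)
  c3 <- symmetry_op("Cn", n = 3)
  e <- expand_symmetry(rec, c3)
  R0 <- euler_zyz_to_mat(10, 30, 20)
  for (k in 0:2) {
    Rk <- sarcgeom:::rot_about_axis(c(0, 0, 1), 120 * k) %*% R0
    Re <- euler_zyz_to_mat(e$rot_deg[k + 1], e$tilt_deg[k + 1],
                           e$psi_deg[k + 1])
    expect_lt(max(abs(Rk - Re)), 1e-9)
  }
})

test_that("C3-expanded crowns show 120-degree twist between mates", {
  canon <- sarcgeom:::canonical_triangle(c(fb = 95, bj = 105, jf = 100))
  cyl <- cylinder_model()
  # one crown per level; expand by C3 and measure the azimuthal spacing
  V <- sarcgeom:::pose_triangle(canon, 0, 20, 0, phi = 0, r = 130, z = 100)
  verts <- data.frame(filament_id = "F1", segment_index = 1:3,
                      x_A = V[, 1], y_A = V[, 2], z_A = V[, 3],
                      rot_deg = NA, tilt_deg = NA, psi_deg = NA)
  e <- expand_symmetry(verts, symmetry_op("Cn", n = 3))
  poses <- do.call(rbind, lapply(split(e, e$sym_copy), function(d)
    crown_pose(c(d$x_A[1], d$y_A[1], d$z_A[1]),
               c(d$x_A[2], d$y_A[2], d$z_A[2]),
               c(d$x_A[3], d$y_A[3], d$z_A[3]), cyl)))
  expect_lt(diff(range(poses$beta)), 1e-9)    # same pose in local frames
  expect_setequal(round(sort(poses$phi %% 360), 6), c(0, 120, 240))
})
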