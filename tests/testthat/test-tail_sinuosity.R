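test_that("coiled-coil midline construction and truncation", {
  # two straight chains offset +/- 5 A laterally: midline on the central line
  z <- seq(0, 75, by = 1.5)
  A <- cbind(-5, 0, z); B <- cbind(5, 0, z)
  mid <- coiled_coil_midline(A, B)
  expect_lt(max(abs(mid$points[, 1])), 1e-12)
  expect_equal(nrow(mid$points), length(z))

  # chains of 50 and 47 residues, offset 0: 47 couples
  mid2 <- coiled_coil_midline(cbind(-5, 0, seq_len(50)),
                              cbind(5, 0, seq_len(47)))
  expect_equal(nrow(mid2$points), 47)

  # offset pairing k = 2 truncates accordingly
  mid3 <- coiled_coil_midline(cbind(-5, 0, seq_len(50)),
                              cbind(5, 0, seq_len(50)), offset = 2)
  expect_equal(nrow(mid3$points), 48)

  expect_error(coiled_coil_midline(A[1:2, ], B, offset = 100), "couples")
})

test_that("ideal straight-axis coiled coil traces to near-zero SCP", {
  tl <- build_tail_curve(1600, list(amplitude = 0, wavelength = 430))
  mid <- coiled_coil_midline(tl$chainA, tl$chainB)
  expect_lt(sinuosity(mid)$SCP, 0.05)
  expect_lt(tl$scp, 1e-9)   # ground-truth midline exactly straight
})

test_that("sinuosity closed forms: straight line and semicircle", {
  straight <- curve3d(cbind(0, 0, seq(0, 100, by = 1)))
  s <- sinuosity(straight)
  expect_equal(s$S, 1)
  expect_equal(s$SCP, 0)

  th <- seq(0, pi, length.out = 4001)
  semi <- curve3d(cbind(100 * cos(th), 100 * sin(th), 0))
  s2 <- sinuosity(semi)
  expect_equal(s2$S, pi / 2, tolerance = 1e-6)
  expect_equal(s2$SCP, 57.08, tolerance = 1e-3)
})

test_that("sine-midline SCP matches the quadrature oracle", {
  A <- 20; lambda <- 430
  x <- seq(0, lambda, by = 0.05)
  crv <- curve3d(cbind(x, A * sin(2 * pi * x / lambda), 0))
  C_oracle <- sine_arclen_quadrature(A, lambda, lambda)
  scp_oracle <- (C_oracle / lambda - 1) * 100
  s <- sinuosity(crv)
  expect_equal(s$SCP, scp_oracle, tolerance = 5e-4 * scp_oracle)
  # arc length itself agrees to 1e-6 relative
  expect_equal(s$C, C_oracle, tolerance = 1e-6 * C_oracle)
})

test_that("near-closed curves are rejected", {
  th <- seq(0, 2 * pi, length.out = 200)
  loop <- curve3d(cbind(cos(th), sin(th), 0))
  expect_error(sinuosity(loop), "unstable")
})

test_that("windowed SCP and profile behave consistently", {
  x <- seq(0, 860, by = 0.5)
  crv <- curve3d(cbind(x, 20 * sin(2 * pi * x / 430), 0))
  L <- crv$arc[length(crv$arc)]
  prof <- scp_profile(crv, window_len = L, step = 100)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$SCP, sinuosity(crv)$SCP, tolerance = 1e-12)

  straight <- curve3d(cbind(0, 0, seq(0, 500, by = 5)))
  p2 <- scp_profile(straight, window_len = 100, step = 50)
  expect_true(all(p2$SCP < 1e-9))
  expect_error(scp_profile(straight, 100, step = 0), "positive")
  expect_error(scp_profile(straight, 1e5, 10), "exceeds")
})

test_that("a localized bend is found by the max-SCP window", {
  tl <- build_tail_curve(1600, list(amplitude = 0, wavelength = 430,
                                    kink_position = 0.6, kink_angle = 25))
  prof <- scp_profile(tl$midline, window_len = 200, step = 20)
  top <- prof[which.max(prof$SCP), ]
  kink_s <- 0.6 * tl$midline$arc[length(tl$midline$arc)]
  expect_true(top$window_start <= kink_s && kink_s <= top$window_end)
})

test_that("curvature profile: circle, line, and kink localization", {
  th <- seq(0, pi, length.out = 2001)
  circ <- curve3d(cbind(200 * cos(th), 200 * sin(th), 0))
  cp <- curvature_profile(circ, smoothing_len = 10)
  expect_true(all(abs(cp$profile$curvature - 1 / 200) < 0.01 / 200))

  line <- curve3d(cbind(0, 0, seq(0, 500, by = 2)))
  cl <- curvature_profile(line, smoothing_len = 10)
  expect_true(all(cl$profile$curvature < 1e-12))
  expect_error(curvature_profile(line, smoothing_len = 0.1), "spacing")

  tl <- build_tail_curve(1600, list(amplitude = 0, wavelength = 430,
                                    kink_position = 0.72, kink_angle = 25))
  ck <- curvature_profile(tl$midline, smoothing_len = 20)
  L <- tl$midline$arc[length(tl$midline$arc)]
  expect_lt(abs(ck$maxima$s[1] - 0.72 * L), 20)
})

test_that("SCP is invariant under rigid motion and uniform scaling", {
  set.seed(31)
  x <- seq(0, 860, by = 1)
  pts <- cbind(x, 30 * sin(2 * pi * x / 430), 5 * cos(2 * pi * x / 200))
  base <- sinuosity(curve3d(pts))$SCP
  for (rep in 1:5) {
    R <- sarcgeom:::random_rotation()
    tvec <- rnorm(3, 0, 50)
    sc <- runif(1, 0.2, 5)
    moved <- t(R %*% t(pts * sc)) + matrix(tvec, nrow(pts), 3, byrow = TRUE)
    expect_equal(sinuosity(curve3d(moved))$SCP, base,
                 tolerance = 1e-9 * max(1, base))
  }
})

test_that("arc length converges monotonically under densification", {
  f <- function(step) {
    x <- seq(0, 860, by = step)
    sinuosity(curve3d(cbind(x, 30 * sin(2 * pi * x / 430), 0)))
  }
  steps <- c(8, 4, 2, 1, 0.5)
  Cs <- vapply(steps, function(s) f(s)$C, numeric(1))
  expect_true(all(diff(Cs) >= 0))          # refinement never shortens
  scps <- vapply(steps, function(s) f(s)$SCP, numeric(1))
  expect_lt(abs(scps[5] - scps[4]), 1e-4)  # Cauchy under halving
})

test_that("per-crown-class tail SCP pipeline recovers prescribed values", {
  spec <- scene_spec()
  sc <- build_thick_filament(spec)
  # assemble an atomic model from the generated tail chains (CA per residue)
  rows <- list()
  pairs <- list()
  for (cls in names(sc$thick[[1]]$tails)) {
    tl <- sc$thick[[1]]$tails[[cls]]
    idA <- paste0("A", cls); idB <- paste0("B", cls)
    rows[[length(rows) + 1]] <- data.frame(
      chain = idA, resno = seq_len(nrow(tl$chainA)), atom = "CA",
      x = tl$chainA[, 1], y = tl$chainA[, 2], z = tl$chainA[, 3])
    rows[[length(rows) + 1]] <- data.frame(
      chain = idB, resno = seq_len(nrow(tl$chainB)), atom = "CA",
      x = tl$chainB[, 1], y = tl$chainB[, 2], z = tl$chainB[, 3])
    pairs[[cls]] <- c(idA, idB)
  }
  df <- do.call(rbind, rows)
  model <- atom_model(df$chain, df$resno, df$atom, df$x, df$y, df$z)
  res <- tail_scp_by_crown(model, pairs)
  prescribed <- spec$tail_plan$scp_percent
  expect_equal(res$SCP, prescribed[as.integer(res$crown_class)],
               tolerance = 0.02)   # tracing the wound chains, not the truth
})
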