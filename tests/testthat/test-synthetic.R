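test_that("default half thick filament reproduces the lattice census", {
  sc <- build_thick_filament(scene_spec())
  cen <- scene_census(sc)
  expect_equal(cen$n_crowns, 93)          # 31 layers x C3
  expect_equal(cen$n_stripe_anchors, 27)  # 9 stripes x C3
  expect_equal(cen$titin_c_zone, 6)       # alpha + beta
  expect_equal(cen$titin_p_zone, 3)       # alpha only
})

test_that("census identities hold over randomized specs", {
  set.seed(13)
  for (rep in 1:4) {
    n_layers <- sample(6:15, 1)
    n_sym <- sample(2:4, 1)
    spec <- scene_spec(layer_plan = c("P1", "P2", "P3",
                                      paste0("A", seq_len(n_layers - 3))),
                       rotational_symmetry = n_sym, include_tails = FALSE)
    sc <- build_thick_filament(spec)
    cen <- scene_census(sc)
    expect_equal(cen$n_crowns, n_layers * n_sym)
    expect_equal(cen$titin_c_zone,
                 (spec$titin_plan$n_alpha + spec$titin_plan$n_beta))
    expect_equal(cen$titin_p_zone, spec$titin_plan$n_alpha)
  }
})

test_that("generation is deterministic for a fixed seed", {
  spec <- scene_spec(n_thick = 2, noise = list(pos_sd = 1.5, ang_sd = 2),
                     include_tails = FALSE, seed = 9)
  a <- build_sarcomere_scene(spec)
  b <- build_sarcomere_scene(spec)
  expect_identical(scene_crowns(a), scene_crowns(b))
  expect_identical(a$links, b$links)
  # different seed changes the noisy draws
  c_ <- build_sarcomere_scene(scene_spec(n_thick = 2,
                                         noise = list(pos_sd = 1.5,
                                                      ang_sd = 2),
                                         include_tails = FALSE, seed = 10))
  expect_false(identical(scene_crowns(a)$alpha, scene_crowns(c_)$alpha))
})

test_that("noise-free regeneration is bit-identical", {
  a <- build_thick_filament(scene_spec())
  b <- build_thick_filament(scene_spec())
  expect_identical(scene_crowns(a), scene_crowns(b))
})

test_that("crown poses in the ground-truth table are recovered exactly", {
  cr <- scene_crowns(build_thick_filament(scene_spec()))
  p <- crown_pose_table(cr, cylinder_model())
  expect_lt(max(abs(p$alpha - cr$alpha)), 1e-6)
  expect_lt(max(abs(p$beta - cr$beta)), 1e-6)
  expect_lt(max(abs(p$gamma - cr$gamma)), 1e-6)
  expect_lt(max(abs(p$r - cr$r)), 1e-6)
  expect_lt(max(abs(normalize_angle(p$phi - cr$phi))), 1e-6)
  expect_lt(max(abs(p$z - cr$z)), 1e-6)
})

test_that("tail curves honour amplitude, determinism, and kink bounds", {
  straight <- build_tail_curve(500, list(amplitude = 0, wavelength = 430))
  expect_lt(max(abs(straight$midline$points[, 1:2])), 1e-12)

  A <- 25; lam <- 430
  tl <- build_tail_curve(860, list(amplitude = A, wavelength = lam))
  C_oracle <- sine_arclen_quadrature(A, lam, 860)
  # the sine closes two full periods, so the chord L is exactly 860
  scp_oracle <- (C_oracle / 860 - 1) * 100
  expect_equal(tl$scp, scp_oracle, tolerance = 1e-3 * scp_oracle)

  t1 <- build_tail_curve(860, list(amplitude = 20, wavelength = 430), seed = 3)
  t2 <- build_tail_curve(860, list(amplitude = 20, wavelength = 430), seed = 3)
  expect_identical(t1$chainA, t2$chainA)

  expect_error(build_tail_curve(860, list(amplitude = 5, wavelength = 430,
                                          kink_position = 1.2,
                                          kink_angle = 10)),
               "kink_position")
  expect_error(build_tail_curve(-5, list(amplitude = 0, wavelength = 430)),
               "positive")
})

test_that("amplitude_for_scp inverts the sinuosity of the built midline", {
  for (target in c(1.2, 3.05, 4.44)) {
    A <- amplitude_for_scp(target, 1600, 860)
    tl <- build_tail_curve(1600, list(amplitude = A, wavelength = 860))
    expect_equal(tl$scp, target, tolerance = 1e-4)
  }
})

test_that("scene counts, link plan, and mirror symmetry", {
  spec <- scene_spec(n_thick = 3, include_tails = FALSE, seed = 2)
  sc <- build_sarcomere_scene(spec)
  cen <- scene_census(sc)
  expect_equal(cen$n_thick, 3)
  # links per pairing = floor(C-zone span / interval), both halves
  th <- sc$thick[[1]]
  per_pair <- floor((th$z_max - th$z_beta) / spec$link_plan$interval)
  pairings <- 3 * min(spec$thin_lattice$count, cen$n_thin)
  expect_equal(cen$n_links, 2 * pairings * per_pair)

  # mirror: every crown at +z has a counterpart at -z with matching class
  cr <- scene_crowns(sc)
  plus <- cr[!cr$mirrored, ]; minus <- cr[cr$mirrored, ]
  expect_equal(nrow(plus), nrow(minus))
  key <- function(d) paste(d$filament_id, d$layer_label, d$sym_copy,
                           round(abs(d$z), 6))
  expect_setequal(key(plus), key(minus))

  # explicit filament counts are reproduced exactly
  sc2 <- build_sarcomere_scene(scene_spec(n_thick = 53, n_thin = 102,
                                          include_tails = FALSE,
                                          half_sarcomere = TRUE,
                                          link_plan = NULL))
  cen2 <- scene_census(sc2)
  expect_equal(cen2$n_thick, 53)
  expect_equal(cen2$n_thin, 102)
  expect_equal(cen2$thin_thick_quotient, 1.92)
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(axial_repeat = -1), "positive")
  expect_error(scene_spec(noise = list(pos_sd = -1, ang_sd = 0)), ">= 0")
  expect_error(scene_spec(n_repeats = 7), "inconsistent")
  expect_error(scene_spec(bogus_field = 1), "unknown")
  expect_error(build_sarcomere_scene(
    scene_spec(thin_lattice = list(spacing = 240, count = 0))), ">= 1")
})

test_that("scene export writes the ground-truth tables and spec echo", {
  dir <- file.path(tempdir(), "scene_export")
  sc <- build_sarcomere_scene(scene_spec(n_thick = 1, include_tails = FALSE))
  export_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("crowns.tsv", "stripes.tsv", "titin.tsv", "links.tsv",
      "scene_spec.json")))))
  crowns <- read.delim(file.path(dir, "crowns.tsv"))
  expect_equal(nrow(crowns), nrow(scene_crowns(sc)))
  spec_echo <- jsonlite::read_json(file.path(dir, "scene_spec.json"))
  expect_equal(spec_echo$seed, 1)   # seed recorded in output
})

test_that("density rendering conserves intensity and localizes points", {
  pt <- matrix(c(10, 12, 14), 1, 3)
  vol <- density_from_points(pt, voxel = 1, sigma = 2)
  amax <- arrayInd(which.max(vol), dim(vol))
  ctr <- (pt[1, ] - attr(vol, "origin")) / 1 + 1
  expect_true(all(abs(amax - ctr) <= 0.51))

  set.seed(4)
  pts <- matrix(runif(30, 0, 40), 10, 3)
  v2 <- density_from_points(pts, voxel = 1, sigma = 2)
  expect_equal(sum(v2), 10 * (sqrt(2 * pi) * 2)^3, tolerance = 0.01)

  expect_error(density_from_points(pts, voxel = 0.01, sigma = 2,
                                   mem_cap_mb = 1), "memory cap")
  expect_error(density_from_points(pts, voxel = -1, sigma = 2), "positive")
})

test_that("MRC export writes a well-formed mode-2 volume", {
  vol <- density_from_points(matrix(c(0, 0, 0, 10, 10, 10), 2, 3,
                                    byrow = TRUE), voxel = 2, sigma = 2)
  f <- tempfile(fileext = ".mrc")
  write_mrc(vol, f)
  expect_equal(file.size(f), 1024 + 4 * length(vol))
  con <- file(f, "rb")
  dims <- readBin(con, integer(), 3, size = 4, endian = "little")
  mode <- readBin(con, integer(), 1, size = 4, endian = "little")
  close(con)
  expect_equal(dims, dim(vol))
  expect_equal(mode, 2L)
})

test_that("axial projection of the rendered filament shows the 143 A repeat", {
  sc <- build_thick_filament(scene_spec(include_tails = FALSE))
  vol <- render_density(sc, voxel = 4, sigma = 6, mem_cap_mb = 512)
  prof <- apply(vol, 3, sum)
  sp <- axial_power_spectrum(profile = prof, bin = 4, pad_factor = 8)
  expect_equal(sp$dominant_period, 143.3, tolerance = 2)
})
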