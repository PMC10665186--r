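## Synthetic sarcomere generator.
##
## Builds ground-truth half-sarcomere scenes with the statistical structure
## the geometry analyses assume: a three-fold-symmetric thick filament whose
## 430 A axial pseudo-repeat contains three crown classes (layers P1-P3 then
## A1-A28, i.e. 31 levels of 3 heads = 93 interacting-heads motifs), titin
## chains (alpha full length, beta terminating at crown A1, hence six chains
## crossing a C-zone section but three in the P zone), nine cMyBP-C stripes
## (27 anchors), sinusoidally undulating coiled-coil tails of prescribed
## sinuosity, hexagonal thin-filament neighbours, and flexible thick-to-thin
## links at 43-nm intervals. The M band sits at z = 0 and +z is Z-ward;
## every generated pose is recorded in ground-truth tables so downstream
## estimators can be checked against exact truth.

#' Specification of a synthetic sarcomere scene
#'
#' Returns the default scene specification, with any field overridden by a
#' named argument. Defaults encode the canonical relaxed cardiac thick
#' filament: 430 Angstrom axial pseudo-repeat, three crowns per repeat, C3
#' rotational symmetry, 31 crown layers (P1-P3, A1-A28), three full-length
#' titin-alpha and three titin-beta chains ending at crown A1, nine cMyBP-C
#' stripes spaced 430 Angstrom, and thick-to-thin links every 430 Angstrom.
#' Crown-class pose presets (radii, azimuth offsets, Euler angles, landmark
#' triangle edges near 100 Angstrom) are arbitrary but distinct so classes
#' are distinguishable; they are generator conventions, not measured values.
#'
#' @param ... named overrides of any top-level field.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(...) {
  spec <- list(
    axial_repeat = 430,
    crowns_per_repeat = 3,
    rotational_symmetry = 3,
    layer_plan = c("P1", "P2", "P3", paste0("A", 1:28)),
    n_repeats = NULL,                  # derived from layer_plan when NULL
    z_first = 0,                       # axial height of the first layer
    crown_presets = data.frame(
      class = 1:3,
      radius = c(130, 140, 125),
      az_offset = c(0, 20, -15),
      alpha = c(5, -15, 25),
      beta = c(10, 30, -20),
      gamma = c(0, 10, -5)),
    triangle_edges = c(fb = 95, bj = 105, jf = 100),
    titin_plan = list(n_alpha = 3, n_beta = 3, beta_terminates = "A1",
                      radius = 185, az_alpha = 40, az_beta = 100),
    stripe_plan = NULL,                # default: 9 stripes at 430 A spacing
    stripe_radius = 160,
    stripe_azimuth = 60,
    tail_plan = list(
      scp_percent = c(3.05, 4.44, 2.53),  # prescribed per-class sinuosity
      length = 1600,
      wavelength = 860,
      kink_fraction = c(0.556, 0.556, NA),
      kink_angle = c(10, 10, 0),
      superhelix = list(radius = 4.9, pitch = 145)),
    thin_lattice = list(spacing = 240, count = 6),
    link_plan = list(interval = 430, angle_mean = 40, angle_sd = 10,
                     domains_min = 3, domains_max = 4, domain_spacing = 35,
                     radius = 160),
    noise = list(pos_sd = 0, ang_sd = 0),
    n_thick = 1, n_thin = NULL, thick_spacing = 400,
    half_sarcomere = FALSE,
    include_tails = TRUE,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) stop("unknown scene_spec field(s): ",
                            paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  if (spec$axial_repeat <= 0) stop("axial_repeat must be positive")
  if (spec$crowns_per_repeat < 1) stop("crowns_per_repeat must be >= 1")
  if (spec$rotational_symmetry < 1) stop("rotational_symmetry must be >= 1")
  if (spec$noise$pos_sd < 0 || spec$noise$ang_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (!is.null(spec$n_repeats)) {
    expect <- ceiling(length(spec$layer_plan) / spec$crowns_per_repeat)
    if (spec$n_repeats != expect)
      stop("n_repeats (", spec$n_repeats, ") inconsistent with layer_plan (",
           length(spec$layer_plan), " layers -> ", expect, " repeats)")
  }
  invisible(spec)
}

## deterministic per-filament RNG substream
filament_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

## canonical landmark triangle from edge lengths: centroid at the origin and
## its own triangle frame equal to the identity (x toward the free-head
## vertex, z the ordered-loop normal)
canonical_triangle <- function(edges = c(fb = 95, bj = 105, jf = 100)) {
  d_fb <- edges[["fb"]]; d_bj <- edges[["bj"]]; d_jf <- edges[["jf"]]
  if (d_fb + d_bj <= d_jf || d_fb + d_jf <= d_bj || d_bj + d_jf <= d_fb)
    stop("triangle inequality violated by edge lengths")
  p_free <- c(0, 0, 0)
  p_blocked <- c(d_fb, 0, 0)
  xj <- (d_fb^2 + d_jf^2 - d_bj^2) / (2 * d_fb)
  yj <- sqrt(max(0, d_jf^2 - xj^2))
  p_junction <- c(xj, yj, 0)
  tf <- triangle_frame(p_free, p_blocked, p_junction)
  V <- rbind(p_free, p_blocked, p_junction)
  sweep(V, 2, tf$centroid) %*% tf$T    # rows: vertices in the canonical frame
}

## forward pose: place the canonical triangle at cylindrical (phi, r, z) on a
## filament whose axis runs along +z through `origin_xy`, with intrinsic
## Z-Y-X angles (alpha, beta, gamma) in the local cylinder frame
pose_triangle <- function(canon, alpha, beta, gamma, phi, r, z,
                          origin_xy = c(0, 0)) {
  phir <- deg2rad(phi)
  ey <- c(cos(phir), sin(phir), 0)     # radial outward
  ez <- c(0, 0, 1)
  ex <- cross3(ey, ez)                 # tangential
  L <- cbind(ex, ey, ez)
  centroid <- c(origin_xy[1], origin_xy[2], 0) + r * ey + z * ez
  Tg <- L %*% euler_zyx_to_mat(alpha, beta, gamma)
  V <- t(Tg %*% t(canon)) + matrix(centroid, 3, 3, byrow = TRUE)
  rownames(V) <- c("p_free", "p_blocked", "p_junction")
  V
}

## axial position of a labelled layer (z of the layer in the layer plan)
layer_z <- function(spec, label) {
  k <- match(label, spec$layer_plan)
  if (is.na(k)) stop("layer ", label, " not in layer_plan")
  spec$z_first + (k - 1) * spec$axial_repeat / spec$crowns_per_repeat
}

#' Build one synthetic half thick filament
#'
#' Places crown landmark triangles at
#' `z = z_first + layer_index * (axial_repeat / crowns_per_repeat)` with
#' class-specific pose presets, replicated by the Cn rotational symmetry
#' (azimuth preset + 360/n * k); adds titin chains (beta chains truncated at
#' the layer named in `titin_plan$beta_terminates`), cMyBP-C stripe anchors,
#' and per-class coiled-coil tails of prescribed sinuosity. Optional
#' Gaussian noise (positional / angular) perturbs the crown poses. Every
#' generated pose is recorded in the `crowns` ground-truth table.
#'
#' @param spec a [scene_spec()].
#' @param filament_id id token (default "T1").
#' @param origin_xy lattice position of the filament axis (Angstrom).
#' @return a `sarco_scene` containing this single filament.
#' @export
build_thick_filament <- function(spec = scene_spec(), filament_id = "T1",
                                 origin_xy = c(0, 0)) {
  validate_scene_spec(spec)
  n_sym <- spec$rotational_symmetry
  layers <- spec$layer_plan
  spacing <- spec$axial_repeat / spec$crowns_per_repeat
  canon <- canonical_triangle(spec$triangle_edges)
  set.seed(filament_seed(spec$seed, match(filament_id, filament_id)))

  rows <- vector("list", length(layers) * n_sym)
  i <- 0
  for (k in seq_along(layers)) {
    cls <- ((k - 1) %% spec$crowns_per_repeat) + 1
    preset <- spec$crown_presets[spec$crown_presets$class == cls, ]
    if (nrow(preset) == 0) stop("no crown preset for class ", cls)
    z0 <- spec$z_first + (k - 1) * spacing
    for (j in seq_len(n_sym) - 1) {
      i <- i + 1
      ang_n <- if (spec$noise$ang_sd > 0) stats::rnorm(3, 0, spec$noise$ang_sd)
               else c(0, 0, 0)
      pos_n <- if (spec$noise$pos_sd > 0) stats::rnorm(2, 0, spec$noise$pos_sd)
               else c(0, 0)
      alpha <- preset$alpha + ang_n[1]
      beta <- preset$beta + ang_n[2]
      gamma <- preset$gamma + ang_n[3]
      phi <- normalize_angle(preset$az_offset + j * 360 / n_sym)
      r <- preset$radius + pos_n[1]
      z <- z0 + pos_n[2]
      V <- pose_triangle(canon, alpha, beta, gamma, phi, r, z, origin_xy)
      rows[[i]] <- data.frame(
        filament_id = filament_id, layer_index = k, layer_label = layers[k],
        crown_class = cls, sym_copy = j, mirrored = FALSE,
        alpha = alpha, beta = beta, gamma = gamma, phi = phi, r = r, z = z,
        p_free_x = V[1, 1], p_free_y = V[1, 2], p_free_z = V[1, 3],
        p_blocked_x = V[2, 1], p_blocked_y = V[2, 2], p_blocked_z = V[2, 3],
        p_junction_x = V[3, 1], p_junction_y = V[3, 2],
        p_junction_z = V[3, 3],
        stringsAsFactors = FALSE)
    }
  }
  crowns <- do.call(rbind, rows)

  z_max <- spec$z_first + (length(layers) - 1) * spacing + spacing / 2
  z_beta <- layer_z(spec, spec$titin_plan$beta_terminates)

  ## titin polylines: straight chains on the filament surface
  titin <- list()
  tp <- spec$titin_plan
  for (j in seq_len(tp$n_alpha) - 1) {
    az <- deg2rad(tp$az_alpha + j * 360 / n_sym)
    xy <- origin_xy + tp$radius * c(cos(az), sin(az))
    titin[[length(titin) + 1]] <- list(
      id = paste0(filament_id, ".titinA", j + 1), type = "alpha",
      points = cbind(xy[1], xy[2], seq(0, z_max, by = 50)),
      zmin = 0, zmax = z_max)
  }
  for (j in seq_len(tp$n_beta) - 1) {
    az <- deg2rad(tp$az_beta + j * 360 / n_sym)
    xy <- origin_xy + tp$radius * c(cos(az), sin(az))
    titin[[length(titin) + 1]] <- list(
      id = paste0(filament_id, ".titinB", j + 1), type = "beta",
      points = cbind(xy[1], xy[2], seq(z_beta, z_max, by = 50)),
      zmin = z_beta, zmax = z_max)
  }

  ## cMyBP-C stripes: default nine, anchored on crown-2 layers at 430 A
  ## spacing through the C zone
  sp <- spec$stripe_plan
  if (is.null(sp)) {
    k2 <- which(((seq_along(layers) - 1) %% spec$crowns_per_repeat) + 1 == 2)
    k2 <- k2[k2 > match(tp$beta_terminates, layers)][1:9]
    k2 <- k2[!is.na(k2)]
    sp <- data.frame(label = paste0("S", seq_along(k2)),
                     z = spec$z_first + (k2 - 1) * spacing)
  }
  srows <- list()
  for (s in seq_len(nrow(sp))) {
    for (j in seq_len(n_sym) - 1) {
      az <- deg2rad(spec$stripe_azimuth + j * 360 / n_sym)
      srows[[length(srows) + 1]] <- data.frame(
        filament_id = filament_id, stripe = sp$label[s], sym_copy = j,
        x = origin_xy[1] + spec$stripe_radius * cos(az),
        y = origin_xy[2] + spec$stripe_radius * sin(az),
        z = sp$z[s], stringsAsFactors = FALSE)
    }
  }
  stripes <- do.call(rbind, srows)

  ## per-class representative tails of prescribed sinuosity
  tails <- list()
  if (isTRUE(spec$include_tails)) {
    tpl <- spec$tail_plan
    for (cls in seq_len(spec$crowns_per_repeat)) {
      kf <- tpl$kink_fraction[cls]
      tails[[as.character(cls)]] <- build_tail_curve(
        length = tpl$length,
        midline_profile = list(
          amplitude = amplitude_for_scp(
            tpl$scp_percent[cls], tpl$length, tpl$wavelength,
            kink_fraction = kf, kink_angle = tpl$kink_angle[cls]),
          wavelength = tpl$wavelength,
          kink_position = if (is.na(kf)) NULL else kf,
          kink_angle = tpl$kink_angle[cls]),
        superhelix = tpl$superhelix,
        seed = filament_seed(spec$seed, 100 + cls))
    }
  }

  trace <- filament_trace(filament_id,
                          cbind(origin_xy[1], origin_xy[2],
                                seq(0, z_max, by = 50)),
                          polarity = 1L)
  structure(list(spec = spec, m_band_z = 0,
                 thick = list(list(filament_id = filament_id,
                                   origin_xy = origin_xy, trace = trace,
                                   crowns = crowns, titin = titin,
                                   stripes = stripes, tails = tails,
                                   z_beta = z_beta, z_max = z_max)),
                 thin = list(), links = NULL, link_domains = NULL),
            class = "sarco_scene")
}

#' Tail midline amplitude that yields a prescribed SCP
#'
#' Solves (by `uniroot` on the generated ground-truth midline) for the sine
#' amplitude giving the requested sinusoidal compression percentage at the
#' stated tail length, undulation wavelength and optional kink.
#'
#' @param scp_target target SCP in percent (>= 0).
#' @param length,wavelength tail axial extent and undulation wavelength, A.
#' @param kink_fraction,kink_angle optional kink position (fraction of
#'   length) and angle (degrees).
#' @return amplitude in Angstrom.
#' @export
amplitude_for_scp <- function(scp_target, length, wavelength,
                              kink_fraction = NA, kink_angle = 0) {
  if (scp_target < 0) stop("scp_target must be >= 0")
  f <- function(A) {
    m <- tail_midline(length, A, wavelength,
                      kink_position = if (is.na(kink_fraction)) NULL
                                      else kink_fraction,
                      kink_angle = kink_angle)
    sinuosity(curve3d(m))$SCP - scp_target
  }
  if (f(0) >= 0) return(0)            # kink alone already meets the target
  upper <- wavelength / 2
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

## ground-truth midline: sine in the x-z plane, optional kink rotating the
## distal part about the lateral y axis at the kink point
tail_midline <- function(length, amplitude, wavelength, kink_position = NULL,
                         kink_angle = 0, step = 2) {
  z <- seq(0, length, by = step)
  if (z[length(z)] < length) z <- c(z, length)
  pts <- cbind(amplitude * sin(2 * pi * z / wavelength), 0, z)
  if (!is.null(kink_position)) {
    if (kink_position <= 0 || kink_position >= 1)
      stop("kink_position must lie strictly inside (0, 1)")
    zk <- kink_position * length
    R <- rot_y(kink_angle)
    distal <- z > zk
    xk <- amplitude * sin(2 * pi * zk / wavelength)
    pivot <- c(xk, 0, zk)
    pts[distal, ] <- t(R %*% (t(pts[distal, , drop = FALSE]) - pivot) + pivot)
  }
  pts
}

#' Build a synthetic coiled-coil tail
#'
#' Generates two chains winding about a prescribed midline (a sine of given
#' amplitude and wavelength in a lateral plane, with an optional kink) at
#' the coiled-coil superhelical radius and pitch, sampled at the canonical
#' 1.485 Angstrom per-residue axial rise. The exact ground-truth midline is
#' returned alongside the chains for oracle comparisons.
#'
#' @param length tail extent along its axis, Angstrom (> 0).
#' @param midline_profile list with `amplitude` (A), `wavelength` (A),
#'   optional `kink_position` (fraction in (0,1)) and `kink_angle` (deg).
#' @param superhelix list with `radius` and `pitch` in Angstrom.
#' @param seed integer; the construction is deterministic, the seed is
#'   recorded for provenance.
#' @return list with `chainA`, `chainB` (n x 3 matrices), `midline` (a
#'   [curve3d()]), the achieved ground-truth `scp`, and the input parameters.
#' @export
build_tail_curve <- function(length,
                             midline_profile = list(amplitude = 0,
                                                    wavelength = 430),
                             superhelix = list(radius = 4.9, pitch = 145),
                             seed = 1) {
  if (length <= 0) stop("length must be positive")
  amp <- midline_profile$amplitude
  wav <- midline_profile$wavelength
  if (is.null(wav) || wav <= 0) stop("wavelength must be positive")
  kp <- midline_profile$kink_position
  ka <- if (is.null(midline_profile$kink_angle)) 0
        else midline_profile$kink_angle
  mid_raw <- tail_midline(length, amp, wav, kink_position = kp,
                          kink_angle = ka, step = 2)
  mid <- curve3d(mid_raw)
  ## per-residue sampling along arc length
  rs <- resample_curve(mid, 1.485)
  P <- rs$points; n <- nrow(P)
  ## tangents by central differences; lateral reference y is perpendicular
  ## to the undulation plane, so it never degenerates
  tang <- rbind(P[2, ] - P[1, ],
                P[3:n, , drop = FALSE] - P[1:(n - 2), , drop = FALSE],
                P[n, ] - P[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  yref <- c(0, 1, 0)
  chainA <- chainB <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    t_ <- tang[i, ]
    nvec <- unit_vec(yref - sum(yref * t_) * t_, "midline normal")
    bvec <- cross3(t_, nvec)
    th <- 2 * pi * rs$s[i] / superhelix$pitch
    off <- superhelix$radius * (cos(th) * nvec + sin(th) * bvec)
    chainA[i, ] <- P[i, ] + off
    chainB[i, ] <- P[i, ] - off
  }
  list(chainA = chainA, chainB = chainB, midline = mid,
       scp = sinuosity(mid)$SCP,
       params = list(length = length, amplitude = amp, wavelength = wav,
                     kink_position = kp, kink_angle = ka,
                     superhelix = superhelix, seed = seed))
}

## mirror a scene's components about the M-band plane z = 0
mirror_scene <- function(scene) {
  for (f in seq_along(scene$thick)) {
    th <- scene$thick[[f]]
    cr <- th$crowns
    zcols <- grep("(_z$|^z$)", names(cr), value = TRUE)
    mc <- cr
    for (col in zcols) mc[[col]] <- -mc[[col]]
    mc$mirrored <- TRUE
    th$crowns <- rbind(cr, mc)
    ms <- th$stripes; ms$z <- -ms$z
    th$stripes <- rbind(th$stripes, ms)
    th$titin <- c(th$titin, lapply(th$titin, function(tc) {
      tc$points[, 3] <- -tc$points[, 3]
      tc$points <- tc$points[rev(seq_len(nrow(tc$points))), , drop = FALSE]
      zr <- range(-c(tc$zmin, tc$zmax))
      tc$zmin <- zr[1]; tc$zmax <- zr[2]
      tc$id <- paste0(tc$id, ".m")
      tc
    }))
    pts <- th$trace$points
    pts <- rbind(cbind(pts[rev(seq_len(nrow(pts)))[-nrow(pts)], 1:2,
                           drop = FALSE],
                       -rev(pts[, 3])[-nrow(pts)]),
                 pts)
    th$trace <- filament_trace(th$filament_id, pts, polarity = 1L)
    scene$thick[[f]] <- th
  }
  ## thin filaments span both halves: extend each trace through the M band
  scene$thin <- lapply(scene$thin, function(tr) {
    pts <- tr$points
    neg <- pts[rev(seq_len(nrow(pts)))[-nrow(pts)], , drop = FALSE]
    neg[, 3] <- -neg[, 3]
    filament_trace(tr$filament_id, rbind(neg, pts), polarity = 1L)
  })
  if (!is.null(scene$links)) {
    ml <- scene$links
    ml$pivot_z <- -ml$pivot_z; ml$terminal_z <- -ml$terminal_z
    ml$z_anchor <- -ml$z_anchor
    ## relative to the fixed Z-ward axis the mirrored link points the other
    ## way: its unfolded angle is the supplement
    ml$angle_true <- 180 - ml$angle_true
    ml$link_id <- paste0(ml$link_id, ".m")
    md <- scene$link_domains
    md$z <- -md$z
    md$link_id <- paste0(md$link_id, ".m")
    scene$links <- rbind(scene$links, ml)
    scene$link_domains <- rbind(scene$link_domains, md)
  }
  scene
}

## hexagonal-ish lattice sites: origin, then rings of 6
lattice_sites <- function(n, spacing) {
  sites <- matrix(0, 1, 2)
  ring <- 1
  while (nrow(sites) < n) {
    for (k in seq_len(6 * ring) - 1) {
      ## walk the hexagonal ring
      corner <- k %/% ring
      step_i <- k %% ring
      a0 <- deg2rad(60 * corner)
      a1 <- deg2rad(60 * (corner + 2))
      p <- ring * spacing * c(cos(a0), sin(a0)) +
        step_i * spacing * c(cos(a1), sin(a1))
      sites <- rbind(sites, p)
    }
    ring <- ring + 1
  }
  sites[seq_len(n), , drop = FALSE]
}

#' Build a synthetic sarcomere scene
#'
#' Thick filaments are placed on a triangular lattice; each gets the full
#' [build_thick_filament()] content (tails on the first filament only).
#' Thin-filament neighbours are generated hexagonally around the thick
#' lattice (deduplicated; truncated or extended to `n_thin` when given) and
#' thick-to-thin links are drawn every `link_plan$interval` Angstrom through
#' the C zone with angles from the prescribed normal distribution. Unless
#' `half_sarcomere = TRUE` the scene is mirrored about the M-band plane.
#'
#' @param spec a [scene_spec()].
#' @return a `sarco_scene`.
#' @export
build_sarcomere_scene <- function(spec = scene_spec()) {
  validate_scene_spec(spec)
  if (!is.null(spec$link_plan) && !is.null(spec$thin_lattice) &&
      spec$thin_lattice$count < 1)
    stop("thin_lattice count must be >= 1 when links are requested")
  set.seed(spec$seed)
  thick_xy <- lattice_sites(spec$n_thick, spec$thick_spacing)
  scene <- NULL
  for (i in seq_len(spec$n_thick)) {
    sp_i <- spec
    sp_i$include_tails <- spec$include_tails && i == 1
    fil <- build_thick_filament(sp_i, filament_id = paste0("T", i),
                                origin_xy = thick_xy[i, ])
    if (is.null(scene)) scene <- fil
    else scene$thick <- c(scene$thick, fil$thick)
  }
  scene$spec <- spec

  ## thin neighbours: hexagonal positions around every thick filament,
  ## rotated 30 degrees off the thick lattice directions, deduplicated
  tl <- spec$thin_lattice
  cand <- NULL
  for (i in seq_len(spec$n_thick)) {
    az <- deg2rad(30 + 60 * (seq_len(tl$count) - 1))
    cand <- rbind(cand, cbind(thick_xy[i, 1] + tl$spacing * cos(az),
                              thick_xy[i, 2] + tl$spacing * sin(az)))
  }
  cand <- unique(round(cand, 3))
  n_thin <- if (is.null(spec$n_thin)) nrow(cand) else spec$n_thin
  while (nrow(cand) < n_thin) {
    ## extend with further rings around the origin until enough sites exist
    extra <- lattice_sites(nrow(cand) + n_thin, tl$spacing)
    extra <- sweep(extra, 2, c(tl$spacing / 2, tl$spacing / 3), "+")
    cand <- unique(round(rbind(cand, extra), 3))
  }
  cand <- cand[seq_len(n_thin), , drop = FALSE]
  z_max <- scene$thick[[1]]$z_max
  scene$thin <- lapply(seq_len(n_thin), function(i)
    filament_trace(paste0("t", i),
                   cbind(cand[i, 1], cand[i, 2], seq(0, z_max, by = 50)),
                   polarity = 1L))

  ## thick-to-thin links through the C zone
  lp <- spec$link_plan
  if (!is.null(lp) && n_thin > 0) {
    links <- list(); doms <- list()
    thin_xy <- cand
    for (i in seq_len(spec$n_thick)) {
      th <- scene$thick[[i]]
      d2 <- colSums((t(thin_xy) - th$origin_xy)^2)
      nb <- order(d2)[seq_len(min(tl$count, n_thin))]
      span <- th$z_max - th$z_beta
      n_link <- floor(span / lp$interval)
      if (n_link < 1) next
      for (j in nb) {
        u_xy <- unit_vec(c(thin_xy[j, ] - th$origin_xy, 0), "link direction")
        for (l in seq_len(n_link)) {
          z_anchor <- th$z_beta + (l - 1) * lp$interval
          pivot <- c(th$origin_xy + lp$radius * u_xy[1:2], z_anchor)
          theta <- stats::rnorm(1, lp$angle_mean, lp$angle_sd)
          dirv <- sin(deg2rad(theta)) * u_xy + cos(deg2rad(theta)) * c(0, 0, 1)
          n_dom <- sample(lp$domains_min:lp$domains_max, 1)
          id <- sprintf("%s.%s.L%02d", th$filament_id,
                        scene$thin[[j]]$filament_id, l)
          dp <- t(vapply(seq_len(n_dom), function(d)
            pivot + d * lp$domain_spacing * dirv, numeric(3)))
          links[[length(links) + 1]] <- data.frame(
            link_id = id, thick_id = th$filament_id,
            thin_id = scene$thin[[j]]$filament_id,
            z_anchor = z_anchor, angle_true = theta, n_domains = n_dom,
            pivot_x = pivot[1], pivot_y = pivot[2], pivot_z = pivot[3],
            terminal_x = dp[n_dom, 1], terminal_y = dp[n_dom, 2],
            terminal_z = dp[n_dom, 3], stringsAsFactors = FALSE)
          doms[[length(doms) + 1]] <- data.frame(
            link_id = id, domain_index = seq_len(n_dom),
            x = dp[, 1], y = dp[, 2], z = dp[, 3], stringsAsFactors = FALSE)
        }
      }
    }
    scene$links <- do.call(rbind, links)
    scene$link_domains <- do.call(rbind, doms)
  }

  if (!isTRUE(spec$half_sarcomere)) scene <- mirror_scene(scene)
  scene
}

#' Ground-truth crown table of a scene
#'
#' @param scene a `sarco_scene`.
#' @return data.frame of all generated crown poses and landmark vertices.
#' @export
scene_crowns <- function(scene) {
  do.call(rbind, lapply(scene$thick, function(th) th$crowns))
}

#' Export a scene's ground truth as plain-text tables
#'
#' Writes `crowns.tsv`, `stripes.tsv`, `titin.tsv`, `links.tsv` (when
#' present), per-filament traces as native particle tables, and the
#' generating spec as JSON (`scene_spec.json`).
#'
#' @param scene a `sarco_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(scene_crowns(scene), file.path(dir, "crowns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stripes <- do.call(rbind, lapply(scene$thick, function(th) th$stripes))
  utils::write.table(stripes, file.path(dir, "stripes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  titin <- do.call(rbind, lapply(scene$thick, function(th)
    do.call(rbind, lapply(th$titin, function(tc)
      data.frame(id = tc$id, type = tc$type, zmin = tc$zmin, zmax = tc$zmax,
                 stringsAsFactors = FALSE)))))
  utils::write.table(titin, file.path(dir, "titin.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(scene$links))
    utils::write.table(scene$links, file.path(dir, "links.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  spec <- unclass(scene$spec)
  spec$crown_presets <- as.list(spec$crown_presets)
  jsonlite::write_json(spec, file.path(dir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Render a coarse density volume from scene landmarks
#'
#' Sums isotropic Gaussian blobs at every crown landmark, stripe anchor and
#' titin node on a regular grid; intended as a quick visual or spectral
#' fixture, not a realistic tomogram.
#'
#' @param scene a `sarco_scene`.
#' @param voxel voxel edge in Angstrom (> 0).
#' @param sigma Gaussian sigma in Angstrom.
#' @param mem_cap_mb refuse grids above this memory footprint (default 256).
#' @return 3D array with attributes `voxel` and `origin`.
#' @export
render_density <- function(scene, voxel, sigma, mem_cap_mb = 256) {
  if (voxel <= 0) stop("voxel must be positive")
  cr <- scene_crowns(scene)
  pts <- rbind(as.matrix(cr[, c("p_free_x", "p_free_y", "p_free_z")]),
               as.matrix(cr[, c("p_blocked_x", "p_blocked_y",
                                "p_blocked_z")]),
               as.matrix(cr[, c("p_junction_x", "p_junction_y",
                                "p_junction_z")]))
  colnames(pts) <- c("x", "y", "z")
  for (th in scene$thick) {
    pts <- rbind(pts, as.matrix(th$stripes[, c("x", "y", "z")]))
    for (tc in th$titin) {
      p <- tc$points
      colnames(p) <- c("x", "y", "z")
      pts <- rbind(pts, p)
    }
  }
  density_from_points(pts, voxel, sigma, mem_cap_mb)
}

#' Gaussian-blob density from a point cloud
#'
#' @param pts n x 3 matrix of Angstrom coordinates.
#' @param voxel voxel edge in Angstrom.
#' @param sigma Gaussian sigma in Angstrom.
#' @param mem_cap_mb memory cap for the grid (default 256).
#' @return 3D array with attributes `voxel` and `origin`.
#' @export
density_from_points <- function(pts, voxel, sigma, mem_cap_mb = 256) {
  if (voxel <= 0) stop("voxel must be positive")
  pts <- as.matrix(pts)
  pad <- 4 * sigma
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  if (prod(dims) * 8 / 2^20 > mem_cap_mb)
    stop("grid of ", paste(dims, collapse = "x"),
         " voxels exceeds the memory cap; use a larger voxel")
  vol <- array(0, dims)
  reach <- ceiling(4 * sigma / voxel)
  for (i in seq_len(nrow(pts))) {
    c_idx <- (pts[i, ] - lo) / voxel + 1
    i0 <- pmax(1L, floor(c_idx) - reach)
    i1 <- pmin(dims, ceiling(c_idx) + reach)
    xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
    gx <- exp(-((xs - c_idx[1]) * voxel)^2 / (2 * sigma^2))
    gy <- exp(-((ys - c_idx[2]) * voxel)^2 / (2 * sigma^2))
    gz <- exp(-((zs - c_idx[3]) * voxel)^2 / (2 * sigma^2))
    vol[xs, ys, zs] <- vol[xs, ys, zs] + outer(gx, outer(gy, gz))
  }
  attr(vol, "voxel") <- voxel
  attr(vol, "origin") <- lo
  vol
}

#' Write a density array as an MRC (mode 2) volume
#'
#' Minimal single-volume MRC2014 writer (32-bit float voxels, standard
#' 1024-byte header).
#'
#' @param vol 3D array from [render_density()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  dims <- dim(vol)
  voxel <- attr(vol, "voxel"); if (is.null(voxel)) voxel <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                      # nx ny nz
  wi(2)                         # mode 2: float32
  wi(c(0, 0, 0))                # nxstart
  wi(dims)                      # mx my mz
  wf(dims * voxel)              # cell dimensions, A
  wf(c(90, 90, 90))             # cell angles
  wi(c(1, 2, 3))                # axis order
  wf(c(min(vol), max(vol), mean(vol)))
  wi(c(1, 0))                   # ispg, nsymbt
  writeBin(raw(100), con)       # extra
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(vol)))
  wi(0)                         # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}
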