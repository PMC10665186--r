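## Axial periodicity spectra, pixel-size calibration, thick-to-thin
## link-angle measurement, and scene census statistics.

#' Axial power spectrum of impulse positions or a 1D profile
#'
#' Impulse positions are binned onto a regular grid (bin width at most 2
#' Angstrom), the mean is subtracted, and the discrete Fourier power is
#' computed with zero padding by `pad_factor`. The dominant period is taken
#' from the largest peak after excluding DC and periods above
#' `box_length / 2`, refined by three-point parabolic interpolation in
#' log-power.
#'
#' @param z_positions impulse positions along the axis (Angstrom); give
#'   either this or `profile`.
#' @param profile numeric vector of equally spaced 1D density samples.
#' @param box_length axial extent in Angstrom; defaults to the position
#'   span (impulses) or `length(profile) * bin` (profile).
#' @param bin grid spacing in Angstrom for impulse binning (default 1,
#'   must be <= 2).
#' @param pad_factor zero-padding multiple (default 8).
#' @return a `spectrum` list: `period` (Angstrom, descending), `power`,
#'   `dominant_period`, `dominant_period_bins` (uninterpolated), `peak_index`.
#' @export
axial_power_spectrum <- function(z_positions = NULL, profile = NULL,
                                 box_length = NULL, bin = 1, pad_factor = 8) {
  if (is.null(z_positions) == is.null(profile))
    stop("give exactly one of z_positions or profile")
  if (!is.null(z_positions)) {
    if (length(unique(round(z_positions, 6))) < 2)
      stop("fewer than 2 distinct positions; no periodicity defined")
    if (length(z_positions) < 4) stop("need at least 4 impulses")
    if (bin > 2) stop("bin must be <= 2 Angstrom")
    z <- z_positions - min(z_positions)
    if (is.null(box_length)) box_length <- max(z) + bin
    if (box_length <= 0) stop("box_length must be positive")
    n <- max(4L, as.integer(ceiling(box_length / bin)))
    idx <- pmin(n, pmax(1L, as.integer(floor(z / bin)) + 1L))
    prof <- tabulate(idx, nbins = n)
  } else {
    if (length(profile) < 4) stop("need at least 4 profile samples")
    prof <- as.numeric(profile)
    n <- length(prof)
    if (is.null(box_length)) box_length <- n * bin
    bin <- box_length / n
  }
  x <- prof - mean(prof)
  if (max(abs(x)) < 1e-12) stop("constant profile: no periodicity (no peak)")
  npad <- as.integer(length(x) * max(1, pad_factor))
  pw <- Mod(stats::fft(c(x, numeric(npad - length(x)))))^2
  k <- seq_len(npad %/% 2)                  # positive-frequency bins, k>=1
  period <- npad * bin / k
  pw <- pw[k + 1]
  valid <- period <= box_length / 2
  if (!any(valid)) stop("no valid spectral band below box_length / 2")
  pk <- which(valid)[which.max(pw[valid])]
  ## parabolic refinement in log-power
  kref <- k[pk]
  if (pk > 1 && pk < length(k) && pw[pk - 1] > 0 && pw[pk + 1] > 0) {
    la <- log(pw[pk - 1]); lb <- log(pw[pk]); lc <- log(pw[pk + 1])
    denom <- la - 2 * lb + lc
    if (abs(denom) > 1e-12) kref <- k[pk] + 0.5 * (la - lc) / denom
  }
  structure(list(period = period, power = pw,
                 dominant_period = npad * bin / kref,
                 dominant_period_bins = npad * bin / k[pk],
                 peak_index = pk, bin = bin, box_length = box_length),
            class = "axial_spectrum")
}

#' Calibrate the pixel size against a reference axial period
#'
#' Given a period measured in pixels from a power spectrum and the known
#' physical repeat (the 143.3 Angstrom myosin quasi-repeat by default),
#' returns Angstrom per pixel.
#'
#' @param measured_period_px measured period in pixels (> 0).
#' @param reference_period_A physical period in Angstrom (default 143.3).
#' @return Angstrom per pixel.
#' @export
calibrate_pixel_size <- function(measured_period_px,
                                 reference_period_A = 143.3) {
  if (measured_period_px <= 0 || reference_period_A <= 0)
    stop("periods must be positive")
  reference_period_A / measured_period_px
}

#' Angle of a thick-to-thin link relative to the filament axis
#'
#' Measures the angle between the vector from the pivot (the C7 domain
#' position) to the terminal (thin-filament-proximal) domain point and the
#' thick-filament axis direction. Unfolded range [0, 180] (180 only for the
#' exactly antiparallel case); with `fold = TRUE` angles are folded to
#' [0, 90].
#'
#' @param pivot pivot point (Angstrom).
#' @param domain_points matrix of ordered domain positions (>= 1 row); the
#'   last row is the terminal domain.
#' @param cylinder the thick filament's [cylinder_model()].
#' @param fold fold to [0, 90]? Default `FALSE`.
#' @return angle in degrees.
#' @export
link_angle <- function(pivot, domain_points, cylinder, fold = FALSE) {
  domain_points <- matrix(as.numeric(domain_points), ncol = 3)
  v <- domain_points[nrow(domain_points), ] - as.numeric(pivot)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("zero-length link vector")
  a <- rad2deg(acos(max(-1, min(1, sum(v / nv * cylinder$axis_direction)))))
  if (fold && a > 90) a <- 180 - a
  a
}

#' Link angles for a scene's ground-truth links
#'
#' Measures every link in a `sarco_scene` against its thick filament's axis
#' (the generated axis, along +z).
#'
#' @param scene a `sarco_scene` with links.
#' @param fold fold angles to [0, 90]? Default `FALSE`.
#' @return the scene's links data.frame with an `angle_measured` column.
#' @export
scene_link_angles <- function(scene, fold = FALSE) {
  if (is.null(scene$links)) stop("scene has no links")
  links <- scene$links
  cyl <- cylinder_model()
  links$angle_measured <- vapply(seq_len(nrow(links)), function(i) {
    dom <- scene$link_domains[scene$link_domains$link_id == links$link_id[i],
                              c("x", "y", "z")]
    link_angle(c(links$pivot_x[i], links$pivot_y[i], links$pivot_z[i]),
               as.matrix(dom), cyl, fold = fold)
  }, numeric(1))
  links
}

#' Histogram and summary of link angles
#'
#' @param angles numeric vector of link angles in degrees (>= 1).
#' @param bin_width histogram bin width in degrees (default 5).
#' @return list with `histogram` (data.frame `bin_lo, bin_hi, count`) and
#'   `summary` (`n`, `mean`, `sd`, `circular_caveat`): the summary uses
#'   plain linear statistics, flagged because angles near the 0/180 wrap
#'   would need circular treatment.
#' @export
link_angle_distribution <- function(angles, bin_width = 5) {
  if (length(angles) < 1) stop("need at least one link angle")
  breaks <- seq(0, 180 + bin_width, by = bin_width)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(histogram = data.frame(bin_lo = utils::head(h$breaks, -1),
                              bin_hi = h$breaks[-1], count = h$counts),
       summary = list(n = length(angles), mean = mean(angles),
                      sd = stats::sd(angles),
                      circular_caveat = any(angles < 10 | angles > 170)))
}

#' Census of a synthetic scene
#'
#' Raw composition counts of a `sarco_scene`: thick and thin filaments, the
#' thin:thick quotient (3 significant figures), crown (IHM) count, cMyBP-C
#' stripe anchors, titin chains crossing a C-zone and a P-zone cross
#' section, link count, and the sarcomere length (Z-plane to Z-plane, um)
#' when both Z planes are given.
#'
#' @param scene a `sarco_scene`.
#' @param z_planes optional `c(z_minus, z_plus)` positions of the two Z
#'   discs (Angstrom).
#' @return list of counts and derived quantities.
#' @export
scene_census <- function(scene, z_planes = NULL) {
  crowns <- scene_crowns(scene)
  stripes <- do.call(rbind, lapply(scene$thick, function(th) th$stripes))
  th1 <- scene$thick[[1]]
  z_c <- (th1$z_beta + th1$z_max) / 2          # representative C-zone height
  z_p <- th1$z_beta / 2                        # representative P-zone height
  titin_cross <- function(zq) sum(vapply(scene$thick, function(th)
    sum(vapply(th$titin, function(tc) tc$zmin <= zq && zq <= tc$zmax,
               logical(1))), numeric(1)))
  n_thick <- length(scene$thick)
  n_thin <- length(scene$thin)
  out <- list(
    n_thick = n_thick,
    n_thin = n_thin,
    thin_thick_quotient = if (n_thick > 0)
      signif(n_thin / n_thick, 3) else NA_real_,
    n_crowns = nrow(crowns),
    n_stripe_anchors = if (is.null(stripes)) 0L else nrow(stripes),
    titin_c_zone = titin_cross(z_c),
    titin_p_zone = titin_cross(z_p),
    n_links = if (is.null(scene$links)) 0L else nrow(scene$links))
  if (!is.null(z_planes)) {
    if (length(z_planes) != 2) stop("z_planes must give both Z-disc heights")
    out$sarcomere_length_um <- abs(diff(z_planes)) / 1e4
  }
  out
}
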