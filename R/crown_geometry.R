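## Crown-pose quantification.
##
## The thick filament is modelled as a cylinder and each interacting-heads
## motif (IHM) as a triangle whose vertices are three landmark sites: the
## ATP-binding site of the free head, the same site of the blocked head, and
## the head-tail junction. The pose of a crown is the orientation of that
## triangle in a local cylinder frame erected at the triangle centroid
## (x tangential, y radial outward, z along the cylinder axis), reported as
## intrinsic Z-Y-X Euler angles (alpha, beta, gamma), plus the cylindrical
## coordinates of the centroid (azimuth phi, radius r, axial height z).

#' Construct a cylinder model
#'
#' @param axis_point a point on the axis (Angstrom).
#' @param axis_direction axis direction; normalized internally. By convention
#'   it points Z-ward (away from the M band).
#' @param radius optional nominal radius in Angstrom.
#' @return a `cylinder_model` object.
#' @export
cylinder_model <- function(axis_point = c(0, 0, 0),
                           axis_direction = c(0, 0, 1), radius = NULL) {
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = unit_vec(as.numeric(axis_direction),
                                           "axis direction"),
                 radius = radius),
            class = "cylinder_model")
}

#' Fit a filament axis by total least squares
#'
#' The axis is the principal direction of the centered point cloud (first
#' eigenvector of the covariance), passing through the centroid — the
#' total-least-squares line. The direction sign is chosen so the dot product
#' with `polarity_hint` is positive.
#'
#' If the cloud has no dominant direction (ratio of first to second singular
#' value below `anisotropy_min`) the result carries attribute
#' `warning = "low anisotropy"`.
#'
#' @param points a `point_set` or n x 3 matrix (n >= 2, not all coincident).
#' @param polarity_hint direction whose half-space the returned axis points
#'   into (default `c(0, 0, 1)`, Z-ward).
#' @param anisotropy_min singular-value ratio below which the fit is flagged
#'   (default 1.5).
#' @return a [cylinder_model()] with `radius` set to the RMS distance of the
#'   points from the fitted line.
#' @export
fit_filament_axis <- function(points, polarity_hint = c(0, 0, 1),
                              anisotropy_min = 1.5) {
  X <- if (inherits(points, "point_set")) point_matrix(points)
       else as.matrix(points)
  if (nrow(X) < 2) stop("axis fit needs at least 2 points")
  ctr <- colMeans(X)
  C <- sweep(X, 2, ctr)
  if (max(abs(C)) < 1e-9) stop("all points coincident; no axis defined")
  sv <- svd(C)
  dir <- sv$v[, 1]
  if (sum(dir * polarity_hint) < 0) dir <- -dir
  ## radial scatter about the fitted line
  proj <- C %*% dir
  radial <- C - proj %*% t(dir)
  out <- cylinder_model(axis_point = ctr, axis_direction = dir,
                        radius = sqrt(mean(rowSums(radial^2))))
  if (sv$d[2] > 0 && sv$d[1] / sv$d[2] < anisotropy_min)
    attr(out, "warning") <- "low anisotropy: no dominant axis"
  out
}

## local cylinder frame at a point: columns (x tangential, y radial, z axial)
## plus cylindrical coordinates of the point
local_cylinder_frame <- function(cylinder, point, r_tol = 1e-6) {
  ez <- cylinder$axis_direction
  d <- point - cylinder$axis_point
  zh <- sum(d * ez)
  radial <- d - zh * ez
  r <- sqrt(sum(radial^2))
  if (r < r_tol) stop("point lies on the cylinder axis; azimuth undefined")
  ey <- radial / r                       # radial, outward
  ex <- cross3(ey, ez)                   # tangential; ex x ey = ez
  ## azimuth measured in a fixed frame perpendicular to the axis
  ref <- perp_reference(ez)
  phi <- rad2deg(atan2(sum(radial * ref$v), sum(radial * ref$u)))
  list(L = cbind(ex, ey, ez), phi = phi, r = r, z = zh)
}

## deterministic orthonormal pair (u, v) perpendicular to axis direction ez,
## defining phi = 0 along u; u is the projection of the global x axis (or y
## axis when ez is parallel to x)
perp_reference <- function(ez) {
  seed <- c(1, 0, 0)
  if (abs(sum(seed * ez)) > 1 - 1e-8) seed <- c(0, 1, 0)
  u <- unit_vec(seed - sum(seed * ez) * ez, "reference")
  v <- cross3(ez, u)
  list(u = u, v = v)
}

## triangle frame: e1 toward p_free from the centroid, e3 the unit normal of
## the ordered vertex loop (free -> blocked -> junction), e2 = e3 x e1
triangle_frame <- function(p_free, p_blocked, p_junction, area_tol = 1e-6) {
  ctr <- (p_free + p_blocked + p_junction) / 3
  n_raw <- cross3(p_blocked - p_free, p_junction - p_free)
  area <- sqrt(sum(n_raw^2)) / 2
  if (area < area_tol) stop("degenerate landmark triangle (area ~ 0)")
  e3 <- n_raw / (2 * area)
  e1 <- unit_vec(p_free - ctr, "centroid-to-free-head vector")
  e2 <- cross3(e3, e1)
  list(T = cbind(e1, e2, e3), centroid = ctr, area = area)
}

#' Pose of one crown from its IHM landmark triangle
#'
#' Builds the local cylinder frame at the triangle centroid (x tangential,
#' y radial outward, z axial), the canonical triangle frame (x toward the
#' free-head landmark, z the ordered-loop normal), and reports the rotation
#' local-frame -> triangle-frame as intrinsic Z-Y-X Euler angles together
#' with the centroid's cylindrical coordinates.
#'
#' @param p_free,p_blocked,p_junction landmark coordinates (Angstrom): the
#'   ATP-binding site of the free head, the same site of the blocked head,
#'   and the head-tail junction.
#' @param cylinder a [cylinder_model()].
#' @param crown_class optional class label carried into the result.
#' @return a one-row data.frame with columns
#'   `alpha, beta, gamma, phi, r, z, crown_class, gimbal`.
#' @export
crown_pose <- function(p_free, p_blocked, p_junction, cylinder,
                       crown_class = NA) {
  tf <- triangle_frame(as.numeric(p_free), as.numeric(p_blocked),
                       as.numeric(p_junction))
  lf <- local_cylinder_frame(cylinder, tf$centroid)
  R <- t(lf$L) %*% tf$T
  ang <- mat_to_euler_zyx(R)
  data.frame(alpha = ang[["alpha"]], beta = ang[["beta"]],
             gamma = ang[["gamma"]], phi = normalize_angle(lf$phi),
             r = lf$r, z = lf$z, crown_class = crown_class,
             gimbal = isTRUE(attr(ang, "gimbal")),
             stringsAsFactors = FALSE)
}

#' Crown poses for a table of landmark triples
#'
#' @param landmarks data.frame with columns `p_free_x/y/z`, `p_blocked_x/y/z`,
#'   `p_junction_x/y/z` and optionally `crown_class`.
#' @param cylinder a [cylinder_model()].
#' @return data.frame of poses, one row per landmark triple.
#' @export
crown_pose_table <- function(landmarks, cylinder) {
  need <- as.vector(outer(c("p_free", "p_blocked", "p_junction"),
                          c("x", "y", "z"), paste, sep = "_"))
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) stop("landmark table missing column(s): ",
                         paste(miss, collapse = ", "))
  cls <- if ("crown_class" %in% names(landmarks)) landmarks$crown_class
         else rep(NA, nrow(landmarks))
  rows <- lapply(seq_len(nrow(landmarks)), function(i) {
    crown_pose(
      p_free = c(landmarks$p_free_x[i], landmarks$p_free_y[i],
                 landmarks$p_free_z[i]),
      p_blocked = c(landmarks$p_blocked_x[i], landmarks$p_blocked_y[i],
                    landmarks$p_blocked_z[i]),
      p_junction = c(landmarks$p_junction_x[i], landmarks$p_junction_y[i],
                     landmarks$p_junction_z[i]),
      cylinder = cylinder, crown_class = cls[i])
  })
  do.call(rbind, rows)
}

#' Per-class pose summaries with helical rise and twist
#'
#' Crowns are sorted by axial height z; within each crown class, consecutive
#' same-class differences define the class's axial rise (delta z) and twist
#' (delta phi, unwrapped to (-180, 180]). When several symmetry-related
#' copies share one axial level, differences are taken between successive
#' distinct levels (mean z gap > `level_tol`), pairing copies by nearest
#' azimuth.
#'
#' @param poses data.frame from [crown_pose_table()] (needs columns
#'   `alpha, beta, gamma, phi, r, z, crown_class`).
#' @param level_tol Angstrom; z gap below which poses count as one axial
#'   level (default 1).
#' @return data.frame with one row per crown class: n, circular means/sds of
#'   the angles, mean/sd radius, mean/sd rise (Angstrom) and twist (degrees);
#'   classes with a single axial level have `NA` rise/twist and
#'   `flag = "single-level"`.
#' @export
crown_series_stats <- function(poses, level_tol = 1) {
  if (nrow(poses) < 2) stop("need at least 2 poses")
  out <- lapply(split(poses, poses$crown_class), function(p) {
    p <- p[order(p$z), , drop = FALSE]
    ## group symmetry copies into axial levels
    lvl <- cumsum(c(TRUE, diff(p$z) > level_tol))
    levels_z <- tapply(p$z, lvl, mean)
    rise <- twist <- numeric(0)
    if (length(levels_z) >= 2) {
      for (i in seq_len(length(levels_z) - 1)) {
        a <- p[lvl == i, , drop = FALSE]
        b <- p[lvl == i + 1, , drop = FALSE]
        ## pair each copy in level i with the nearest-azimuth copy in i+1
        for (j in seq_len(nrow(a))) {
          dphi <- normalize_angle(b$phi - a$phi[j])
          k <- which.min(abs(dphi))
          rise <- c(rise, b$z[k] - a$z[j])
          twist <- c(twist, dphi[k])
        }
      }
    }
    data.frame(crown_class = p$crown_class[1], n = nrow(p),
               alpha_mean = circ_mean(p$alpha), alpha_sd = circ_sd(p$alpha),
               beta_mean = circ_mean(p$beta), beta_sd = circ_sd(p$beta),
               gamma_mean = circ_mean(p$gamma), gamma_sd = circ_sd(p$gamma),
               r_mean = mean(p$r), r_sd = stats::sd(p$r),
               rise_mean = if (length(rise)) mean(rise) else NA_real_,
               rise_sd = if (length(rise) > 1) stats::sd(rise) else NA_real_,
               twist_mean = if (length(twist)) circ_mean(twist) else NA_real_,
               twist_sd = if (length(twist) > 1) circ_sd(twist) else NA_real_,
               flag = if (length(levels_z) < 2) "single-level" else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

circ_mean <- function(deg) {
  t <- deg2rad(deg)
  normalize_angle(rad2deg(atan2(mean(sin(t)), mean(cos(t)))))
}

circ_sd <- function(deg) {
  if (length(deg) < 2) return(NA_real_)
  ## sd of deviations from the circular mean (adequate for the small angular
  ## spreads of crown poses)
  m <- circ_mean(deg)
  stats::sd(normalize_angle(deg - m))
}

#' Assign crown classes from axial position
#'
#' Each pose is assigned the class whose axial offset is nearest to
#' `z mod repeat` (circular distance modulo the repeat). Ties break toward
#' the lower class index and are flagged ambiguous.
#'
#' @param poses pose data.frame with column `z`.
#' @param repeat_A axial pseudo-repeat in Angstrom (default 430).
#' @param class_offsets axial offsets of the classes within one repeat
#'   (Angstrom), distinct modulo the repeat; default `c(0, 143.3, 286.7)`.
#' @return `poses` with `crown_class` (integer index into `class_offsets`),
#'   `class_dist` (Angstrom) and `class_ambiguous` columns filled.
#' @export
classify_crowns <- function(poses, repeat_A = 430,
                            class_offsets = c(0, 143.3, 286.7)) {
  off <- class_offsets %% repeat_A
  if (anyDuplicated(round(off, 9)))
    stop("class offsets must be distinct modulo the repeat")
  zmod <- poses$z %% repeat_A
  d <- outer(zmod, off, function(a, b) {
    dd <- abs(a - b) %% repeat_A
    pmin(dd, repeat_A - dd)
  })
  cls <- apply(d, 1, which.min)      # which.min takes the first (lower) index
  best <- d[cbind(seq_len(nrow(d)), cls)]
  nties <- rowSums(abs(d - best) < 1e-9)
  poses$crown_class <- as.integer(cls)
  poses$class_dist <- best
  poses$class_ambiguous <- nties > 1
  poses
}

#' Unroll crown positions from the cylinder onto a plane
#'
#' Maps each pose to planar coordinates `(s, z)` with
#' `s = r_ref * phi_radians`, the isometric cylinder-to-plane development at
#' the reference radius; relative azimuthal order is preserved.
#'
#' @param poses pose data.frame with columns `phi`, `z`.
#' @param r_ref reference radius in Angstrom (> 0); default the mean pose
#'   radius.
#' @return `poses` with columns `s` (Angstrom) and `r_ref` added.
#' @export
unroll_poses <- function(poses, r_ref = NULL) {
  if (is.null(r_ref)) r_ref <- mean(poses$r)
  if (!is.numeric(r_ref) || r_ref <= 0) stop("r_ref must be positive")
  poses$s <- r_ref * deg2rad(poses$phi)
  poses$r_ref <- r_ref
  poses
}

#' Inverse of [unroll_poses()]
#'
#' @param unrolled data.frame with columns `s`, `z`, `r_ref`.
#' @return data.frame with columns `phi` (degrees) and `z`.
#' @export
reroll_poses <- function(unrolled) {
  data.frame(phi = normalize_angle(rad2deg(unrolled$s / unrolled$r_ref)),
             z = unrolled$z)
}
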