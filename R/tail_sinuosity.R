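## Coiled-coil midline tracing and the sinuosity statistic.
##
## A myosin tail is a two-chain coiled coil; its midline is the 3D curve
## through the midpoints of paired alpha-carbons. Sinuosity S is the curve
## length C over the end-to-end distance L, and the sinusoidal compression
## percentage is SCP = (S - 1) * 100. Arc length is the plain polyline sum
## over the traced midpoints; no spline smoothing is applied (resampling
## happens only inside the curvature profile).

#' Construct a 3D curve
#'
#' @param points n x 3 matrix of Angstrom coordinates, n >= 2, consecutive
#'   points distinct.
#' @return a `curve3d` object with cumulative arc length.
#' @export
curve3d <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a curve needs at least 2 points")
  if (!all(is.finite(points))) stop("non-finite curve coordinates")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("consecutive curve points must be distinct")
  structure(list(points = points, arc = c(0, cumsum(seg))),
            class = "curve3d")
}

#' Midline of a coiled coil from its two chains
#'
#' Pairs alpha-carbon i of chain A with alpha-carbon i + k of chain B
#' (`offset = k`, default 0), truncated to the common index range; the
#' midline point for each couple is the midpoint of the pair.
#'
#' @param chainA,chainB `point_set`s or n x 3 matrices in sequence order.
#' @param offset integer pairing offset k.
#' @return a [curve3d()] midline.
#' @export
coiled_coil_midline <- function(chainA, chainB, offset = 0L) {
  A <- if (inherits(chainA, "point_set")) point_matrix(chainA)
       else as.matrix(chainA)
  B <- if (inherits(chainB, "point_set")) point_matrix(chainB)
       else as.matrix(chainB)
  ## couple (A_i, B_{i+k}) over the common range
  iA <- seq_len(nrow(A))
  iB <- iA + as.integer(offset)
  keep <- iB >= 1 & iB <= nrow(B)
  if (sum(keep) < 2)
    stop("fewer than 2 alpha-carbon couples after pairing; check offset")
  curve3d((A[iA[keep], , drop = FALSE] + B[iB[keep], , drop = FALSE]) / 2)
}

## sub-curve between arc positions [s0, s1], interpolating the end points
curve_window <- function(curve, s0, s1) {
  arc <- curve$arc; pts <- curve$points
  L <- arc[length(arc)]
  if (s0 < -1e-9 || s1 > L + 1e-9 || s1 <= s0)
    stop("window [", s0, ", ", s1, "] outside curve extent [0, ", L, "]")
  s0 <- max(0, s0); s1 <- min(L, s1)
  at <- function(s) {
    i <- findInterval(s, arc, rightmost.closed = TRUE)
    i <- max(1, min(i, nrow(pts) - 1))
    t_ <- (s - arc[i]) / (arc[i + 1] - arc[i])
    pts[i, ] + t_ * (pts[i + 1, ] - pts[i, ])
  }
  inner <- which(arc > s0 & arc < s1)
  curve3d(rbind(at(s0), pts[inner, , drop = FALSE], at(s1)))
}

#' Sinuosity and sinusoidal compression percentage of a curve
#'
#' `C` is the polyline arc length of the (windowed) curve, `L` the Euclidean
#' distance between its ends, `S = C / L`, `SCP = (S - 1) * 100` (percent).
#'
#' @param curve a [curve3d()].
#' @param window optional `c(start, end)` arc-length interval in Angstrom.
#' @param min_L minimum end-to-end distance in Angstrom below which the
#'   statistic is refused as unstable (default 1).
#' @return a one-row data.frame `C, L, S, SCP, window_start, window_end`.
#' @export
sinuosity <- function(curve, window = NULL, min_L = 1) {
  stopifnot(inherits(curve, "curve3d"))
  if (!is.null(window)) curve <- curve_window(curve, window[1], window[2])
  C <- curve$arc[length(curve$arc)]
  ends <- curve$points[c(1, nrow(curve$points)), ]
  L <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  if (L < min_L)
    stop("end-to-end distance ", format(L), " A below ", min_L,
         " A; sinuosity unstable for (near-)closed curves")
  S <- C / L
  data.frame(C = C, L = L, S = S, SCP = (S - 1) * 100,
             window_start = if (is.null(window)) 0 else window[1],
             window_end = if (is.null(window)) C else window[2])
}

#' Sliding-window SCP profile along a curve
#'
#' Windows of arc length `window_len` advanced by `step`; the final window is
#' anchored at the curve end so the whole curve is covered.
#'
#' @param curve a [curve3d()].
#' @param window_len window length in Angstrom (<= curve length).
#' @param step window advance in Angstrom (> 0).
#' @return data.frame of [sinuosity()] rows, one per window.
#' @export
scp_profile <- function(curve, window_len, step) {
  stopifnot(inherits(curve, "curve3d"))
  if (step <= 0) stop("step must be positive")
  L <- curve$arc[length(curve$arc)]
  if (window_len > L + 1e-9) stop("window_len exceeds curve length")
  starts <- seq(0, L - window_len, by = step)
  if (length(starts) == 0 || max(starts) < L - window_len - 1e-9)
    starts <- unique(c(starts, L - window_len))
  out <- lapply(starts, function(s0)
    sinuosity(curve, window = c(s0, s0 + window_len)))
  do.call(rbind, out)
}

## resample a curve at equal arc spacing (linear interpolation on the
## polyline); keeps both end points
resample_curve <- function(curve, spacing) {
  L <- curve$arc[length(curve$arc)]
  s <- unique(c(seq(0, L, by = spacing), L))
  pts <- t(vapply(s, function(si) {
    arc <- curve$arc
    i <- findInterval(si, arc, rightmost.closed = TRUE)
    i <- max(1, min(i, nrow(curve$points) - 1))
    t_ <- (si - arc[i]) / (arc[i + 1] - arc[i])
    curve$points[i, ] + t_ * (curve$points[i + 1, ] - curve$points[i, ])
  }, numeric(3)))
  list(points = pts, s = s)
}

#' Discrete curvature profile with located maxima
#'
#' The curve is resampled at equal arc spacing `smoothing_len`; curvature at
#' each interior sample is the inverse radius of the circle through it and
#' its two neighbours (`kappa = 4 * area / (a * b * c)`). Local maxima whose
#' curvature exceeds `prominence` times the median curvature are reported
#' with their arc positions.
#'
#' @param curve a [curve3d()] with >= 3 points.
#' @param smoothing_len resampling arc spacing in Angstrom; must exceed the
#'   median raw point spacing.
#' @param prominence multiple of the median curvature a maximum must reach
#'   (default 2).
#' @return list with `profile` (data.frame `s`, `curvature` in 1/Angstrom)
#'   and `maxima` (data.frame `s`, `curvature`, ordered by curvature).
#' @export
curvature_profile <- function(curve, smoothing_len, prominence = 2) {
  stopifnot(inherits(curve, "curve3d"))
  if (nrow(curve$points) < 3) stop("curvature needs at least 3 points")
  spac <- diff(curve$arc)
  if (smoothing_len < stats::median(spac))
    stop("smoothing_len smaller than the median point spacing (",
         format(stats::median(spac)), " A)")
  rs <- resample_curve(curve, smoothing_len)
  P <- rs$points; n <- nrow(P)
  if (n < 3) stop("curve too short for the requested smoothing_len")
  kappa <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    a <- P[i - 1, ]; b <- P[i, ]; c_ <- P[i + 1, ]
    ab <- sqrt(sum((b - a)^2)); bc <- sqrt(sum((c_ - b)^2))
    ac <- sqrt(sum((c_ - a)^2))
    area <- sqrt(sum(cross3(b - a, c_ - a)^2)) / 2
    kappa[i - 1] <- 4 * area / (ab * bc * ac)
  }
  s_mid <- rs$s[2:(n - 1)]
  prof <- data.frame(s = s_mid, curvature = kappa)
  thr <- prominence * stats::median(kappa)
  is_max <- which(kappa > thr &
                  kappa >= c(-Inf, kappa[-length(kappa)]) &
                  kappa >= c(kappa[-1], -Inf))
  maxima <- prof[is_max, , drop = FALSE]
  maxima <- maxima[order(-maxima$curvature), , drop = FALSE]
  rownames(maxima) <- NULL
  list(profile = prof, maxima = maxima)
}

#' Per-crown-class tail SCP from an atomic model
#'
#' For each crown class, extracts the alpha-carbons of the two tail chains,
#' traces the coiled-coil midline and computes the whole-tail sinuosity —
#' the per-class tail-compression analysis applied to a thick-filament
#' atomic model.
#'
#' @param model an [atom_model()].
#' @param chain_pairs named list mapping a crown-class label to a character
#'   vector of the two chain ids of that class's tail coiled coil.
#' @param atom landmark atom name traced along each chain (default `"CA"`).
#' @param offset residue pairing offset passed to [coiled_coil_midline()].
#' @return data.frame with one row per class: `crown_class, n_couples, C, L,
#'   S, SCP`.
#' @export
tail_scp_by_crown <- function(model, chain_pairs, atom = "CA", offset = 0L) {
  stopifnot(is.list(chain_pairs), length(chain_pairs) >= 1)
  rows <- lapply(names(chain_pairs), function(cls) {
    chains <- chain_pairs[[cls]]
    if (length(chains) != 2)
      stop("class ", cls, ": need exactly two chain ids")
    A <- select_atoms(model, chain = chains[1], atom = atom)
    B <- select_atoms(model, chain = chains[2], atom = atom)
    mid <- coiled_coil_midline(A, B, offset = offset)
    s <- sinuosity(mid)
    data.frame(crown_class = cls, n_couples = nrow(mid$points),
               C = s$C, L = s$L, S = s$S, SCP = s$SCP,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
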