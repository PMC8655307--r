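#' Five-segment sagittal rigid-link model of the standing rat
#'
#' Inertial model used for all marker-based analyses. Each segment (foot,
#' leg, lower trunk, upper trunk, head) is a line between two of the nine
#' sagittal landmarks, with its mass given as a percentage of body mass and
#' its centre of mass placed `Ls` percent along the segment line from the
#' proximal end plus `Lv` percent of the segment length perpendicular to it.
#' Positive `Lv` displaces the segment CoM ventrally (toward the animal's
#' front face of the segment line); the head's negative `Lv` therefore
#' displaces dorsally. Foot and leg have `Lv = 0` (linear segments).
#'
#' The default values are the measured inertial parameters (mass 1/9/53/29/8
#' percent, Ls 32/68/18/40/33 percent, Lv 0/0/33/10/-7 percent); hindlimb
#' segments count both limbs.
#'
#' @param table optionally a replacement data frame with the same columns.
#' @return A data frame of class `segment_model` with columns `segment`,
#'   `mass_pct`, `ls_pct`, `lv_pct`, `proximal`, `distal`.
#' @export
segment_model <- function(table = NULL) {
  sm <- table %||% data.frame(
    segment  = c("foot", "leg", "lower_trunk", "upper_trunk", "head"),
    mass_pct = c(1, 9, 53, 29, 8),
    ls_pct   = c(32, 68, 18, 40, 33),
    lv_pct   = c(0, 0, 33, 10, -7),
    proximal = c("mtp", "malleolus", "iliac_crest", "mid_trunk", "tmj"),
    distal   = c("malleolus", "trochanter", "mid_trunk", "scapula", "nose"),
    stringsAsFactors = FALSE)
  need <- c("segment", "mass_pct", "ls_pct", "lv_pct", "proximal", "distal")
  if (!all(need %in% names(sm))) stop_bad_arg("segment model lacks columns")
  if (abs(sum(sm$mass_pct) - 100) > 1e-9)
    stop_bad_arg("segment mass percentages must sum to 100")
  structure(sm, class = c("segment_model", "data.frame"))
}

#' The nine sagittal landmarks
#' @return Character vector of landmark names in proximal-to-distal order.
#' @export
landmark_names <- function() {
  c("mtp", "malleolus", "knee", "trochanter", "iliac_crest",
    "scapula", "mid_trunk", "tmj", "nose")
}

#' Sagittal marker time series
#'
#' Validates and wraps marker coordinates: one row per frame, columns `t`
#' plus `<landmark>_x`, `<landmark>_y` in meters (x forward, y up), sampled
#' uniformly (nominally 200 Hz).
#'
#' @param frames a data frame as described above.
#' @return The data frame with class `marker_frames` and attribute `fs`.
#' @export
marker_frames <- function(frames) {
  if (!"t" %in% names(frames)) stop_bad_arg("marker frames need a column t")
  miss <- setdiff(c(paste0(landmark_names(), "_x"), paste0(landmark_names(), "_y")),
                  names(frames))
  if (length(miss))
    stop_bad_arg("missing landmark columns: ", paste(miss, collapse = ", "))
  dts <- diff(frames$t)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-9))
    stop_bad_arg("marker frames must be uniformly sampled")
  attr(frames, "fs") <- 1 / dts[1]
  class(frames) <- unique(c("marker_frames", class(frames)))
  frames
}

#' Zero-phase low-pass smoothing of marker trajectories
#'
#' Forward-backward Butterworth filtering of every coordinate column (the
#' effective attenuation is the squared magnitude response; the pass band is
#' phase-free). Defaults: 15 Hz cutoff, 4th order.
#'
#' @param frames a [marker_frames()] object.
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order filter order.
#' @return Smoothed `marker_frames`.
#' @export
smooth_markers <- function(frames, cutoff = 15, order = 4) {
  frames <- marker_frames(frames)
  fs <- attr(frames, "fs")
  if (cutoff >= fs / 2)
    stop_bad_arg("cutoff must be below the Nyquist frequency (", fs / 2, " Hz)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  cols <- setdiff(names(frames), "t")
  for (cc in cols) frames[[cc]] <- signal::filtfilt(bf, frames[[cc]])
  frames
}

marker_xy <- function(frames, name) {
  cbind(frames[[paste0(name, "_x")]], frames[[paste0(name, "_y")]])
}

segment_com_xy <- function(frames, model, i) {
  p <- marker_xy(frames, model$proximal[i])
  d <- marker_xy(frames, model$distal[i])
  v <- d - p
  len <- sqrt(rowSums(v^2))
  bad <- which(len < 1e-12)
  if (length(bad))
    stop_bad_arg("zero-length ", model$segment[i], " segment at frame ", bad[1])
  nrm <- cbind(v[, 2], -v[, 1])  # ventral (forward) unit normal, scaled by len
  p + (model$ls_pct[i] / 100) * v + (model$lv_pct[i] / 100) * nrm
}

body_com_xy <- function(frames, model) {
  w <- model$mass_pct / 100
  com <- matrix(0, nrow(frames), 2)
  for (i in seq_len(nrow(model)))
    com <- com + w[i] * segment_com_xy(frames, model, i)
  com
}

#' Centre-of-mass angle from marker kinematics
#'
#' Whole-body CoM from the mass-weighted segment CoMs, then the angle of the
#' MTP-to-CoM vector from the vertical, backward rotation positive.
#'
#' @param frames a [marker_frames()] object.
#' @param model a [segment_model()].
#' @return Numeric vector of angles, rad, one per frame.
#' @export
com_angle <- function(frames, model = segment_model()) {
  frames <- marker_frames(frames)
  com <- body_com_xy(frames, model)
  mtp <- marker_xy(frames, "mtp")
  atan2(-(com[, 1] - mtp[, 1]), com[, 2] - mtp[, 2])
}

#' Segment angles from the vertical
#'
#' Angle of each segment line (proximal to distal marker) from the vertical,
#' backward rotation positive.
#'
#' @inheritParams com_angle
#' @return A matrix, frames x segments, rad.
#' @export
segment_angles <- function(frames, model = segment_model()) {
  frames <- marker_frames(frames)
  out <- sapply(seq_len(nrow(model)), function(i) {
    p <- marker_xy(frames, model$proximal[i])
    d <- marker_xy(frames, model$distal[i])
    v <- d - p
    if (any(rowSums(v^2) < 1e-24))
      stop_bad_arg("zero-length ", model$segment[i], " segment")
    atan2(-v[, 1], v[, 2])
  })
  colnames(out) <- model$segment
  out
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Contribution of segment rotations to the CoM-angle change
#'
#' For each segment `i` the per-frame integrand
#' `(m_i / M) * cos(angle(r, r_i)) * omega_i` is integrated (trapezoidal
#' rule) over the analysis window, where `m_i` is the mass of the body part
#' above segment `i` (the segment itself and everything more cranial), `r`
#' the vector from the MTP marker to the whole-body CoM, `r_i` the vector
#' from the lower-end (proximal) marker of segment `i` to the CoM of the
#' body part above it, and `omega_i` the segment's angular velocity (central
#' differences on the unwrapped segment angle, one-sided at the window
#' edges). The underlying picture is that the body above the segment of
#' interest is rigid and rotates about the segment's lower end.
#'
#' `omega = "joint"` (default) uses the segment's rotation relative to the
#' segment below (relative, i.e. joint, angular velocity; the foot rotates
#' relative to the ground), under which the per-segment effects of a chain
#' motion add up to the CoM-angle change whenever the rigid-above-joint
#' picture holds. `omega = "segment"` uses the segment's absolute angular
#' velocity instead.
#'
#' @inheritParams com_angle
#' @param segment segment names or indices; default all five.
#' @param window integration window `c(from, to)` in seconds, default the
#'   first 0.3 s after tilt onset.
#' @param omega `"joint"` or `"segment"` angular velocity (see Details).
#' @return Named numeric vector of effects in degrees.
#' @export
segment_effect <- function(frames, model = segment_model(), segment = NULL,
                           window = c(0, 0.3), omega = c("joint", "segment")) {
  omega <- match.arg(omega)
  frames <- marker_frames(frames)
  t <- frames$t
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9)
    stop_bad_arg("analysis window lies outside the recording")
  dt <- 1 / attr(frames, "fs")
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)

  ang <- segment_angles(frames, model)
  ang <- apply(ang, 2, function(a) as.numeric(signal::unwrap(a)))
  om <- apply(ang, 2, central_diff, dt = dt)
  if (omega == "joint")
    om <- om - cbind(0, om[, -ncol(om), drop = FALSE])

  mtp <- marker_xy(frames, "mtp")
  com <- body_com_xy(frames, model)
  r <- com - mtp

  segs <- segment %||% model$segment
  if (is.numeric(segs)) segs <- model$segment[segs]
  w <- model$mass_pct / 100
  out <- sapply(segs, function(sname) {
    i <- match(sname, model$segment)
    if (is.na(i)) stop_bad_arg("unknown segment: ", sname)
    above <- i:nrow(model)
    mi <- sum(w[above])
    # CoM of the body part above segment i (mass-weighted)
    up <- matrix(0, nrow(frames), 2)
    for (j in above) up <- up + (w[j] / mi) * segment_com_xy(frames, model, j)
    ri <- up - marker_xy(frames, model$proximal[i])
    cosang <- rowSums(r * ri) / (sqrt(rowSums(r^2)) * sqrt(rowSums(ri^2)))
    integrand <- mi * cosang * om[, i]
    y <- integrand[idx]
    sum((y[-1] + y[-length(y)]) / 2) * dt * 180 / pi
  })
  setNames(as.numeric(out), segs)
}
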