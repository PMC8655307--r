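# A rigid upright chain and simple prescribed motions built with the
# forward-kinematics generator serve as geometric fixtures throughout.

test_that("zero-phase smoothing preserves the pass band and kills the stop band", {
  t <- seq(0, 2, by = 1 / 200)
  base <- synth_marker_motion(t_range = c(0, 2))
  # constant signals pass unchanged (DC gain 1)
  sm <- smooth_markers(base)
  expect_equal(sm$nose_x, base$nose_x, tolerance = 1e-12)
  # 1 Hz component preserved within 1%, 50 Hz attenuated below 1%
  f <- base
  f$nose_x <- sin(2 * pi * 1 * t)
  f$nose_y <- sin(2 * pi * 50 * t)
  sf <- smooth_markers(marker_frames(f))
  mid <- t > 0.4 & t < 1.6
  expect_equal(max(abs(sf$nose_x[mid])), 1, tolerance = 0.01)
  expect_lt(max(abs(sf$nose_y[mid])), 0.01)
  expect_error(smooth_markers(base, cutoff = 120), "Nyquist")
})

test_that("segment angles follow the vertical-datum, backward-positive convention", {
  fr <- synth_marker_motion()      # upright chain, all angles zero
  ang <- segment_angles(fr)
  expect_equal(max(abs(ang)), 0, tolerance = 1e-12)
  # 10 deg backward rotation reproduced exactly from constructed markers
  a10 <- 10 * pi / 180
  fr10 <- synth_marker_motion(angle_fns = list(
    foot = function(t) rep(a10, length(t)),
    leg = function(t) rep(a10, length(t)),
    lower_trunk = function(t) rep(a10, length(t)),
    upper_trunk = function(t) rep(a10, length(t)),
    head = function(t) rep(a10, length(t))))
  expect_equal(as.numeric(segment_angles(fr10)), rep(a10, 5 * nrow(fr10)),
               tolerance = 1e-9)
  # horizontal backward-pointing segment sits at +pi/2
  f2 <- as.data.frame(fr)
  f2$malleolus_x <- f2$mtp_x - 0.02
  f2$malleolus_y <- f2$mtp_y
  expect_equal(segment_angles(marker_frames(f2))[1, "foot"], pi / 2,
               ignore_attr = TRUE)
})

test_that("CoM angle agrees with hand-computed weighted geometry", {
  fr <- synth_marker_motion()
  # straight-line model (Lv = 0): CoM lies on the vertical through the MTP
  straight <- segment_model()
  straight$lv_pct[] <- 0
  expect_equal(max(abs(com_angle(fr, straight))), 0, tolerance = 1e-12)
  # rigid 45 deg backward lean of the whole chain: angle pi/4
  a45 <- pi / 4
  fr45 <- synth_marker_motion(angle_fns = sapply(
    c("foot", "leg", "lower_trunk", "upper_trunk", "head"),
    function(s) function(t) rep(a45, length(t)), simplify = FALSE))
  expect_equal(unique(round(com_angle(fr45, straight), 12)), a45,
               tolerance = 1e-9)
  # two-segment toy with hand-placed markers and hand-computed answer
  toy <- segment_model(data.frame(
    segment = c("foot", "leg"), mass_pct = c(40, 60),
    ls_pct = c(50, 50), lv_pct = c(0, 0),
    proximal = c("mtp", "malleolus"), distal = c("malleolus", "knee"),
    stringsAsFactors = FALSE))
  f <- as.data.frame(synth_marker_motion(t_range = c(0, 0.05)))
  f$mtp_x <- 0; f$mtp_y <- 0
  f$malleolus_x <- 0; f$malleolus_y <- 0.10          # foot CoM (0, 0.05)
  f$knee_x <- -0.10; f$knee_y <- 0.10                # leg CoM (-0.05, 0.10)
  # weighted CoM = 0.4*(0,0.05) + 0.6*(-0.05,0.10) = (-0.03, 0.08)
  expect_equal(unique(com_angle(marker_frames(f), toy)), atan2(0.03, 0.08),
               tolerance = 1e-12)
  # invariance to uniform translation of every marker
  gx <- grep("_x$", names(f)); gy <- grep("_y$", names(f))
  f2 <- f; f2[gx] <- f2[gx] + 1.23; f2[gy] <- f2[gy] - 0.77
  expect_equal(com_angle(marker_frames(f2), toy), com_angle(marker_frames(f), toy),
               tolerance = 1e-12)
})

test_that("segment effects vanish without motion and scale linearly in omega", {
  fr <- synth_marker_motion(t_range = c(-0.1, 0.4))
  expect_equal(max(abs(segment_effect(fr))), 0, tolerance = 1e-12)
  lean <- function(rate) {
    fns <- sapply(c("foot", "leg", "lower_trunk", "upper_trunk", "head"),
                  function(s) function(t) rate * pmax(t, 0), simplify = FALSE)
    synth_marker_motion(angle_fns = fns, t_range = c(-0.1, 0.4))
  }
  w <- 10 * pi / 180
  e1 <- segment_effect(lean(w))
  e2 <- segment_effect(lean(2 * w))
  expect_equal(e2, 2 * e1, tolerance = 1e-6)
})

test_that("rigid whole-body rotation: foot effect is the CoM-angle change", {
  # whole chain rotates about the MTP at 10 deg/s; above the MTP joint the
  # body is rigid, so the foot term carries the entire whole-body mass and
  # its integrand reduces to the rotation rate: 3.0 deg over 0.3 s
  w <- 10 * pi / 180
  fns <- sapply(c("foot", "leg", "lower_trunk", "upper_trunk", "head"),
                function(s) function(t) w * t, simplify = FALSE)
  fr <- synth_marker_motion(angle_fns = fns, t_range = c(-0.1, 0.4))
  eff <- segment_effect(fr)
  expect_equal(unname(eff["foot"]), 3.0, tolerance = 1e-6)
  # joint-velocity convention: only the foot joint moves, the sum equals
  # the CoM-angle change to within discretization error
  th <- com_angle(fr)
  idx <- which(fr$t >= -1e-9 & fr$t <= 0.3 + 1e-9)
  dcom <- (th[max(idx)] - th[min(idx)]) * 180 / pi
  expect_equal(sum(eff), dcom, tolerance = 0.005 * abs(dcom))
  # absolute segment velocities overcount on purpose (every segment rotates)
  eff_abs <- segment_effect(fr, omega = "segment")
  expect_gt(sum(eff_abs), sum(eff) * 2)
})

test_that("multi-joint motion: summed effects track the CoM-angle change", {
  # foot-dominated motion with slower joint rotations above, the pattern a
  # backward tilt evokes; each body part above a moving joint stays rigid
  # during most of the motion
  deg <- pi / 180
  foot <- function(t) 25 * deg * t
  leg <- function(t) 25 * deg * t + 5 * deg * pmax(t - 0.05, 0)
  trunk <- function(t) leg(t)
  fns <- list(foot = foot, leg = leg, lower_trunk = trunk,
              upper_trunk = trunk, head = trunk)
  fr <- synth_marker_motion(angle_fns = fns, t_range = c(-0.1, 0.4))
  eff <- segment_effect(fr)
  th <- com_angle(fr)
  idx <- which(fr$t >= -1e-9 & fr$t <= 0.3 + 1e-9)
  dcom <- (th[max(idx)] - th[min(idx)]) * 180 / pi
  expect_equal(sum(eff), dcom, tolerance = 0.05 * abs(dcom))
  expect_error(segment_effect(fr, window = c(0, 1)), "window")
})
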