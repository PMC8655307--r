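#' Specification of synthetic stance trials
#'
#' Bundles the generating model for synthetic CoM-angle sequences. Defaults
#' are the identified operating point of the model — Hp = 0.96 s,
#' Hu = 24.4 ms, kP = 0.34 mgh, kD = 0.03 mgh, sigma = 0.50 mNm — under the
#' experimental constants (8.8 deg over 0.25 s ramp, m = 0.404 kg,
#' h = 0.107 m, 40 ms sensory delay, 1 ms sampling) with 18 sequences,
#' standing in for the unavailable terminal recordings.
#'
#' @param params generating [pendulum_params()].
#' @param mpc generating [mpc_config()].
#' @param profile [floor_profile()] of the tilt.
#' @param sim [sim_config()] for the window and integration.
#' @param n_sequences number of sequences the generator stands in for.
#' @param seed base seed; sequence `i` uses a seed derived from `(seed, i)`.
#' @return An object of class `synth_trial_spec`.
#' @export
synth_trial_spec <- function(params = pendulum_params(),
                             mpc = mpc_config(),
                             profile = floor_profile(),
                             sim = sim_config(),
                             n_sequences = 18L, seed = 20230101L) {
  structure(list(params = params, mpc = mpc, profile = profile, sim = sim,
                 n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed)),
            class = "synth_trial_spec")
}

#' Synthetic terminal-trial CoM-angle sequence
#'
#' One seeded closed-loop simulation with the preview predictive controller
#' at the spec's generating parameters, in the same format as a recorded
#' identification target.
#'
#' @param spec a [synth_trial_spec()].
#' @param index sequence index (selects the derived noise seed).
#' @param seed base seed override; defaults to `spec$seed`.
#' @return A `stance_trajectory`.
#' @export
synth_trial <- function(spec = synth_trial_spec(), index = 1L,
                        seed = spec$seed) {
  ctrl <- mpc_controller(spec$params, spec$mpc)
  tr <- simulate_stance(spec$params, ctrl, spec$profile, spec$sim,
                        seed = derive_seed(seed, index))
  if (attr(tr, "status") != 0L)
    stop("synthetic generator configuration is unstable (sequence ", index,
         ")", call. = FALSE)
  tr
}

#' Synthetic pre-learning ("naive") trial
#'
#' Emulates a trial before the cue-tilt association is acquired. The default
#' surrogate is the linear PD baseline (reactive feedback with no internal
#' model), whose tilt response is consistently larger than the trained
#' preview controller's. A `"preview_off"` variant — the trained controller
#' with its disturbance preview removed — is also available; note that with
#' predictor-based delay compensation that variant tracks the tilt tightly,
#' so it does not reproduce a naive animal's large response.
#'
#' @inheritParams synth_trial
#' @param controller `"pd"` (linear PD baseline) or `"preview_off"`.
#' @return A `stance_trajectory`.
#' @export
synth_naive_trial <- function(spec = synth_trial_spec(), index = 1L,
                              controller = c("pd", "preview_off"),
                              seed = spec$seed) {
  controller <- match.arg(controller)
  ctrl <- if (controller == "preview_off") {
    cfg <- spec$mpc
    cfg$preview_enabled <- FALSE
    mpc_controller(spec$params, cfg)
  } else {
    pd_controller(pd_config("linear"), spec$params, delay = spec$mpc$delay)
  }
  tr <- simulate_stance(spec$params, ctrl, spec$profile, spec$sim,
                        seed = derive_seed(seed, index))
  if (attr(tr, "status") != 0L)
    stop("naive-trial configuration is unstable (sequence ", index, ")",
         call. = FALSE)
  tr
}

#' All synthetic sequences of a trial spec
#'
#' @inheritParams synth_trial
#' @param naive generate pre-learning surrogates instead of terminal trials.
#' @return A list of `stance_trajectory` objects of length
#'   `spec$n_sequences`.
#' @export
synth_sequences <- function(spec = synth_trial_spec(), naive = FALSE,
                            seed = spec$seed) {
  lapply(seq_len(spec$n_sequences), function(i)
    if (naive) synth_naive_trial(spec, i, seed = seed)
    else synth_trial(spec, i, seed = seed))
}

#' Synthetic marker motion with known segment angular velocities
#'
#' Forward-kinematics fixture generator: builds the nine-landmark sagittal
#' chain from prescribed absolute segment-angle functions, so that segment
#' angles and angular velocities are known by construction. The chain runs
#' MTP -> malleolus (foot), -> trochanter (leg, knee placed on the segment
#' midline), trochanter -> iliac crest (pelvic link rigid with the lower
#' trunk), -> mid-trunk (lower trunk), -> scapula (upper trunk), scapula ->
#' TMJ (neck rigid with the head), -> nose (head).
#'
#' @param model a [segment_model()].
#' @param angle_fns named list of functions of time returning the absolute
#'   angle (rad, backward positive) of `foot`, `leg`, `lower_trunk`,
#'   `upper_trunk`, `head`; missing entries default to a constant 0.
#' @param lengths named link lengths in meters (`foot`, `leg`, `pelvis`,
#'   `lower_trunk`, `upper_trunk`, `neck`, `head`).
#' @param fs sampling rate, Hz.
#' @param t_range window `c(from, to)`, s.
#' @return A [marker_frames()] object with attribute `segment_angles_true`
#'   (matrix of the prescribed angles).
#' @export
synth_marker_motion <- function(model = segment_model(), angle_fns = list(),
                                lengths = c(foot = 0.025, leg = 0.075,
                                            pelvis = 0.015, lower_trunk = 0.04,
                                            upper_trunk = 0.045, neck = 0.02,
                                            head = 0.03),
                                fs = 200, t_range = c(-0.35, 0.45)) {
  if (any(lengths <= 0)) stop_bad_arg("chain lengths must be positive")
  t <- seq(t_range[1], t_range[2], by = 1 / fs)
  segs <- c("foot", "leg", "lower_trunk", "upper_trunk", "head")
  ang <- sapply(segs, function(s) {
    f <- angle_fns[[s]] %||% function(tt) rep(0, length(tt))
    v <- f(t)
    if (length(v) == 1) v <- rep(v, length(t))
    v
  })
  u <- function(a) cbind(-sin(a), cos(a))  # unit vector at angle a from vertical

  mtp <- matrix(0, length(t), 2)
  mall <- mtp + lengths[["foot"]] * u(ang[, "foot"])
  troch <- mall + lengths[["leg"]] * u(ang[, "leg"])
  knee <- mall + 0.5 * lengths[["leg"]] * u(ang[, "leg"])
  iliac <- troch + lengths[["pelvis"]] * u(ang[, "lower_trunk"])
  midt <- iliac + lengths[["lower_trunk"]] * u(ang[, "lower_trunk"])
  scap <- midt + lengths[["upper_trunk"]] * u(ang[, "upper_trunk"])
  tmj <- scap + lengths[["neck"]] * u(ang[, "head"])
  nose <- tmj + lengths[["head"]] * u(ang[, "head"])

  pts <- list(mtp = mtp, malleolus = mall, knee = knee, trochanter = troch,
              iliac_crest = iliac, scapula = scap, mid_trunk = midt,
              tmj = tmj, nose = nose)
  df <- data.frame(t = t)
  for (nm in names(pts)) {
    df[[paste0(nm, "_x")]] <- pts[[nm]][, 1]
    df[[paste0(nm, "_y")]] <- pts[[nm]][, 2]
  }
  out <- marker_frames(df)
  attr(out, "segment_angles_true") <- ang
  out
}
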