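#' Configuration of the receding-horizon predictive controller
#'
#' `Hp` is the prediction horizon: how far ahead the controller forecasts the
#' body angle with its internal model. `Hu` is the control horizon: the
#' planned input may take distinct values for the first `Hu` of those steps
#' and is then held constant (move blocking). Both are given in seconds and
#' rounded to whole steps of `dt` (minimum one step); `Hu` is clipped to
#' `Hp`. The cost is the sum of squared predicted angles over the prediction
#' horizon (the target angle is always zero) plus a tiny input-move
#' regularizer used purely for numerical conditioning.
#'
#' @param Hp prediction horizon, s.
#' @param Hu control horizon, s.
#' @param dt controller sampling interval, s.
#' @param delay sensory delay, s; must be a whole number of steps.
#' @param state_weight weight on squared predicted angle (dimensionless).
#' @param input_weight weight on the squared control torque over the
#'   prediction horizon; limits control authority and therefore shapes how
#'   strongly the controller leans on (possibly stale) feedback.
#' @param input_move_regularizer weight on squared input increments.
#' @param preview_enabled if `TRUE` the controller knows the future floor
#'   trajectory over the prediction horizon (the learned cue-tilt
#'   association); if `FALSE` it assumes the current floor angle persists.
#' @param delay_compensation if `TRUE` the delayed state measurement is
#'   forward-predicted to the current time through the internal model
#'   ([delay_compensate()]) before the gain is applied; if `FALSE`
#'   (default) the controller acts on the stale measurement as if it were
#'   current, i.e. the sensory delay is a genuine, uncompensated feedback
#'   lag.
#' @return An object of class `mpc_config`.
#' @export
mpc_config <- function(Hp = 0.96, Hu = 0.0244, dt = 0.001, delay = 0.040,
                       state_weight = 1, input_weight = 0,
                       input_move_regularizer = 0.1,
                       preview_enabled = TRUE, delay_compensation = TRUE) {
  if (!is.finite(Hp) || !is.finite(Hu) || Hp <= 0 || Hu <= 0)
    stop_bad_arg("Hp and Hu must be strictly positive")
  if (Hu > Hp + 1e-12) Hu <- Hp
  if (delay < 0) stop_bad_arg("delay must be non-negative")
  ds <- delay / dt
  if (abs(ds - round(ds)) > 1e-6)
    stop_bad_arg("delay must be a whole number of steps of dt")
  if (state_weight <= 0) stop_bad_arg("state_weight must be positive")
  if (input_weight < 0) stop_bad_arg("input_weight must be non-negative")
  structure(list(Hp = Hp, Hu = Hu, dt = dt, delay = delay,
                 state_weight = state_weight, input_weight = input_weight,
                 input_move_regularizer = input_move_regularizer,
                 preview_enabled = isTRUE(preview_enabled),
                 delay_compensation = isTRUE(delay_compensation)),
            class = "mpc_config")
}

horizon_steps <- function(H, dt) max(1L, as.integer(round(H / dt)))

#' Closed-form preview gains of the predictive controller
#'
#' Solves the unconstrained finite-horizon quadratic problem once and returns
#' the linear gains that map the current state estimate, the previous applied
#' input and the floor-angle preview onto the first optimal move. Because the
#' problem has no inequality constraints the receding-horizon controller is a
#' fixed linear preview law, recomputed only when the model or horizons
#' change.
#'
#' The stacked least-squares system (prediction matrix over `Hp` steps with
#' move blocking after `Hu` free moves, plus the scaled input-move rows) is
#' solved by QR factorization.
#'
#' @param model an [linearize_internal_model()] object.
#' @param config an [mpc_config()] object with matching `dt`.
#' @return An object of class `mpc_gains`: gains `kx` (state), `ktau`
#'   (previous input), `kdphi`/`kdphid` (previews of floor angle and rate,
#'   length `Np`), with the horizon step counts and the model attached.
#' @export
mpc_gain <- function(model, config) {
  stopifnot(inherits(model, "internal_model"), inherits(config, "mpc_config"))
  dt <- model$dt
  if (abs(config$dt - dt) > 1e-12)
    stop_bad_arg("controller and internal model sampling intervals differ")
  Np <- horizon_steps(config$Hp, dt)
  Nu <- min(horizon_steps(config$Hu, dt), Np)
  A <- model$A; B <- model$B; Bd <- model$Bd
  qw <- sqrt(config$state_weight)

  # impulse responses of the predicted angle:
  #   h[k]  = C A^(k-1) B,  f*[k] = C A^(k-1) Bd[, *],  Fm[j, ] = C A^j
  aux <- mpc_gain_aux_cpp(A, B, Bd, Np)
  h <- aux$h; fphi <- aux$fphi; fphid <- aux$fphid; Fm <- aux$Fm

  # prediction matrix with move blocking: input step i (0-based) uses free
  # move min(i, Nu-1)
  G <- matrix(0, Np, Nu)
  if (Nu > 1)
    for (l in seq_len(Nu - 1)) G[l:Np, l] <- h[seq_len(Np - l + 1)]
  hc <- cumsum(h)
  G[Nu:Np, Nu] <- hc[seq_len(Np - Nu + 1)]

  # input-amplitude weight, applied per horizon step (the blocked final move
  # is held for the remaining steps, hence its multiplicity)
  su <- sqrt(config$input_weight)
  Mw <- diag(c(rep(1, Nu - 1), sqrt(Np - Nu + 1)), Nu)

  # input-increment operator (first increment is relative to the previously
  # applied input)
  D <- diag(Nu)
  if (Nu > 1) D[cbind(2:Nu, 1:(Nu - 1))] <- -1
  srho <- sqrt(config$input_move_regularizer)

  Abar <- rbind(qw * G, su * Mw, srho * D)
  qrA <- qr(Abar, LAPACK = TRUE)
  R <- qr.R(qrA)
  if (any(abs(diag(R)) < .Machine$double.eps * max(abs(diag(R))) * nrow(Abar)))
    stop_bad_arg("degenerate weighting: normal equations are rank deficient")
  # first free move in the original column order (the LAPACK QR pivots)
  ej <- numeric(Nu); ej[which(qrA$pivot == 1L)] <- 1
  z <- backsolve(R, ej, transpose = TRUE)
  v <- qr.Q(qrA) %*% z                      # tau0 = v' %*% rhs
  vG <- qw * v[seq_len(Np)]

  kx <- -as.numeric(vG %*% Fm)
  ktau <- srho * v[Np + Nu + 1]
  kdphi <- -rev_xcorr_cpp(vG, fphi)
  kdphid <- -rev_xcorr_cpp(vG, fphid)

  structure(list(kx = kx, ktau = ktau, kdphi = kdphi, kdphid = kdphid,
                 Np = Np, Nu = Nu, dt = dt,
                 delay_steps = as.integer(round(config$delay / dt)),
                 preview_enabled = config$preview_enabled,
                 delay_compensation = config$delay_compensation,
                 model = model, config = config),
            class = "mpc_gains")
}

#' @export
print.mpc_gains <- function(x, ...) {
  cat(sprintf("Preview MPC gains: Hp = %d steps, Hu = %d steps, dt = %g s, delay = %d steps\n",
              x$Np, x$Nu, x$dt, x$delay_steps))
  cat(sprintf("  state gain (%.4g, %.4g); preview %s\n", x$kx[1], x$kx[2],
              if (x$preview_enabled) "enabled" else "disabled"))
  invisible(x)
}

#' First optimal control move of the predictive controller
#'
#' A pure function of its arguments: applies the precomputed preview gains to
#' the current state estimate, the previously applied input and the
#' floor-angle preview over the prediction horizon.
#'
#' @param gains an [mpc_gain()] object.
#' @param state_estimate numeric length 2, `(theta, theta_dot)` at the
#'   current step (after delay compensation).
#' @param phi_preview floor angles at the current and next `Np - 1` steps,
#'   rad; length must equal `Np`.
#' @param phi_dot_preview matching floor angular velocities, rad/s.
#' @param tau_prev previously applied control torque, N m.
#' @return Control torque, N m.
#' @export
mpc_control <- function(gains, state_estimate, phi_preview, phi_dot_preview,
                        tau_prev = 0) {
  stopifnot(inherits(gains, "mpc_gains"))
  if (length(state_estimate) != 2)
    stop_bad_arg("state_estimate must have length 2")
  if (length(phi_preview) != gains$Np || length(phi_dot_preview) != gains$Np)
    stop_bad_arg("previews must have exactly Np = ", gains$Np, " entries")
  sum(gains$kx * state_estimate) + gains$ktau * tau_prev +
    sum(gains$kdphi * phi_preview) + sum(gains$kdphid * phi_dot_preview)
}

#' Sensory-delay compensation by internal-model forward prediction
#'
#' Propagates a delayed state measurement to the current time through the
#' discrete internal model, replaying the control inputs applied and the
#' floor trajectory observed during the delay interval (predictor structure;
#' the optimization itself is left unchanged).
#'
#' @param model an [linearize_internal_model()] object.
#' @param delayed_measurement numeric length 2, the state measured
#'   `delay` steps ago.
#' @param input_history applied control torques over the delay interval,
#'   oldest first; length defines the delay in steps.
#' @param phi_history floor angles over the same steps.
#' @param phi_dot_history floor angular velocities over the same steps.
#' @return Estimated current state, numeric length 2.
#' @export
delay_compensate <- function(model, delayed_measurement, input_history,
                             phi_history, phi_dot_history) {
  stopifnot(inherits(model, "internal_model"))
  d <- length(input_history)
  if (length(phi_history) != d || length(phi_dot_history) != d)
    stop_bad_arg("input and floor histories must span the same number of steps")
  x <- as.numeric(delayed_measurement)
  if (length(x) != 2) stop_bad_arg("delayed_measurement must have length 2")
  for (i in seq_len(d))
    x <- as.numeric(model$A %*% x) + model$B * input_history[i] +
      as.numeric(model$Bd %*% c(phi_history[i], phi_dot_history[i]))
  x
}
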