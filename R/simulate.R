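#' Simulation window and integration settings
#'
#' The default window spans −0.35 s to 0.45 s around tilt onset at a 1 ms
#' step, matching the identification window. The torque noise is sampled
#' once per step; `noise_scaling` selects whether `sigma` is interpreted as
#' the per-sample standard deviation at the simulation rate (`"per-sample"`,
#' default) or as a continuous-time intensity discretized as
#' `sigma/sqrt(dt)` per step (`"sqrt-dt"`). `integrator` selects the
#' fixed-step scheme used for the deterministic drift within each step
#' (`"rk4"` default, `"euler"` available); the noise torque is held constant
#' over the step in either case.
#'
#' @param dt integration and controller step, s.
#' @param t_start,t_end window bounds, s.
#' @param noise_seed integer seed for the noise draws, or `NULL` to use the
#'   current RNG state.
#' @param noise_scaling `"per-sample"` or `"sqrt-dt"`.
#' @param integrator `"rk4"` or `"euler"`.
#' @param theta0,theta_dot0 initial state at `t_start`, rad and rad/s; the
#'   default upright rest state reflects that the animals are stationary
#'   before the trigger.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, t_start = -0.35, t_end = 0.45,
                       noise_seed = NULL,
                       noise_scaling = c("per-sample", "sqrt-dt"),
                       integrator = c("rk4", "euler"),
                       theta0 = 0, theta_dot0 = 0) {
  if (!is.finite(dt) || dt <= 0) stop_bad_arg("dt must be strictly positive")
  if (t_end <= t_start) stop_bad_arg("t_end must exceed t_start")
  n <- (t_end - t_start) / dt
  if (abs(n - round(n)) > 1e-6)
    stop_bad_arg("window length must be a whole number of steps of dt")
  structure(list(dt = dt, t_start = t_start, t_end = t_end,
                 noise_seed = noise_seed,
                 noise_scaling = match.arg(noise_scaling),
                 integrator = match.arg(integrator),
                 theta0 = theta0, theta_dot0 = theta_dot0),
            class = "sim_config")
}

#' Closed-loop simulation of perturbed stance
#'
#' Integrates the stochastic stance pendulum under a floor-tilt profile with
#' the given controller at a fixed step, recording the body angle, angular
#' velocity, control torque, floor-coupling torque and floor angle at every
#' sample. With a fixed `seed` the output is bit-reproducible.
#'
#' @param params a [pendulum_params()] object (the plant keeps the full
#'   `sin(theta)` gravity term).
#' @param controller a `stance_controller` handle ([mpc_controller()],
#'   [pd_controller()] or [no_controller()]).
#' @param profile a [floor_profile()].
#' @param config a [sim_config()].
#' @param seed noise seed; defaults to `config$noise_seed`.
#' @return A `stance_trajectory`: a data frame with columns `t`, `theta`,
#'   `theta_dot`, `tau`, `tau_floor`, `phi` and attributes `dt`, `seed`,
#'   `status` (0 ok, 1 fell over and the trace was frozen at the fall angle).
#' @examples
#' p <- pendulum_params(sigma = 0)
#' tr <- simulate_stance(p, mpc_controller(p), floor_profile())
#' max(abs(tr$theta)) * 180 / pi # peak CoM excursion, degrees
#' @export
simulate_stance <- function(params, controller, profile = floor_profile(),
                            config = sim_config(), seed = config$noise_seed) {
  stopifnot(inherits(params, "pendulum_params"),
            inherits(controller, "stance_controller"),
            inherits(profile, "floor_profile"),
            inherits(config, "sim_config"))
  out <- run_stance_loop(params, controller, profile, config, seed)
  n <- length(out$theta)
  times <- config$t_start + (seq_len(n) - 1L) * config$dt
  if (out$status == 2L)
    stop("simulation failure: controller returned a non-finite torque at step ",
         out$step, " (t = ", format(times[out$step + 1L]), " s)", call. = FALSE)

  traj <- data.frame(t = times, theta = out$theta, theta_dot = out$theta_dot,
                     tau = out$tau, tau_floor = out$tau_floor, phi = out$phi)
  attr(traj, "dt") <- config$dt
  attr(traj, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(traj, "status") <- out$status
  attr(traj, "controller") <- controller$label
  class(traj) <- c("stance_trajectory", "data.frame")
  traj
}

# Raw closed-loop run shared by simulate_stance() and the identification
# objective (which only needs the angle series and the status flag).
run_stance_loop <- function(params, controller, profile, config, seed) {
  dt <- config$dt
  n <- as.integer(round((config$t_end - config$t_start) / dt)) + 1L
  times <- config$t_start + (seq_len(n) - 1L) * dt

  scale <- if (config$noise_scaling == "per-sample") params$sigma
           else params$sigma / sqrt(dt)
  w <- if (scale > 0) with_seed(seed, rnorm(n)) * scale else numeric(n)

  ctype <- switch(controller$type, none = 0L, pd = 1L, nonlinear_pd = 2L,
                  mpc = 3L)
  g <- c(0, 0, 0); dsteps <- 0L
  kx <- c(0, 0); ktau <- 0; kdphi <- 0; kdphid <- 0
  A <- diag(2); B <- c(0, 0); Bd <- matrix(0, 2, 2); prev <- TRUE
  comp <- FALSE
  if (ctype %in% c(1L, 2L)) {
    g <- controller$g
    dsteps <- as.integer(round(controller$delay / dt))
  } else if (ctype == 3L) {
    gn <- controller$gains
    if (abs(gn$dt - dt) > 1e-12)
      stop_bad_arg("controller was built for a different sampling interval")
    kx <- gn$kx; ktau <- gn$ktau; kdphi <- gn$kdphi; kdphid <- gn$kdphid
    m <- gn$model
    A <- m$A; B <- m$B; Bd <- m$Bd
    dsteps <- gn$delay_steps
    prev <- gn$preview_enabled
    comp <- isTRUE(gn$delay_compensation)
  }

  simulate_loop_cpp(n, dt, config$t_start,
                    mgh(params), params$J, params$kP, params$kD,
                    profile$onset, profile$duration, profile$amplitude,
                    w, ctype, g[1], g[2], g[3], dsteps,
                    kx, ktau, kdphi, kdphid, A, B, Bd, prev, comp,
                    if (config$integrator == "euler") 0L else 1L, 10,
                    config$theta0 %||% 0, config$theta_dot0 %||% 0)
}

#' Stability of a simulated trajectory
#'
#' A trajectory counts as stable when the body angle never exceeds the fall
#' limit (default pi/2, i.e. the body never reaches horizontal).
#'
#' @param traj a `stance_trajectory`.
#' @param angle_limit fall threshold, rad.
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(traj, angle_limit = pi / 2) {
  if (!nrow(traj)) stop_bad_arg("empty trajectory")
  max(abs(traj$theta)) <= angle_limit
}
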