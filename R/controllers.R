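#' Controller handles for the closed-loop simulation
#'
#' [simulate_stance()] accepts declarative controller handles. Each handle
#' states what the controller sees — the state measurement delayed by the
#' sensory delay — and how it maps that onto a torque:
#'
#' * `mpc_controller()` wraps precomputed preview gains ([mpc_gain()]); the
#'   delayed measurement is forward-predicted to the current time through the
#'   internal model before the gain is applied.
#' * `pd_controller()` applies a linear or nonlinear PD law directly to the
#'   delayed measurement (conventional feedback, no internal model).
#' * `no_controller()` applies zero torque, leaving only the passive MTP
#'   coupling.
#'
#' @param params a [pendulum_params()] object.
#' @param config an [mpc_config()] or [pd_config()].
#' @param delay sensory delay for the PD baselines, s.
#' @return An object of class `stance_controller`.
#' @export
mpc_controller <- function(params, config = mpc_config()) {
  model <- linearize_internal_model(params, config$dt)
  gains <- mpc_gain(model, config)
  structure(list(type = "mpc", label = sprintf("MPC (Hp=%g s, Hu=%g s%s)",
                                               config$Hp, config$Hu,
                                               if (config$preview_enabled) ""
                                               else ", no preview"),
                 gains = gains, delay_steps = gains$delay_steps),
            class = "stance_controller")
}

#' @rdname mpc_controller
#' @export
pd_controller <- function(config = pd_config(), params, delay = 0.040) {
  stopifnot(inherits(config, "pd_config"))
  s <- mgh(params)
  if (config$variant == "linear") {
    structure(list(type = "pd", label = "linear PD",
                   g = c(config$kP_lin * s, config$kD_lin * s, 0),
                   delay = delay),
              class = "stance_controller")
  } else {
    structure(list(type = "nonlinear_pd", label = "nonlinear PD",
                   g = c(config$kP2 * s, config$kP0 * s, config$kD_nl * s),
                   delay = delay),
              class = "stance_controller")
  }
}

#' @rdname mpc_controller
#' @export
no_controller <- function() {
  structure(list(type = "none", label = "no control", delay = 0),
            class = "stance_controller")
}

#' @export
print.stance_controller <- function(x, ...) {
  cat("Stance controller:", x$label, "\n")
  invisible(x)
}
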