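#' Proportional-derivative baseline controllers
#'
#' Two conventional feedback baselines for comparison with the predictive
#' controller, with gains expressed as dimensionless multiples of `m*g*h`:
#'
#' * `variant = "linear"`: `tau = -kP_lin*mgh*theta - kD_lin*mgh*theta_dot`,
#'   defaulting to the classic human quiet-stance gains (1.46, 0.3).
#' * `variant = "nonlinear"`: `tau = -kP2*mgh*theta*|theta| - kP0*mgh*theta
#'   - kD_nl*mgh*theta_dot`, defaulting to gains reported for quiet standing
#'   rats (196, 0.88, 0.11). The quadratic term uses `theta*|theta|` so that
#'   its magnitude follows `theta^2` while always opposing the displacement
#'   (odd symmetry).
#'
#' @param variant `"linear"` or `"nonlinear"`.
#' @param kP_lin,kD_lin linear-variant gains, multiples of `mgh`.
#' @param kP2,kP0,kD_nl nonlinear-variant gains, multiples of `mgh`.
#' @return An object of class `pd_config`.
#' @export
pd_config <- function(variant = c("linear", "nonlinear"),
                      kP_lin = 1.46, kD_lin = 0.3,
                      kP2 = 196, kP0 = 0.88, kD_nl = 0.11) {
  variant <- match.arg(variant)
  gains <- if (variant == "linear") c(kP_lin = kP_lin, kD_lin = kD_lin)
           else c(kP2 = kP2, kP0 = kP0, kD_nl = kD_nl)
  if (any(!is.finite(gains)) || any(gains < 0))
    stop_bad_arg("PD gains must be finite and non-negative")
  structure(c(list(variant = variant), as.list(gains)), class = "pd_config")
}

#' Linear PD control torque
#'
#' @param config a [pd_config()] with `variant = "linear"`.
#' @param params a [pendulum_params()] object (supplies `mgh`).
#' @param theta body angle, rad.
#' @param theta_dot body angular velocity, rad/s.
#' @return Control torque, N m.
#' @export
pd_control <- function(config, params, theta, theta_dot) {
  stopifnot(inherits(config, "pd_config"))
  if (config$variant != "linear")
    stop_bad_arg("pd_control() requires the linear variant")
  s <- mgh(params)
  -config$kP_lin * s * theta - config$kD_lin * s * theta_dot
}

#' Nonlinear PD control torque
#'
#' @inheritParams pd_control
#' @param config a [pd_config()] with `variant = "nonlinear"`.
#' @export
nonlinear_pd_control <- function(config, params, theta, theta_dot) {
  stopifnot(inherits(config, "pd_config"))
  if (config$variant != "nonlinear")
    stop_bad_arg("nonlinear_pd_control() requires the nonlinear variant")
  s <- mgh(params)
  -config$kP2 * s * theta * abs(theta) - config$kP0 * s * theta -
    config$kD_nl * s * theta_dot
}
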