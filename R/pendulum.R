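#' Physical parameters of the stance pendulum
#'
#' The standing rat is reduced to a single rigid link from the
#' metatarsophalangeal (MTP) joint to the whole-body centre of mass (CoM).
#' `m`, `h` and `g` set the gravitational toppling torque `m*g*h*sin(theta)`;
#' `J` is the moment of inertia about the MTP joint; `kP` and `kD` are the
#' passive elastic and viscous coefficients of the tissues around the MTP
#' joint, which couple the body to the floor angle; `sigma` is the magnitude
#' of the additive Gaussian torque noise.
#'
#' `J` is not measurable from the marker set, so the default places the whole
#' mass at the CoM (`J = m * h^2`), consistent with the single-link
#' reduction; it can be overridden.
#'
#' @param m body mass, kg.
#' @param h MTP-to-CoM distance, m.
#' @param g gravitational acceleration, m/s^2.
#' @param J moment of inertia about the MTP joint, kg m^2; default `m * h^2`.
#' @param kP passive MTP elastic coefficient, N m/rad.
#' @param kD passive MTP viscous coefficient, N m s/rad.
#' @param sigma torque-noise magnitude, N m (interpreted per sample at the
#'   simulation rate unless the simulation config says otherwise).
#' @return An object of class `pendulum_params`.
#' @examples
#' p <- pendulum_params()
#' mgh(p) # restoring-torque scale used to normalize stiffness gains
#' @export
pendulum_params <- function(m = 0.404, h = 0.107, g = 9.81, J = m * h^2,
                            kP = 0.34 * m * g * h, kD = 0.03 * m * g * h,
                            sigma = 0.5e-3) {
  vals <- c(m = m, h = h, g = g, J = J)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_bad_arg("m, h, g and J must be finite and strictly positive")
  nn <- c(kP = kP, kD = kD, sigma = sigma)
  if (any(!is.finite(nn)) || any(nn < 0))
    stop_bad_arg("kP, kD and sigma must be finite and non-negative")
  structure(list(m = m, h = h, g = g, J = J, kP = kP, kD = kD, sigma = sigma),
            class = "pendulum_params")
}

#' @rdname pendulum_params
#' @param params a `pendulum_params` object.
#' @export
mgh <- function(params) params$m * params$g * params$h

#' @export
print.pendulum_params <- function(x, ...) {
  cat("Stance pendulum parameters\n")
  cat(sprintf("  m = %.4g kg, h = %.4g m, g = %.4g m/s^2, J = %.5g kg m^2\n",
              x$m, x$h, x$g, x$J))
  cat(sprintf("  kP = %.4g N m/rad (%.3g mgh), kD = %.4g N m s/rad (%.3g mgh)\n",
              x$kP, x$kP / mgh(x), x$kD, x$kD / mgh(x)))
  cat(sprintf("  sigma = %.4g N m (%.3g mNm)\n", x$sigma, 1e3 * x$sigma))
  invisible(x)
}

#' Ramp-and-hold floor tilt profile
#'
#' The floor is flat before `onset`, rotates backward (toes-up, positive) at
#' constant angular velocity for `duration` seconds, and then holds the final
#' angle. The returned profile is evaluable through [floor_angle()] and
#' [floor_rate()].
#'
#' @param onset ramp start time, s.
#' @param duration ramp duration, s; must be positive.
#' @param amplitude_deg total tilt, degrees (stored internally in radians).
#' @return An object of class `floor_profile`.
#' @examples
#' fp <- floor_profile(0, 0.25, 8.8)
#' floor_angle(fp, c(-0.1, 0.125, 0.25, 1)) * 180 / pi
#' @export
floor_profile <- function(onset = 0, duration = 0.25, amplitude_deg = 8.8) {
  if (!is.finite(duration) || duration <= 0)
    stop_bad_arg("floor ramp duration must be strictly positive")
  structure(list(onset = onset, duration = duration,
                 amplitude = amplitude_deg * pi / 180),
            class = "floor_profile")
}

#' @rdname floor_profile
#' @param profile a `floor_profile`.
#' @param t time or vector of times, s.
#' @return `floor_angle` returns the floor angle phi(t) in radians,
#'   `floor_rate` its time derivative in rad/s.
#' @export
floor_angle <- function(profile, t) {
  a <- profile$amplitude
  pmin(pmax((t - profile$onset) / profile$duration, 0), 1) * a
}

#' @rdname floor_profile
#' @export
floor_rate <- function(profile, t) {
  # small tolerance so that samples landing on a ramp corner up to floating
  # jitter classify consistently
  on <- t >= profile$onset - 1e-12 &
    t < profile$onset + profile$duration - 1e-12
  ifelse(on, profile$amplitude / profile$duration, 0)
}

#' @export
print.floor_profile <- function(x, ...) {
  cat(sprintf("Floor tilt: %.3g deg over %.3g s starting at t = %.3g s\n",
              x$amplitude * 180 / pi, x$duration, x$onset))
  invisible(x)
}

#' Passive floor-coupling torque at the MTP joint
#'
#' Torque exerted on the body by the elastic and viscous tissues around the
#' MTP joint, `-kP * (theta - phi) - kD * (theta_dot - phi_dot)`. With the
#' floor flat it is a stabilizing restoring torque; during a tilt it acts as
#' the disturbance that drags the body with the floor.
#'
#' @param params a [pendulum_params()] object.
#' @param theta body angle from vertical, rad (backward positive).
#' @param theta_dot body angular velocity, rad/s.
#' @param phi floor angle, rad.
#' @param phi_dot floor angular velocity, rad/s.
#' @return Torque in N m.
#' @export
floor_torque <- function(params, theta, theta_dot, phi, phi_dot) {
  v <- c(theta, theta_dot, phi, phi_dot)
  if (any(!is.finite(v))) stop_bad_arg("floor_torque() requires finite inputs")
  -params$kP * (theta - phi) - params$kD * (theta_dot - phi_dot)
}

#' Angular acceleration of the stance pendulum
#'
#' Evaluates `(m*g*h*sin(theta) + tau + tau_floor + noise_torque) / J`.
#'
#' @inheritParams floor_torque
#' @param tau control torque, N m.
#' @param tau_floor passive floor-coupling torque, N m.
#' @param noise_torque additive noise torque, N m.
#' @return Angular acceleration, rad/s^2.
#' @export
pendulum_accel <- function(params, theta, tau, tau_floor, noise_torque = 0) {
  (mgh(params) * sin(theta) + tau + tau_floor + noise_torque) / params$J
}
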