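#' Discrete linear internal model of the stance dynamics
#'
#' Linearizes the pendulum and floor-coupling torques about upright
#' (`sin(theta) -> theta`) and discretizes the result by zero-order hold at
#' the controller sampling interval. The continuous dynamics are
#' \deqn{\ddot\theta = \frac{mgh - k_P}{J}\theta - \frac{k_D}{J}\dot\theta
#'   + \frac{1}{J}\tau + \frac{k_P}{J}\phi + \frac{k_D}{J}\dot\phi,}
#' i.e. state `x = (theta, theta_dot)`, control input `tau` and measured
#' disturbance `d = (phi, phi_dot)`. The predictive controller uses this as
#' its forecast model, taken to be an exact copy of the (linearized) plant.
#'
#' @param params a [pendulum_params()] object.
#' @param dt sampling interval, s.
#' @return An object of class `internal_model` with discrete maps `A` (2x2),
#'   `B` (2), `Bd` (2x2) such that `x[k+1] = A x[k] + B tau[k] + Bd d[k]`,
#'   plus the continuous-time matrices `Ac`, `Bc`, `Ec`.
#' @export
linearize_internal_model <- function(params, dt) {
  if (!is.finite(dt) || dt <= 0) stop_bad_arg("dt must be strictly positive")
  J <- params$J
  Ac <- matrix(c(0, (mgh(params) - params$kP) / J,
                 1, -params$kD / J), 2, 2)
  Bc <- c(0, 1 / J)
  Ec <- matrix(c(0, params$kP / J, 0, params$kD / J), 2, 2)
  # zero-order hold on (tau, phi, phi_dot) via the augmented matrix exponential
  Maug <- rbind(cbind(Ac, Bc, Ec), matrix(0, 3, 5))
  Md <- as.matrix(Matrix::expm(Maug * dt))
  structure(list(A = Md[1:2, 1:2, drop = FALSE], B = Md[1:2, 3],
                 Bd = Md[1:2, 4:5, drop = FALSE],
                 Ac = Ac, Bc = Bc, Ec = Ec, dt = dt, params = params),
            class = "internal_model")
}

#' @export
print.internal_model <- function(x, ...) {
  cat(sprintf("Discrete internal model (zero-order hold, dt = %g s)\n", x$dt))
  cat("A:\n"); print(x$A)
  cat("B:", format(x$B, digits = 6), "\n")
  cat("Bd:\n"); print(x$Bd)
  invisible(x)
}
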