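# Independent oracles used across the suite.

# Brute-force first move of the finite-horizon quadratic problem: the
# predicted-angle map is constructed by rolling the internal model forward
# (simulation, not the analytic impulse-response assembly used by
# mpc_gain()), and the stacked least-squares problem is solved by QR.
qp_first_move <- function(model, Np, Nu, x0, phis, phids, tau_prev = 0,
                          state_weight = 1, input_weight = 0, rho = 0.1) {
  roll <- function(u) {
    x <- x0
    th <- numeric(Np)
    for (j in seq_len(Np)) {
      uu <- u[min(j, Nu)]
      x <- as.numeric(model$A %*% x) + model$B * uu +
        as.numeric(model$Bd %*% c(phis[j], phids[j]))
      th[j] <- x[1]
    }
    th
  }
  base <- roll(numeric(Nu))
  G <- vapply(seq_len(Nu), function(l) {
    e <- numeric(Nu); e[l] <- 1
    roll(e) - base
  }, numeric(Np))
  G <- matrix(G, nrow = Np)
  D <- diag(Nu)
  if (Nu > 1) D[cbind(2:Nu, 1:(Nu - 1))] <- -1
  Mw <- diag(c(rep(1, Nu - 1), sqrt(Np - Nu + 1)), Nu)
  Abar <- rbind(sqrt(state_weight) * G, sqrt(input_weight) * Mw,
                sqrt(rho) * D)
  bbar <- c(-sqrt(state_weight) * base, numeric(Nu),
            sqrt(rho) * c(tau_prev, numeric(Nu - 1)))
  qr.solve(Abar, bbar)[1]
}

# High-order reference integration of the discrete closed loop: the
# controller runs at the sampling rate exactly as in simulate_stance(), but
# the plant is integrated with deSolve::lsoda at tight tolerances within
# each step. Noise-free only.
reference_closed_loop <- function(params, controller, profile, config) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  dt <- config$dt
  n <- as.integer(round((config$t_end - config$t_start) / dt)) + 1L
  times <- config$t_start + (seq_len(n) - 1L) * dt

  deriv <- function(t, y, parms) {
    phi <- floor_angle(profile, t)
    # each sampling step belongs to the floor-rate regime of [t_k, t_{k+1});
    # clamp so a corner at the right endpoint does not leak into the step
    phid <- floor_rate(profile, min(t, parms$tmax))
    tf <- -params$kP * (y[1] - phi) - params$kD * (y[2] - phid)
    list(c(y[2], (mgh(params) * sin(y[1]) + parms$tau + tf) / params$J))
  }

  th0 <- if (is.null(config$theta0)) 0 else config$theta0
  thd0 <- if (is.null(config$theta_dot0)) 0 else config$theta_dot0
  theta <- numeric(n); theta_dot <- numeric(n); tau <- numeric(n)
  x <- c(th0, thd0)
  gn <- if (controller$type == "mpc") controller$gains else NULL
  model <- if (!is.null(gn)) gn$model else NULL
  dsteps <- switch(controller$type, mpc = gn$delay_steps, none = 0L,
                   as.integer(round(controller$delay / dt)))
  for (k in seq_len(n)) {
    theta[k] <- x[1]; theta_dot[k] <- x[2]
    km <- k - dsteps
    meas <- if (km >= 1) c(theta[km], theta_dot[km]) else c(th0, thd0)
    u <- if (controller$type == "none") 0 else if (controller$type == "pd") {
      -controller$g[1] * meas[1] - controller$g[2] * meas[2]
    } else if (controller$type == "nonlinear_pd") {
      -controller$g[1] * meas[1] * abs(meas[1]) - controller$g[2] * meas[1] -
        controller$g[3] * meas[2]
    } else {
      est <- meas
      if (isTRUE(gn$delay_compensation) && dsteps > 0) {
        idx <- km:(k - 1)
        tpast <- times[1] + (idx - 1) * dt
        est <- delay_compensate(model, meas,
                                ifelse(idx >= 1, tau[pmax(idx, 1)], 0),
                                floor_angle(profile, tpast),
                                floor_rate(profile, tpast))
      }
      tprev <- if (k > 1) tau[k - 1] else 0
      tfut <- times[k] + (seq_len(gn$Np) - 1L) * dt
      if (gn$preview_enabled) {
        mpc_control(gn, est, floor_angle(profile, tfut),
                    floor_rate(profile, tfut), tprev)
      } else {
        mpc_control(gn, est, rep(floor_angle(profile, times[k]), gn$Np),
                    rep(0, gn$Np), tprev)
      }
    }
    tau[k] <- u
    if (k == n) break
    sol <- deSolve::lsoda(x, c(times[k], times[k + 1]), deriv,
                          parms = list(tau = u,
                                       tmax = times[k + 1] - 1e-6 * dt),
                          rtol = 1e-11, atol = 1e-12)
    x <- as.numeric(sol[2, 2:3])
  }
  data.frame(t = times, theta = theta, theta_dot = theta_dot, tau = tau)
}

# body constants used throughout the tests
test_params <- function(sigma = 0, kP = 0.34, kD = 0.03) {
  p0 <- pendulum_params()
  s <- mgh(p0)
  pendulum_params(kP = kP * s, kD = kD * s, sigma = sigma)
}
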