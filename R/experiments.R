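#' Cosine correlation between two time series
#'
#' Normalized inner product `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`, the
#' trajectory-similarity statistic used throughout the sweep experiments.
#'
#' @param a,b numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

sweep_controller <- function(spec, Hp = NULL, Hu = NULL) {
  cfg <- spec$mpc
  if (!is.null(Hp)) cfg$Hp <- Hp
  if (!is.null(Hu)) cfg$Hu <- Hu
  if (cfg$Hu > cfg$Hp) cfg$Hu <- cfg$Hp
  mpc_controller(spec$params, cfg)
}

run_reps <- function(spec, ctrl, n_rep, seed) {
  lapply(seq_len(n_rep), function(r)
    simulate_stance(spec$params, ctrl, spec$profile, spec$sim,
                    seed = derive_seed(seed, r)))
}

#' Prediction-horizon sweep
#'
#' For each prediction horizon, runs `n_rep` seeded simulations (the same
#' seeds for every horizon, so differences reflect the parameter, not the
#' noise realization) and summarizes the mean maximum absolute CoM angle and
#' control torque. Horizons whose runs fall over are flagged, not errors.
#'
#' @param values prediction horizons, s.
#' @param spec base [synth_trial_spec()] supplying all other settings.
#' @param n_rep simulations per value.
#' @param seed base seed.
#' @return A data frame of class `sweep_result` with one row per value:
#'   `Hp`, `max_theta`, `max_tau` (whole window), `max_theta_post`,
#'   `max_tau_post` (from tilt onset on, i.e. the disturbance response
#'   proper, excluding the anticipatory lean), `frac_stable`, `n_rep`.
#' @export
sweep_prediction_horizon <- function(values, spec = synth_trial_spec(),
                                     n_rep = 10, seed = 1L) {
  rows <- lapply(values, function(hp) {
    ctrl <- try(sweep_controller(spec, Hp = hp), silent = TRUE)
    if (inherits(ctrl, "try-error"))
      return(data.frame(Hp = hp, max_theta = NA_real_, max_tau = NA_real_,
                        max_theta_post = NA_real_, max_tau_post = NA_real_,
                        frac_stable = 0, n_rep = n_rep))
    trs <- run_reps(spec, ctrl, n_rep, seed)
    st <- vapply(trs, is_stable, logical(1))
    post <- trs[[1]]$t >= spec$profile$onset
    mx <- function(f) mean(vapply(trs, f, numeric(1)))
    data.frame(Hp = hp,
               max_theta = mx(function(x) max(abs(x$theta))),
               max_tau = mx(function(x) max(abs(x$tau))),
               max_theta_post = mx(function(x) max(abs(x$theta[post]))),
               max_tau_post = mx(function(x) max(abs(x$tau[post]))),
               frac_stable = mean(st), n_rep = n_rep)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Control-horizon sweep
#'
#' For each control horizon, the `n_rep`-averaged CoM-angle trace is
#' compared by cosine correlation against the averaged trace at the
#' reference control horizon (same seeds throughout).
#'
#' @param values control horizons, s.
#' @param reference reference control horizon, s (included implicitly).
#' @inheritParams sweep_prediction_horizon
#' @return A `sweep_result` data frame with `Hu`, `correlation`,
#'   `max_theta`, `max_tau`, `frac_stable`, `n_rep`.
#' @export
sweep_control_horizon <- function(values, reference = 0.05,
                                  spec = synth_trial_spec(), n_rep = 10,
                                  seed = 1L) {
  avg_theta <- function(hu) {
    trs <- run_reps(spec, sweep_controller(spec, Hu = hu), n_rep, seed)
    list(theta = rowMeans(sapply(trs, `[[`, "theta")),
         max_theta = mean(vapply(trs, function(x) max(abs(x$theta)), numeric(1))),
         max_tau = mean(vapply(trs, function(x) max(abs(x$tau)), numeric(1))),
         frac_stable = mean(vapply(trs, is_stable, logical(1))))
  }
  ref <- avg_theta(reference)
  rows <- lapply(values, function(hu) {
    a <- avg_theta(hu)
    data.frame(Hu = hu, correlation = cosine_correlation(a$theta, ref$theta),
               max_theta = a$max_theta, max_tau = a$max_tau,
               frac_stable = a$frac_stable, n_rep = n_rep)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "reference") <- reference
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Stability scan over the prediction horizon
#'
#' For each scanned horizon, the fraction of `n_rep` seeded runs that remain
#' stable ([is_stable()]); reports the smallest and largest horizon whose
#' runs are all stable.
#'
#' @param from,to,step scan range and resolution, s.
#' @inheritParams sweep_prediction_horizon
#' @return A list with `table` (per-value stable fraction), `smallest_stable`
#'   and `largest_stable` (s, `NA` if none).
#' @export
stability_scan <- function(from = 0.01, to = 0.1, step = 0.01,
                           spec = synth_trial_spec(), n_rep = 10, seed = 1L) {
  if (step <= 0) stop_bad_arg("step must be positive")
  values <- seq(from, to, by = step)
  sw <- sweep_prediction_horizon(values, spec, n_rep, seed)
  all_st <- sw$Hp[sw$frac_stable == 1]
  list(table = sw,
       smallest_stable = if (length(all_st)) min(all_st) else NA_real_,
       largest_stable = if (length(all_st)) max(all_st) else NA_real_)
}

#' Side-by-side comparison of the three controllers
#'
#' Runs the predictive controller and the two PD baselines on the same
#' scenario and seeds, returning mean angle and torque traces plus the
#' maximum one-step torque increment in the window just after the ramp ends
#' (the measure of how abruptly each controller reacts to the end of the
#' disturbance).
#'
#' @inheritParams sweep_prediction_horizon
#' @param post_window length of the post-ramp window, s.
#' @return A list with `traces` (long data frame: `t`, `controller`,
#'   `theta`, `tau`) and `summary` (per controller: `max_theta`, `max_tau`,
#'   `max_post_ramp_dtau`, `stable`).
#' @export
compare_controllers <- function(spec = synth_trial_spec(), n_rep = 10,
                                seed = 1L, post_window = 0.1) {
  ctrls <- list(mpc = mpc_controller(spec$params, spec$mpc),
                pd = pd_controller(pd_config("linear"), spec$params,
                                   delay = spec$mpc$delay),
                nonlinear_pd = pd_controller(pd_config("nonlinear"),
                                             spec$params,
                                             delay = spec$mpc$delay))
  ramp_end <- spec$profile$onset + spec$profile$duration
  traces <- list(); rows <- list()
  for (nm in names(ctrls)) {
    trs <- run_reps(spec, ctrls[[nm]], n_rep, seed)
    th <- rowMeans(sapply(trs, `[[`, "theta"))
    ta <- rowMeans(sapply(trs, `[[`, "tau"))
    t <- trs[[1]]$t
    traces[[nm]] <- data.frame(t = t, controller = nm, theta = th, tau = ta)
    post <- which(t > ramp_end & t <= ramp_end + post_window)
    rows[[nm]] <- data.frame(controller = nm,
                             max_theta = max(abs(th)), max_tau = max(abs(ta)),
                             max_post_ramp_dtau = max(abs(diff(ta[post]))),
                             stable = all(vapply(trs, is_stable, logical(1))))
  }
  list(traces = do.call(rbind, traces),
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
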