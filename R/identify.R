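#' Identification target: a CoM-angle trace to be reproduced
#'
#' Wraps a uniformly sampled CoM-angle series over the identification window
#' together with the tilt profile under which it was recorded and the body
#' constants of the animal. Targets are usually built from a simulated
#' trajectory ([synth_trial()]) or from a trajectory file
#' ([read_trajectory()]).
#'
#' @param trace a `stance_trajectory`, or a data frame with columns `t` and
#'   `theta` (seconds, radians).
#' @param profile the [floor_profile()] used during the recording.
#' @param params a [pendulum_params()] giving the body constants `m`, `h`
#'   (and `g`, `J`); the free parameters stored in it are ignored.
#' @param delay sensory delay assumed during identification, s.
#' @return An object of class `identification_target`.
#' @export
identification_target <- function(trace, profile = floor_profile(),
                                  params = pendulum_params(),
                                  delay = 0.040) {
  if (!all(c("t", "theta") %in% names(trace)))
    stop_bad_arg("trace must have columns t and theta")
  t <- trace$t
  dts <- diff(t)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-9))
    stop_bad_arg("trace must be uniformly sampled")
  structure(list(theta = as.numeric(trace$theta), times = as.numeric(t),
                 dt = round(dts[1], 9), t_start = t[1], t_end = t[length(t)],
                 profile = profile, params = params, delay = delay),
            class = "identification_target")
}

#' Search bounds for the five free parameters
#'
#' Defaults cover the explored stable ranges: prediction horizon 0.03–1.3 s,
#' control horizon 2–50 ms, MTP stiffness 0–1.5 mgh, MTP viscosity
#' 0–0.3 mgh, noise magnitude 0–2 mNm. Each element is `c(low, high)`;
#' `Hp`/`Hu` in seconds, `kP`/`kD` in multiples of `mgh`, `sigma` in N m.
#'
#' @param Hp,Hu,kP,kD,sigma numeric length-2 bounds.
#' @return A named list of bounds with class `parameter_bounds`.
#' @export
parameter_bounds <- function(Hp = c(0.03, 1.3), Hu = c(0.002, 0.05),
                             kP = c(0, 1.5), kD = c(0, 0.3),
                             sigma = c(0, 2e-3)) {
  b <- list(Hp = Hp, Hu = Hu, kP = kP, kD = kD, sigma = sigma)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[1] >= v[2])
      stop_bad_arg("bounds for ", nm, " must satisfy low < high")
  }
  structure(b, class = "parameter_bounds")
}

#' Genetic-algorithm settings
#'
#' Population-based search with tournament selection, blend crossover,
#' Gaussian mutation scaled to a fraction of each parameter's range, and
#' elitism. `n_rep` is the number of noisy simulations averaged inside each
#' objective evaluation.
#'
#' @param pop_size individuals per generation.
#' @param generations maximum number of generations.
#' @param elite number of top individuals copied unchanged.
#' @param tournament tournament size for parent selection.
#' @param crossover_alpha blend-crossover expansion factor.
#' @param mutation_prob per-gene mutation probability.
#' @param mutation_sd_frac initial mutation standard deviation as a fraction
#'   of each parameter's range; annealed geometrically to about 1/20 of this
#'   by the final generation so late generations refine rather than explore.
#' @param stall_generations stop early after this many generations without
#'   improvement of the best objective.
#' @param n_rep simulations averaged per evaluation.
#' @param polish_elites number of top (mutually distinct) individuals passed
#'   to the local refinement stage after the GA; 0 disables refinement.
#' @param polish_maxit iteration cap for each Nelder-Mead polish.
#' @param hu_refine if `TRUE`, the refinement stage alternates a fine grid
#'   search over the control horizon (the objective is rippled in `Hu`
#'   because horizons round to whole steps and the blocked input interacts
#'   with the ramp) with further polishing.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, generations = 60, elite = 2,
                      tournament = 3, crossover_alpha = 0.5,
                      mutation_prob = 0.25, mutation_sd_frac = 0.10,
                      stall_generations = 15, n_rep = 5,
                      polish_elites = 2, polish_maxit = 250,
                      hu_refine = TRUE) {
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 elite = as.integer(elite), tournament = as.integer(tournament),
                 crossover_alpha = crossover_alpha,
                 mutation_prob = mutation_prob,
                 mutation_sd_frac = mutation_sd_frac,
                 stall_generations = as.integer(stall_generations),
                 n_rep = as.integer(n_rep),
                 polish_elites = as.integer(polish_elites),
                 polish_maxit = as.integer(polish_maxit),
                 hu_refine = isTRUE(hu_refine)),
            class = "ga_config")
}

candidate_params <- function(candidate, target) {
  bp <- target$params
  s <- mgh(bp)
  pendulum_params(m = bp$m, h = bp$h, g = bp$g, J = bp$J,
                  kP = candidate[["kP"]] * s, kD = candidate[["kD"]] * s,
                  sigma = candidate[["sigma"]])
}

#' Mean-squared-error objective for parameter identification
#'
#' Simulates the model `n_rep` times with the candidate parameters (fresh
#' noise per replicate, seeds derived deterministically from `seed`),
#' averages the angle traces sample-wise, and returns the mean squared error
#' against the target trace over the identification window. Candidates whose
#' simulation falls over receive a large finite penalty (1e6 rad^2).
#'
#' @param candidate named numeric: `Hp`, `Hu` (s), `kP`, `kD` (multiples of
#'   `mgh`), `sigma` (N m). `Hu` is clipped to `Hp`.
#' @param target an [identification_target()].
#' @param n_rep replicates averaged per evaluation.
#' @param seed integer seed; the evaluation is deterministic given
#'   `(candidate, seed)`.
#' @return Mean squared error, rad^2.
#' @export
objective_mse <- function(candidate, target, n_rep = 5, seed = 1L) {
  stopifnot(inherits(target, "identification_target"), n_rep >= 1)
  pars <- try(candidate_params(candidate, target), silent = TRUE)
  if (inherits(pars, "try-error")) return(1e6)
  cfg <- try(mpc_config(Hp = candidate[["Hp"]],
                        Hu = min(candidate[["Hu"]], candidate[["Hp"]]),
                        dt = target$dt, delay = target$delay), silent = TRUE)
  if (inherits(cfg, "try-error")) return(1e6)
  ctrl <- try(mpc_controller(pars, cfg), silent = TRUE)
  if (inherits(ctrl, "try-error")) return(1e6)
  scfg <- sim_config(dt = target$dt, t_start = target$t_start,
                     t_end = target$t_end)
  acc <- numeric(length(target$theta))
  for (r in seq_len(n_rep)) {
    out <- run_stance_loop(pars, ctrl, target$profile, scfg,
                           seed = derive_seed(seed, r))
    if (out$status != 0L || max(abs(out$theta)) > pi / 2) return(1e6)
    acc <- acc + out$theta
  }
  mean((acc / n_rep - target$theta)^2)
}

#' Identify the five model parameters from a CoM-angle trace
#'
#' Genetic-algorithm search over (prediction horizon, control horizon, MTP
#' stiffness, MTP viscosity, noise magnitude) minimizing [objective_mse()].
#' Horizons are real-valued during the search and rounded to whole steps
#' inside the objective. Reproducible given `seed`; each candidate's noisy
#' objective uses seeds derived from `(seed, evaluation index)`.
#'
#' @param target an [identification_target()].
#' @param bounds a [parameter_bounds()].
#' @param control a [ga_config()].
#' @param seed integer run seed.
#' @return An `identification_result`: `par` (named vector, internal units),
#'   `par_report` (Hp s, Hu ms, kP and kD in mgh, sigma in mNm),
#'   `objective` (rad^2), `trace` (best objective per generation,
#'   non-increasing), `evaluations`, `seed`, `converged`.
#' @export
identify_parameters <- function(target, bounds = parameter_bounds(),
                                control = ga_config(), seed = 1L) {
  stopifnot(inherits(target, "identification_target"),
            inherits(bounds, "parameter_bounds"))
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  npar <- length(lo); nms <- names(bounds)
  evals <- 0L
  score <- function(cand) {
    evals <<- evals + 1L
    objective_mse(setNames(cand, nms), target, n_rep = control$n_rep,
                  seed = derive_seed(seed, evals))
  }

  set.seed(derive_seed(seed, 0))
  pop <- matrix(runif(control$pop_size * npar), control$pop_size, npar)
  pop <- sweep(sweep(pop, 2, hi - lo, "*"), 2, lo, "+")
  obj <- apply(pop, 1, score)

  best_trace <- numeric(0)
  stall <- 0L
  for (gen in seq_len(control$generations)) {
    ord <- order(obj)
    pop <- pop[ord, , drop = FALSE]; obj <- obj[ord]
    bt <- obj[1]
    improved <- length(best_trace) == 0 || bt < min(best_trace) - 1e-15
    best_trace <- c(best_trace, if (length(best_trace)) min(min(best_trace), bt) else bt)
    stall <- if (improved) 0L else stall + 1L
    if (stall >= control$stall_generations) break
    if (gen == control$generations) break

    n_off <- control$pop_size - control$elite
    off <- matrix(0, n_off, npar)
    pick <- function() {
      idx <- sample.int(control$pop_size, control$tournament)
      idx[which.min(obj[idx])]
    }
    for (i in seq_len(n_off)) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      d <- abs(p1 - p2)
      child <- runif(npar, pmin(p1, p2) - control$crossover_alpha * d,
                     pmax(p1, p2) + control$crossover_alpha * d)
      mut <- runif(npar) < control$mutation_prob
      msd <- control$mutation_sd_frac * exp(-3 * gen / control$generations)
      child[mut] <- child[mut] + rnorm(sum(mut), 0, msd * (hi - lo)[mut])
      off[i, ] <- pmin(pmax(child, lo), hi)
    }
    off_obj <- apply(off, 1, score)
    pop <- rbind(pop[seq_len(control$elite), , drop = FALSE], off)
    obj <- c(obj[seq_len(control$elite)], off_obj)
  }
  ord <- order(obj)
  pop <- pop[ord, , drop = FALSE]; obj <- obj[ord]

  # --- local refinement (memetic stage) ---------------------------------
  # A fixed evaluation seed (common random numbers) makes the objective a
  # deterministic function so that downhill simplex search is meaningful.
  crn <- derive_seed(seed, 999999L)
  obj_crn <- function(x) {
    evals <<- evals + 1L
    objective_mse(setNames(x, nms), target, n_rep = control$n_rep, seed = crn)
  }
  scale01 <- function(x) (x - lo) / (hi - lo)
  unscale <- function(z) lo + pmin(pmax(z, 0), 1) * (hi - lo)
  # downhill-simplex polish over all parameters, or over a subset with the
  # remaining parameters held fixed
  polish <- function(x, free = seq_along(x), maxit = control$polish_maxit) {
    x0 <- x
    fn <- function(zf) {
      z <- scale01(x0); z[free] <- zf
      obj_crn(unscale(z))
    }
    r <- stats::optim(scale01(x0)[free], fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    z <- scale01(x0); z[free] <- r$par
    list(par = unscale(z), value = r$value)
  }

  best <- pop[1, ]; best_obj <- obj[1]
  if (control$polish_elites > 0 && best_obj < 1e6) {
    # pick mutually distinct elites (scaled distance) to polish
    starts <- list(pop[1, ])
    for (i in seq_len(nrow(pop))[-1]) {
      if (length(starts) >= control$polish_elites) break
      zi <- scale01(pop[i, ])
      if (all(vapply(starts, function(s)
        sqrt(sum((scale01(s) - zi)^2)), numeric(1)) > 0.05))
        starts <- c(starts, list(pop[i, ]))
    }
    cand <- lapply(starts, polish)
    vals <- vapply(cand, `[[`, numeric(1), "value")
    best <- cand[[which.min(vals)]]$par
    best_obj <- min(vals)

    if (control$hu_refine) {
      # The horizons round to whole steps inside the objective, so the
      # landscape is a rippled staircase along them, and the control
      # horizon trades off jointly against the stiffness and viscosity: a
      # broad spurious valley sits at the upper Hu bound with kP and kD
      # inflated, and population search regularly collapses into it. The
      # cure is a profile search: pin Hu at each value of a coarse grid,
      # polish the remaining four parameters, and keep the best profile
      # point before a final full polish and a local Hp line search.
      ihu <- match("Hu", nms); ihp <- match("Hp", nms)
      rest <- setdiff(seq_along(nms), ihu)
      for (hu in seq(lo[ihu], hi[ihu], by = 2 * target$dt)) {
        y <- best; y[ihu] <- hu
        r <- polish(y, free = rest,
                    maxit = max(60L, control$polish_maxit %/% 2L))
        if (r$value < best_obj) { best <- r$par; best_obj <- r$value }
      }
      r <- polish(best)
      if (r$value < best_obj) { best <- r$par; best_obj <- r$value }
      # profile over the prediction horizon as well: each whole-step cell
      # has its own locally optimal compensation of the other parameters
      hp_grid <- best[ihp] + (-5:5) * target$dt
      hp_grid <- hp_grid[hp_grid >= lo[ihp] & hp_grid <= hi[ihp]]
      rest_hp <- setdiff(seq_along(nms), ihp)
      for (hp in hp_grid) {
        y <- best; y[ihp] <- hp
        r <- polish(y, free = rest_hp,
                    maxit = max(40L, control$polish_maxit %/% 4L))
        if (r$value < best_obj) { best <- r$par; best_obj <- r$value }
      }
      r <- polish(best)
      if (r$value < best_obj) { best <- r$par; best_obj <- r$value }
    }
    best_trace <- c(best_trace, min(best_trace[length(best_trace)], best_obj))
  }

  best <- setNames(best, nms)
  par_report <- c(Hp = unname(best["Hp"]), Hu = unname(best["Hu"]) * 1e3,
                  kP = unname(best["kP"]), kD = unname(best["kD"]),
                  sigma = unname(best["sigma"]) * 1e3)
  structure(list(par = best, par_report = par_report, objective = best_obj,
                 trace = best_trace, evaluations = evals, seed = seed,
                 converged = best_obj < 1e6),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("Identified stance-model parameters\n")
  cat(sprintf("  Hp = %.3f s, Hu = %.1f ms, kP = %.3f mgh, kD = %.3f mgh, sigma = %.2f mNm\n",
              x$par_report["Hp"], x$par_report["Hu"], x$par_report["kP"],
              x$par_report["kD"], x$par_report["sigma"]))
  cat(sprintf("  objective %.3e rad^2 after %d evaluations%s\n", x$objective,
              x$evaluations, if (x$converged) "" else " (no stable candidate)"))
  invisible(x)
}

#' Batch identification over several target traces
#'
#' Runs [identify_parameters()] on each target with seeds derived from
#' `seed` and summarizes the recovered parameters as mean and standard
#' deviation, mirroring per-sequence identification followed by averaging.
#'
#' @param targets a list of [identification_target()] objects.
#' @inheritParams identify_parameters
#' @return A list with `results` (per-target `identification_result`),
#'   `estimates` (matrix, reporting units) and `summary` (data frame of
#'   mean/sd per parameter).
#' @export
identify_batch <- function(targets, bounds = parameter_bounds(),
                           control = ga_config(), seed = 1L) {
  results <- lapply(seq_along(targets), function(i)
    identify_parameters(targets[[i]], bounds, control,
                        seed = derive_seed(seed, 1000L + i)))
  est <- do.call(rbind, lapply(results, `[[`, "par_report"))
  list(results = results, estimates = est,
       summary = data.frame(parameter = colnames(est),
                            mean = colMeans(est),
                            sd = apply(est, 2, sd),
                            row.names = NULL))
}
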