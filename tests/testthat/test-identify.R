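# A compact scenario keeps identification tests affordable: a 0.25 s window
# around a fast ramp with a short true prediction horizon.
small_scene <- function(sigma = 0, Hp = 0.1, Hu = 0.012, seed = 1L) {
  params <- test_params(sigma = sigma)
  profile <- floor_profile(0, 0.1, 8.8)
  sim <- sim_config(t_start = -0.05, t_end = 0.2)
  ctrl <- mpc_controller(params, mpc_config(Hp = Hp, Hu = Hu))
  tr <- simulate_stance(params, ctrl, profile, sim, seed = seed)
  identification_target(tr, profile, params)
}

test_that("objective is zero at the generator and positive off it", {
  tgt <- small_scene()
  truth <- c(Hp = 0.1, Hu = 0.012, kP = 0.34, kD = 0.03, sigma = 0)
  expect_lt(objective_mse(truth, tgt, n_rep = 2, seed = 1), 1e-14)
  off <- truth; off["kP"] <- 0.68
  expect_gt(objective_mse(off, tgt, n_rep = 2, seed = 1), 1e-9)
})

test_that("objective equals hand-computed mean squared residuals on a toy", {
  # flat floor, zero noise, zero initial state: the simulated trace is
  # identically zero, so the MSE is the mean square of the target itself
  params <- test_params(sigma = 0)
  toy <- data.frame(t = c(0, 0.001, 0.002), theta = c(0.01, -0.02, 0.005))
  tgt <- identification_target(toy, floor_profile(0, 0.25, 0), params)
  got <- objective_mse(c(Hp = 0.01, Hu = 0.005, kP = 0.34, kD = 0.03,
                         sigma = 0), tgt, n_rep = 1, seed = 1)
  expect_equal(got, mean(c(0.01, -0.02, 0.005)^2))
})

test_that("objective is deterministic given candidate and seed", {
  tgt <- small_scene(sigma = 0.5e-3)
  cand <- c(Hp = 0.09, Hu = 0.01, kP = 0.3, kD = 0.02, sigma = 0.4e-3)
  expect_identical(objective_mse(cand, tgt, seed = 5),
                   objective_mse(cand, tgt, seed = 5))
  expect_false(identical(objective_mse(cand, tgt, seed = 5),
                         objective_mse(cand, tgt, seed = 6)))
})

test_that("unstable candidates receive the large finite penalty", {
  # a 10 ms horizon at the default operating point falls over under noise
  spec <- synth_trial_spec(params = test_params(sigma = 0))
  tgt <- identification_target(synth_trial(spec, 1), spec$profile,
                               spec$params)
  bad <- c(Hp = 0.01, Hu = 0.01, kP = 0.34, kD = 0.03, sigma = 0.5e-3)
  expect_equal(objective_mse(bad, tgt, n_rep = 3, seed = 1), 1e6)
})

test_that("identification recovers a noise-free generator inside a tight box", {
  tgt <- small_scene()
  bounds <- parameter_bounds(Hp = c(0.07, 0.13), Hu = c(0.008, 0.02),
                             kP = c(0.25, 0.45), kD = c(0.01, 0.06),
                             sigma = c(0, 1e-4))
  ctl <- ga_config(pop_size = 16, generations = 10, stall_generations = 6,
                   n_rep = 2, polish_elites = 2, polish_maxit = 400)
  res <- identify_parameters(tgt, bounds, ctl, seed = 2L)
  expect_true(res$converged)
  expect_lte(res$objective, 1e-6)
  # best-so-far objective is non-increasing over generations
  expect_true(all(diff(res$trace) <= 0))
  # horizon recovery bias within one sampling step
  expect_lt(abs(res$par[["Hp"]] - 0.1), 0.001 + 1e-9)
  # determinism of the whole search
  res2 <- identify_parameters(tgt, bounds, ctl, seed = 2L)
  expect_identical(res$par, res2$par)
  expect_identical(res$objective, res2$objective)
})

test_that("the generating parameters beat 2-SD perturbations in expectation", {
  tgt <- small_scene(sigma = 0.5e-3)
  truth <- c(Hp = 0.1, Hu = 0.012, kP = 0.34, kD = 0.03, sigma = 0.5e-3)
  pert <- truth + c(0.38, 0.0172, 0.26, 0.04, 0.46e-3)  # 2 printed SDs
  o_t <- sapply(1:10, function(s) objective_mse(truth, tgt, n_rep = 2, seed = s))
  o_p <- sapply(1:10, function(s) objective_mse(pert, tgt, n_rep = 2, seed = s))
  expect_lt(mean(o_t), mean(o_p))
})

test_that("batch identification summarizes mean and spread per parameter", {
  spec <- synth_trial_spec(params = test_params(sigma = 0),
                           mpc = mpc_config(Hp = 0.1, Hu = 0.012),
                           profile = floor_profile(0, 0.1, 8.8),
                           sim = sim_config(t_start = -0.05, t_end = 0.2))
  targets <- lapply(1:2, function(i)
    identification_target(synth_trial(spec, i), spec$profile, spec$params))
  bounds <- parameter_bounds(Hp = c(0.07, 0.13), Hu = c(0.008, 0.02),
                             kP = c(0.25, 0.45), kD = c(0.01, 0.06),
                             sigma = c(0, 1e-4))
  ctl <- ga_config(pop_size = 12, generations = 6, stall_generations = 4,
                   n_rep = 1, polish_elites = 1, polish_maxit = 80)
  batch <- identify_batch(targets, bounds, ctl, seed = 3L)
  expect_equal(dim(batch$estimates), c(2L, 5L))
  expect_named(batch$summary, c("parameter", "mean", "sd"))
  expect_true(all(batch$summary$sd >= 0))
})
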