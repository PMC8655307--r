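test_that("undisturbed noise-free closed loop stays exactly upright", {
  p <- test_params(sigma = 0)
  flat <- floor_profile(0, 0.25, 0)
  ctrls <- list(mpc_controller(p, mpc_config()),
                pd_controller(pd_config("linear"), p),
                pd_controller(pd_config("nonlinear"), p),
                no_controller())
  for (ctrl in ctrls) {
    tr <- simulate_stance(p, ctrl, flat, sim_config())
    expect_identical(max(abs(tr$theta)), 0)
    expect_identical(max(abs(tr$tau)), 0)
  }
})

test_that("noise-free simulation matches a high-order reference integrator", {
  p <- test_params(sigma = 0)
  fp <- floor_profile()
  cfg <- sim_config()
  ctrls <- list(mpc = mpc_controller(p, mpc_config(Hp = 0.3, Hu = 0.0244)),
                pd = pd_controller(pd_config("linear"), p),
                npd = pd_controller(pd_config("nonlinear"), p))
  for (ctrl in ctrls) {
    tr <- simulate_stance(p, ctrl, fp, cfg)
    ref <- reference_closed_loop(p, ctrl, fp, cfg)
    expect_lt(max(abs(tr$theta - ref$theta)), 1e-4)
  }
})

test_that("simulations are bit-reproducible under a fixed seed", {
  p <- pendulum_params()  # sigma = 0.5 mNm
  ctrl <- mpc_controller(p, mpc_config(Hp = 0.2, Hu = 0.02))
  a <- simulate_stance(p, ctrl, floor_profile(), sim_config(), seed = 11L)
  b <- simulate_stance(p, ctrl, floor_profile(), sim_config(), seed = 11L)
  c <- simulate_stance(p, ctrl, floor_profile(), sim_config(), seed = 12L)
  expect_identical(a$theta, b$theta)
  expect_identical(a$tau, b$tau)
  expect_false(identical(a$theta, c$theta))
  # the noise draw must not disturb the caller's RNG stream
  set.seed(99); r1 <- runif(1)
  set.seed(99)
  invisible(simulate_stance(p, ctrl, floor_profile(), sim_config(), seed = 5L))
  expect_identical(runif(1), r1)
})

test_that("the uncontrolled pendulum diverges from a small displacement", {
  # net stiffness mgh - kP > 0 and no viscous term: upright is unstable
  p <- test_params(sigma = 0, kD = 0)
  cfg <- sim_config(t_start = 0, t_end = 0.8, theta0 = 0.01)
  tr <- simulate_stance(p, no_controller(), floor_profile(0, 0.25, 0), cfg)
  first <- tr$theta[tr$t <= 0.3]
  expect_true(all(diff(abs(first)) > 0))
  # linearized closed form with damping: theta'' = a theta - b theta',
  # a = (mgh - kP)/J, b = kD/J, theta(0) = 0.01, theta'(0) = 0
  a <- (mgh(p) - p$kP) / p$J
  b <- p$kD / p$J
  r1 <- (-b + sqrt(b^2 + 4 * a)) / 2
  r2 <- (-b - sqrt(b^2 + 4 * a)) / 2
  tt <- tr$t[tr$t <= 0.3]
  closed <- 0.01 * (r2 * exp(r1 * tt) - r1 * exp(r2 * tt)) / (r2 - r1)
  expect_equal(first, closed, tolerance = 1e-2)
  expect_false(is_stable(tr))
})

test_that("a controller emitting non-finite torque aborts with the step", {
  p <- test_params(sigma = 0)
  ctrl <- pd_controller(pd_config("linear"), p)
  ctrl$g[1] <- NaN
  cfg <- sim_config(theta0 = 0.01)
  expect_error(simulate_stance(p, ctrl, floor_profile(), cfg),
               "non-finite torque at step")
})

test_that("noise scaling modes differ by the documented sqrt(dt) factor", {
  p <- pendulum_params()
  ctrl <- pd_controller(pd_config("linear"), p)
  a <- simulate_stance(p, ctrl, floor_profile(0, 0.25, 0),
                       sim_config(noise_scaling = "per-sample"), seed = 3L)
  b <- simulate_stance(p, ctrl, floor_profile(0, 0.25, 0),
                       sim_config(noise_scaling = "sqrt-dt"), seed = 3L)
  # same noise path, amplified 1/sqrt(dt): responses scale accordingly
  expect_gt(sd(b$theta), 10 * sd(a$theta))
})
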