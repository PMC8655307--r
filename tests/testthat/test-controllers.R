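test_that("PD baselines reproduce hand-computed torques", {
  p <- pendulum_params()
  s <- mgh(p)   # 0.4240667 N m
  lin <- pd_config("linear")
  expect_equal(pd_control(lin, p, 0, 0), 0)
  # Peterka gains: -1.46 * 0.42407 * 0.1 = -0.061914
  expect_equal(pd_control(lin, p, 0.1, 0), -0.061914, tolerance = 1e-4)
  # -0.3 * 0.42407 * 0.1 = -0.012722
  expect_equal(pd_control(lin, p, 0, 0.1), -0.012722, tolerance = 1e-4)
  nl <- pd_config("nonlinear")
  expect_equal(nonlinear_pd_control(nl, p, 0, 0), 0)
  # (196 * 0.05^2 + 0.88 * 0.05) * 0.42407 = 0.226452
  expect_equal(nonlinear_pd_control(nl, p, 0.05, 0), -0.226452,
               tolerance = 1e-4)
  # odd symmetry of the quadratic term
  for (th in c(0.02, 0.1, 0.3))
    expect_equal(nonlinear_pd_control(nl, p, -th, 0),
                 -nonlinear_pd_control(nl, p, th, 0))
  expect_error(pd_control(nl, p, 0, 0), "linear variant")
  expect_error(nonlinear_pd_control(lin, p, 0, 0), "nonlinear variant")
  expect_error(pd_config("linear", kP_lin = -1), "non-negative")
})

test_that("closed-form preview gains equal the brute-force QP solution", {
  p <- test_params()
  m <- linearize_internal_model(p, 0.001)
  cases <- list(c(5, 1), c(20, 5), c(50, 25), c(120, 50), c(200, 40),
                c(100, 100))
  set.seed(7)
  for (cs in cases) {
    Np <- cs[1]; Nu <- cs[2]
    g <- mpc_gain(m, mpc_config(Hp = Np * 1e-3, Hu = Nu * 1e-3, dt = 1e-3))
    for (rep in 1:2) {
      x0 <- rnorm(2, 0, c(0.05, 0.3))
      phis <- cumsum(runif(Np, 0, 1e-3))
      phids <- c(diff(phis), 0) / 1e-3
      tp <- rnorm(1, 0, 0.01)
      u_qp <- qp_first_move(m, Np, Nu, x0, phis, phids, tp)
      u_cf <- mpc_control(g, x0, phis, phids, tp)
      expect_equal(u_cf, u_qp, tolerance = 1e-8)
    }
  }
})

test_that("one-step horizon reduces to the hand-solved scalar quadratic", {
  p <- test_params()
  m <- linearize_internal_model(p, 0.001)
  rho <- 1e-12
  g <- mpc_gain(m, mpc_config(Hp = 1e-3, Hu = 1e-3, dt = 1e-3,
                              input_move_regularizer = rho))
  x0 <- c(0.02, -0.1); phi0 <- 0.05; phid0 <- 0.2
  # minimize (C A x0 + C B u + C Bd d)^2  ->  u = -(C A x0 + C Bd d)/(C B)
  CA <- m$A[1, ]; CB <- m$B[1]; CBd <- m$Bd[1, ]
  u_hand <- -(sum(CA * x0) + sum(CBd * c(phi0, phid0))) / CB
  expect_equal(mpc_control(g, x0, phi0, phid0), u_hand, tolerance = 1e-4)
})

test_that("mpc_control is a stateless pure function with strict previews", {
  p <- test_params()
  g <- mpc_gain(linearize_internal_model(p, 0.001),
                mpc_config(Hp = 0.05, Hu = 0.01))
  expect_equal(mpc_control(g, c(0, 0), numeric(50), numeric(50)), 0)
  u1 <- mpc_control(g, c(0.01, 0.1), runif(50, 0, 0.1) * 0 + 0.05, numeric(50), 0.01)
  u2 <- mpc_control(g, c(0.01, 0.1), rep(0.05, 50), numeric(50), 0.01)
  expect_identical(u1, u2)
  expect_error(mpc_control(g, c(0, 0), numeric(49), numeric(50)), "Np")
  expect_error(mpc_control(g, c(0), numeric(50), numeric(50)), "length 2")
})

test_that("an approaching ramp in the preview triggers anticipatory torque", {
  p <- test_params()
  g <- mpc_gain(linearize_internal_model(p, 0.001),
                mpc_config(Hp = 0.2, Hu = 0.02))
  # ramp starts 100 ms into the 200 ms preview; plant still undisturbed
  fp <- floor_profile(0.1, 0.25, 8.8)
  tf <- (seq_len(g$Np) - 1) * 1e-3
  u <- mpc_control(g, c(0, 0), floor_angle(fp, tf), floor_rate(fp, tf))
  expect_gt(abs(u), 1e-6)
  u_qp <- qp_first_move(linearize_internal_model(p, 0.001), g$Np, g$Nu,
                        c(0, 0), floor_angle(fp, tf), floor_rate(fp, tf))
  expect_equal(u, u_qp, tolerance = 1e-8)
})

test_that("delay compensation reconstructs the current state", {
  p <- test_params()
  m <- linearize_internal_model(p, 0.001)
  # zero delay: measurement returned unchanged
  expect_equal(delay_compensate(m, c(0.1, -0.2), numeric(0), numeric(0),
                                numeric(0)), c(0.1, -0.2))
  # all-zero histories and measurement stay zero
  expect_equal(delay_compensate(m, c(0, 0), numeric(40), numeric(40),
                                numeric(40)), c(0, 0))
  expect_error(delay_compensate(m, c(0, 0), numeric(40), numeric(39),
                                numeric(40)), "same number")
  # noise-free closed loop at small amplitude (where the linearized
  # internal model is essentially exact): compensated estimate matches the
  # plant state to well under a microradian scale
  ctrl <- mpc_controller(p, mpc_config(Hp = 0.3, Hu = 0.02))
  fp <- floor_profile(0, 0.25, 0.88)
  tr <- simulate_stance(p, ctrl, fp, sim_config())
  d <- 40L
  for (k in c(300L, 400L, 500L, 700L)) {
    idx <- (k - d):(k - 1)
    est <- delay_compensate(m, c(tr$theta[k - d], tr$theta_dot[k - d]),
                            tr$tau[idx],
                            floor_angle(fp, tr$t[idx]),
                            floor_rate(fp, tr$t[idx]))
    expect_lt(abs(est[1] - tr$theta[k]), 1e-6)
  }
})
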