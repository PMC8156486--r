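test_that("concentration mapping is the scaled presence probability", {
  expect_equal(unname(to_concentration(c(S = 1), scale_params(1, 1))), 1)
  expect_equal(unname(to_concentration(c(S = 0.25),
                                       scale_params(N = 2, V = 0.5))), 1)
  sc <- scale_params(N = 5, V = 2)
  q <- c(A = 0.3, B = 0.9)
  expect_equal(to_probability(to_concentration(q, sc), sc), q)
})

test_that("mass-action right-hand side implements Omega r(u)", {
  r <- mass_action_reaction(c(S1 = 2), c(S3 = 1, S4 = 1), kf = 1, kr = 1)
  expect_equal(mass_action_rhs(c(S1 = 2, S3 = 0, S4 = 0), list(r)),
               c(S1 = -8, S3 = 4, S4 = 4))
  r0 <- mass_action_reaction(c(A = 1), c(B = 1), kf = 0, kr = 0)
  expect_equal(mass_action_rhs(c(A = 1, B = 2), list(r0)),
               c(A = 0, B = 0))
  # detailed balance: kf * u^sigma == kr * u^rho gives a fixed point
  rq <- mass_action_reaction(c(A = 1, B = 1), c(C = 1), kf = 2, kr = 4)
  u <- c(A = 1, B = 2, C = 1)   # 2*1*2 == 4*1
  expect_equal(mass_action_rhs(u, list(rq)), c(A = 0, B = 0, C = 0))
  expect_error(mass_action_rhs(c(A = -1, B = 1, C = 1), list(rq)),
               "negative")
})

test_that("coupled-network rate constants match their closed forms", {
  expect_equal(table1_constants(0.2, 0.5, 0.5),
               c(kappa1 = 7.5, kappa2 = 0.5, kappa3 = 0.5, kappa4 = 7.5))
  k <- table1_constants(0.3, 0.3, 0.4)
  expect_equal(unname(k[c("kappa1", "kappa4")]), c(0, 0))
  k <- table1_constants(0.2, 0.5, 1 - 1e-12)
  expect_equal(unname(k[["kappa3"]]), 0, tolerance = 1e-9)

  # dual route: the same constants derived from the generative model
  set.seed(31)
  for (i in 1:5) {
    a1 <- runif(1, 0.05, 0.4); a2 <- runif(1, a1 + 0.05, 0.95)
    z <- runif(1, 0.1, 0.9)
    kc <- catflow:::reaction_constants(coupled_reaction_model(a1, a2, z),
                                       corrected = TRUE)
    tab <- table1_constants(a1, a2, z)
    expect_equal(unname(c(kc$r1$kf, kc$r1$kr, kc$r2$kf, kc$r2$kr)),
                 unname(tab), tolerance = 1e-12)
  }
})

test_that("enzymatic rate constants match their closed forms", {
  sys <- enzymatic_system(0.5, 0.5, z = 0.5, c = 0)
  expect_equal(sys$kappa,
               c(kappa1 = 2, kappa2 = 0.5, kappa3 = 0.5, kappa4 = 2))
  # at the throughput bound the reverse catalytic constant vanishes
  sysb <- enzymatic_system(0.3, 0.5, z = 0.6, c = (1 - 0.6) * (1 - 0.3))
  expect_equal(unname(sysb$kappa[["kappa4"]]), 0)
  expect_error(enzymatic_system(0.3, 0.5, z = 0.6, c = 0.5), "exceed")

  # non-negativity across a sweep respecting the bound, and agreement with
  # the constants derived from the generative model
  set.seed(32)
  for (i in 1:10) {
    a1 <- runif(1, 0.05, 0.95); a2 <- runif(1, 0.05, 0.95)
    z <- runif(1, 0.05, 0.95)
    cc <- runif(1, 0, (1 - z) * (1 - a1))
    sys <- enzymatic_system(a1, a2, z = z, c = cc)
    expect_true(all(sys$kappa >= 0))
    kc <- catflow:::reaction_constants(sys$model, corrected = TRUE)
    expect_equal(unname(c(kc$r1$kf, kc$r1$kr, kc$r2$kf, kc$r2$kr)),
                 unname(sys$kappa), tolerance = 1e-10)
  }
})

test_that("enzymatic dynamics conserve the enzyme moiety and hold their
           fixed point", {
  sys <- enzymatic_system(0.2, 0.5, z = 0.9, c = 0.05)
  # an empty system only receives the source
  expect_equal(unname(enzymatic_rhs(c(S = 0, E = 0, C = 0, P = 0),
                                    sys$kappa, sys$c)[["S"]]), 0.05)
  # closed system at its equilibrium
  sys0 <- enzymatic_system(0.2, 0.5, z = 0.9, c = 0)
  m0 <- model_marginals(sys0$model)
  expect_lte(max(abs(enzymatic_rhs(
    c(S = m0[["S"]], E = m0[["E"]], C = m0[["C"]], P = m0[["P"]]),
    sys0$kappa, 0))), 1e-14)

  m <- model_marginals(sys$model)
  tr <- simulate_enzymatic(sys, c(S = m[["S"]] + m[["C"]] + m[["P"]],
                                  E = 1, C = 0, P = 0), seq(0, 400, 0.5))
  expect_lte(diff(range(tr$states[, "E"] + tr$states[, "C"])), 1e-8)
  expect_gte(min(tr$states), -1e-10)
  expect_lte(max(abs(final_state(tr) - m[c("S", "E", "C", "P")])), 1e-3)
})

test_that("probabilistic and mass-action pictures of the pair reaction
           coincide", {
  alpha <- 1/4
  m <- reaction_model(alpha = alpha)
  times <- seq(0, 60, 0.25)
  q0 <- c(S1 = 1, S2 = 1, S3 = 0, S4 = 0)
  trq <- meanfield_simulate(m, q0, times, model = m)

  sc <- scale_params(N = 2, V = 0.5)   # u = 4 q
  kap1 <- sc$lambda * sc$V / sc$N
  kap2 <- kap1 * corrected_beta(alpha, 2, 2)
  rx <- mass_action_reaction(c(S1 = 1, S2 = 1), c(S3 = 1, S4 = 1),
                             kf = kap1, kr = kap2)
  u0 <- to_concentration(q0, sc)
  sol <- deSolve::ode(y = u0, times = times, parms = NULL,
                      func = function(t, y, p)
                        list(mass_action_rhs(y, list(rx))),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  u_traj <- unname(sol[, -1])
  q_as_u <- t(apply(trq$states, 1, to_concentration, scale = sc))
  expect_lte(max(abs(u_traj - q_as_u)), 1e-6)

  # equilibrium ratio kappa1 u1 u2 = kappa2 u3 u4
  uf <- u_traj[nrow(u_traj), ]
  expect_lte(abs(kap1 * uf[1] * uf[2] - kap2 * uf[3] * uf[4]), 1e-8)

  # the probabilistic image descends its free energy all along
  expect_lte(max(diff(trq$free_energy)), 1e-6)
})

test_that("Michaelis-Menten reduction obeys its limits and converges with
           timescale separation", {
  red <- michaelis_menten(v_max = 2, kappa_m = 0.5)
  expect_equal(mm_rate(red, 0.5), 1)        # half saturation
  expect_equal(mm_rate(red, 0), 0)
  expect_gt(mm_rate(red, 500), 2 * 0.999)   # saturation

  a1 <- 0.95; a2 <- 0.5; cc <- 0.9 * (1 - 0.99) * (1 - a1)
  expect_warning(mm_reduce(enzymatic_system(a1, a2, z = 0.5, c = cc), 1),
                 "quasi-equilibrium")

  sys <- enzymatic_system(a1, a2, z = 0.99, c = cc)
  red <- mm_reduce(sys, 1)
  expect_equal(red$kappa_m,
               unname(sys$kappa[["kappa2"]] / sys$kappa[["kappa1"]]))
  expect_equal(red$v_max, unname(sys$kappa[["kappa3"]]))
  uS0 <- 0.9
  uC0 <- uS0 / (red$kappa_m + uS0)
  times <- seq(0, 6000, 10)
  full <- simulate_enzymatic(sys, c(S = uS0, E = 1 - uC0, C = uC0, P = 0),
                             times)
  mmtr <- simulate_mm(red, c(S = uS0, P = 0), times, c = cc)
  rel_err <- max(abs(mmtr$states[, "P"] - full$states[, "P"])) /
    max(full$states[, "P"])
  expect_lt(rel_err, 0.05)
})
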