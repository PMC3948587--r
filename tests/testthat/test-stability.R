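test_that("the analytic Jacobian matches central finite differences", {
  par <- ref_params(m = 0.9, phi = 0.35, rho = 0.8)
  set.seed(10)
  for (i in 1:100) {
    st <- random_state()
    J <- jacobian_allele_ld(st, par)
    fd <- vapply(1:6, function(j) {
      h <- 1e-6; e <- rep(0, 6); e[j] <- h
      (allele_ld_rhs(st + e, par) - allele_ld_rhs(st - e, par)) / (2 * h)
    }, numeric(6))
    expect_lt(max(abs(J - fd)) / max(1, max(abs(J))), 1e-6)
  }
  # demes decouple at m = 0: cross-deme blocks vanish
  par0 <- model_parameters(0.5, -1, 2, -2, m1 = 0, m2 = 0, rho = 1,
                           canonicalize = FALSE)
  J0 <- jacobian_allele_ld(random_state(), par0)
  d1 <- c("p1", "q1", "D1"); d2 <- c("p2", "q2", "D2")
  expect_equal(max(abs(J0[d1, d2])), 0)
  expect_equal(max(abs(J0[d2, d1])), 0)
})

test_that("closed-form monomorphic stability matches the eigenvalues", {
  # low total migration: no monomorphic equilibrium is stable
  par_small <- ref_params(m = 0.05, phi = 0.4, rho = 1)
  v <- monomorphic_stability(par_small)
  expect_true(all(vapply(v, `[[`, "", "classification") == "unstable"))
  # M3 stability is independent of the recombination rate
  sel <- ref_sel_strongB()
  for (rho in c(0, 0.3, 5)) {
    par <- ref_params(m = 25, phi = 0.45, rho = rho)
    expect_equal(monomorphic_stability(par)$M3$classification,
                 "asymptotically_stable")
  }
  # oracle agreement over random draws (away from condition boundaries)
  set.seed(12)
  sw <- generate_sweep(300, seed = 12, m_range = c(0.05, 30))
  me <- monomorphic_equilibria()
  n_checked <- 0
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ])
    cf <- monomorphic_stability(par)
    for (lab in names(me)) {
      slack <- cf[[lab]]$slack
      if (!is.null(slack) && is.finite(slack) && abs(slack) < 1e-3) next
      ev <- classify_equilibrium(me[[lab]], par)
      expect_equal(ev$classification, cf[[lab]]$classification,
                   info = sprintf("draw %d, %s", i, lab))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 1000)
})

test_that("F0 stability follows the m1*m2 threshold, including the margin", {
  par <- model_parameters(0.5, -1, 2, -2, m1 = 0.5, m2 = 0.5, rho = 0,
                          canonicalize = FALSE)
  v <- f_zero_stability(par)
  expect_equal(v$m_tilde, 15)
  expect_equal(v$classification, "asymptotically_stable")
  expect_equal(classify_equilibrium(f_zero(par), par,
                                    subsystem = "trigametic")$classification,
               "asymptotically_stable")
  # the line-of-equilibria margin: m1*m2 = m_tilde gives a zero eigenvalue
  par_line <- model_parameters(0.5, -1, 2, -2, m1 = 4, m2 = 3.75, rho = 0,
                               canonicalize = FALSE)
  expect_equal(f_zero_stability(par_line)$classification, "marginal")
  evs <- classify_equilibrium(f_zero(par_line), par_line,
                              subsystem = "trigametic")$eigenvalues
  expect_lt(min(abs(Re(evs))), 1e-10)
  # inadmissible F0 is rejected
  par_out <- ref_params(m = 30, phi = 0.5, rho = 0)
  expect_error(f_zero_stability(par_out), "not admissible")
})

test_that("rho = 0 SLP stability matches the tri-gametic eigenvalues", {
  set.seed(13)
  sw <- generate_sweep(200, seed = 13, m_range = c(0.05, 25))
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ], rho = 0)
    cf <- slp_stability_rho0(par)
    slp <- slp_equilibria(par)
    for (lab in c("PA1", "PB2")) {
      if (!slp[[lab]]$admissible) next
      if (abs(cf[[lab]]$slack) < 1e-3) next
      ev <- classify_equilibrium(slp[[lab]], par, subsystem = "trigametic")
      expect_equal(ev$classification, cf[[lab]]$classification,
                   info = sprintf("draw %d %s", i, lab))
    }
    # if m1*m2 < m_tilde both SLPs are unstable (whenever admissible)
    if (par$migration$m1 * par$migration$m2 < m_tilde(par) - 1e-6) {
      for (lab in c("PA1", "PB2"))
        expect_false(cf[[lab]]$classification == "asymptotically_stable")
    }
  }
})

test_that("at most one of M1, M3, M4 is stable; F0 excludes M3", {
  set.seed(14)
  sw <- generate_sweep(400, seed = 14, m_range = c(0.05, 40))
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ])
    v <- monomorphic_stability(par)
    stable <- sum(vapply(v[c("M1", "M3", "M4")], `[[`, "", "classification") ==
                    "asymptotically_stable")
    expect_lte(stable, 1)
    par0 <- migsel2:::sweep_params(sw[i, ], rho = 0)
    if (f_zero(par0)$admissible) {
      f0v <- f_zero_stability(par0)
      if (f0v$classification == "asymptotically_stable")
        expect_false(monomorphic_stability(par0)$M3$classification ==
                       "asymptotically_stable")
    }
  }
})

test_that("with complete linkage the repulsed gamete A1B2 is always lost", {
  set.seed(15)
  sw <- generate_sweep(5, seed = 15)
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ], rho = 0)
    st <- random_state()
    r <- integrate_dynamics(st, par, horizon = 2e4, rhs_tol = 1e-10)
    x <- state_to_gametes(migsel2:::clip_state(r$state, tol = 1e-6),
                          check = FALSE)
    expect_lt(max(x[2, ]), 1e-4)
  }
})
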