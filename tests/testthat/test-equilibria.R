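test_that("monomorphic equilibria are dynamics roots for any parameters", {
  me <- monomorphic_equilibria()
  expect_equal(unname(me$M1$state), c(1, 1, 1, 1, 0, 0))
  expect_equal(unname(me$M4$state), c(0, 0, 0, 0, 0, 0))
  set.seed(7)
  sw <- generate_sweep(25, seed = 7)
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ])
    for (e in me) expect_lt(max(abs(allele_ld_rhs(e$state, par))), 1e-12)
  }
})

test_that("single-locus polymorphisms have exact coordinates and limits", {
  sel <- ref_sel_strongB()
  par0 <- model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                           m1 = 0, m2 = 0, rho = 1, canonicalize = FALSE)
  slp0 <- slp_equilibria(par0)
  expect_equal(unname(slp0$PA1$state[c("p1", "p2")]), c(1, 0))
  # marginal one-locus residuals vanish at the SLP frequencies
  par <- ref_params(m = 1, phi = 3 / 8, rho = "LE")
  slp <- slp_equilibria(par)
  expect_lt(max(abs(le_rhs(slp$PA1$state[1:4], par))), 1e-12)
  expect_lt(max(abs(le_rhs(slp$PB2$state[1:4], par))), 1e-12)
  # as sigma1 + sigma2 approaches 1 from below, PA1 approaches M3
  mtA <- m_thresholds(sel, 0.45)$m_A          # positive for phi > phi_A
  par_edge <- ref_params(m = mtA * (1 - 1e-9), phi = 0.45, rho = 1)
  slp_edge <- slp_equilibria(par_edge)
  expect_true(slp_edge$PA1$admissible)
  expect_equal(slp_edge$PA1$exit_target, "M3")
  expect_lt(max(abs(slp_edge$PA1$state -
                      monomorphic_equilibria()$M3$state)), 1e-4)
  # inadmissible records are flagged, not omitted
  par_out <- ref_params(m = mtA * 1.01, phi = 0.45, rho = 1)
  expect_false(slp_equilibria(par_out)$PA1$admissible)
  expect_length(slp_equilibria(par_out), 4)
})

test_that("the LE polymorphism exists iff all four SLPs are admissible", {
  set.seed(8)
  sw <- generate_sweep(200, seed = 8)
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ], rho = "LE")
    fi <- f_infinity(par)
    slp <- slp_equilibria(par)
    expect_equal(fi$admissible, all(vapply(slp, `[[`, TRUE, "admissible")))
    if (fi$admissible)
      expect_lt(max(abs(le_rhs(fi$state[1:4], par))), 1e-10)
  }
})

test_that("the complete-linkage polymorphism F0 matches its closed form", {
  par <- model_parameters(0.5, -1, 2, -2, m1 = 0.5, m2 = 0.5, rho = 0,
                          canonicalize = FALSE)
  r <- compute_ratios(par)
  expect_equal(r$kappa1, 0.2)
  expect_equal(r$kappa2, -1 / 6)
  fz <- f_zero(par)
  expect_true(fz$admissible)
  expect_lt(max(abs(allele_ld_rhs(fz$state, par))), 1e-12)
  expect_equal(unname(fz$state["D1"]),
               unname(fz$state["p1"] * (1 - fz$state["p1"])))
  # integration oracle: the tri-gametic flow converges to F0
  z <- integrate_trig(c(0.5, 0.2, 0.3, 0.2), par)
  expect_lt(max(abs(z - migsel2:::state_to_trigametic(fz$state))), 1e-6)
  # m = 0 limit and the exit through M4 as kappa1 + kappa2 approaches 1
  par0 <- model_parameters(0.5, -1, 2, -2, m1 = 0, m2 = 0, rho = 0,
                           canonicalize = FALSE)
  expect_equal(unname(f_zero(par0)$state[c("p1", "p2")]), c(1, 0))
  mF0 <- abs(m_thresholds(ref_sel_strongB(), 0.8)$m_F0)
  par_e <- ref_params(m = mF0 * (1 - 1e-9), phi = 0.8, rho = 0)
  expect_lt(max(abs(f_zero(par_e)$state -
                      monomorphic_equilibria()$M4$state)), 1e-4)
})

test_that("the weak-migration expansion has the stated leading order", {
  sel <- ref_sel_strongB()
  par0 <- model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                           m1 = 0, m2 = 0, rho = 1, canonicalize = FALSE)
  expect_equal(unname(weak_migration_F(par0)$state), c(1, 0, 1, 0, 0, 0))
  # direct substitution: D1 = m1 / (alpha1 + beta1 + rho)
  pard <- model_parameters(0.5, -1, 2, -2, m1 = 0.01, m2 = 0.01, rho = 0,
                           canonicalize = FALSE)
  expect_equal(unname(weak_migration_F(pard)$state["D1"]), 0.004)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(m) {
    p <- ref_params(m = m, phi = 0.4, rho = 1)
    wf <- weak_migration_F(p)
    nr <- migsel2:::newton_equilibrium(wf$state, p)
    expect_true(nr$converged)
    max(abs(wf$state - nr$state))
  }, 0)
  slope <- coef(lm(log(errs) ~ log(c(1e-2, 1e-3, 1e-4))))[[2]]
  expect_lt(abs(slope - 2), 0.2)
})

test_that("the QLE expansion converges to Finf with order 1/rho^2", {
  sel <- ref_sel_strongB()
  parbig <- ref_params(m = 1, phi = 0.45, rho = 1e9)
  qf <- qle_F(parbig)
  fi <- f_infinity(parbig)
  expect_lt(max(abs(qf$state[1:4] - fi$state[1:4])), 1e-8)
  # positive LD whenever the demes are differentiated
  parq <- ref_params(m = 1, phi = 0.45, rho = 50)
  expect_gt(qle_F(parq)$state[["D1"]], 0)
  expect_gt(qle_F(parq)$state[["D2"]], 0)
  errs <- vapply(c(10, 100, 1000), function(r) {
    p <- ref_params(m = 1, phi = 0.45, rho = r)
    qf <- qle_F(p)
    nr <- migsel2:::newton_equilibrium(qf$state, p)
    max(abs(qf$state - nr$state))
  }, 0)
  slope <- coef(lm(log(errs) ~ log(c(10, 100, 1000))))[[2]]
  expect_lt(abs(slope + 2), 0.2)
  # rejected when Finf is not admissible
  par_bad <- ref_params(m = 30, phi = 0.45, rho = 50)
  expect_false(f_infinity(par_bad)$admissible)
  expect_error(qle_F(par_bad), "not admissible")
})

test_that("the numerical root search finds the internal equilibria", {
  parw <- ref_params(m = 0.01, phi = 0.4, rho = 1)
  roots <- find_internal(parw)
  expect_length(roots, 1)
  expect_lt(max(abs(roots[[1]]$state - weak_migration_F(parw)$state)), 1e-3)
  # internal equilibria always exhibit LD
  set.seed(9)
  sw <- generate_sweep(20, seed = 9, rho_range = c(0.2, 2))
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ])
    for (e in find_internal(par, n_starts = 16)) {
      expect_gt(abs(e$state[["D1"]]), 1e-12)
      expect_gt(abs(e$state[["D2"]]), 1e-12)
    }
  }
  # highly asymmetric migration with intermediate recombination: a stable
  # and an unstable fully polymorphic equilibrium coexist
  parci <- model_parameters(1, -2, 1.2, -1, m = 1.2, phi = 0.99, rho = 1.2,
                            canonicalize = FALSE)
  ints <- find_internal(parci, n_starts = 60)
  expect_equal(length(ints), 2)
  cls <- sort(vapply(ints, function(e)
    classify_equilibrium(e, parci)$classification, ""))
  expect_equal(cls, c("asymptotically_stable", "unstable"))
})
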