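test_that("the one-locus invasion threshold matches its closed form", {
  oli <- one_locus_invasion(0.1, -0.1, m = 1, phi = 0.6)
  expect_equal(oli$phi_A, 0.5)
  expect_equal(oli$phi_inv, 0.55)
  expect_false(oli$invades)
  expect_true(one_locus_invasion(0.1, -0.1, m = 1, phi = 0.52)$invades)
  # phi_inv > 1 iff m < alpha1: invasion is then unconditional in phi
  expect_gt(one_locus_invasion(0.1, -0.1, m = 0.05, phi = 0.9)$phi_inv, 1)
  expect_true(one_locus_invasion(0.1, -0.1, m = 0.05, phi = 0.9)$unconditional)
  # the symmetric regime is redirected
  expect_error(one_locus_invasion(0.1, -0.1, m = 1, phi = 0.4), "relabel")
})

test_that("external stability of PB2 matches the LE criterion for large rho", {
  set.seed(25)
  sw <- generate_sweep(80, seed = 25, m_range = c(0.2, 3))
  checked <- 0
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ], rho = 1e4)
    r <- compute_ratios(par)
    if (abs(r$tau1 + r$tau2) >= 1) next
    mt <- m_thresholds(par, par$migration$phi)
    # LE: the mutant A1 invades at PB2 iff the A2-fixation boundary of the
    # marginal locus-A system is unstable, i.e. sigma1 + sigma2 < 1
    # (equivalently m < m_A when m_A > 0; always when m_A < 0). The
    # O(1/rho) correction to the collision rate scales with |m_A|^3, so
    # only draws with a safely resolvable margin are compared.
    mA <- mt$m_A
    if (mA > 0) {
      if (mA > 10) next
      margin <- max(0.05 * mA, 20 * mA^3 / 1e4)
      if (abs(par$migration$m - mA) < margin) next
      le_pred <- par$migration$m < mA
    } else le_pred <- TRUE
    es <- external_stability_PB2(par)
    expect_equal(es$invades, le_pred, info = paste("draw", i))
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("the complete-linkage invasion threshold is m1*m2 = m_tilde", {
  # As rho -> 0, PB2 is unstable (the mutant invades) iff m1*m2 < m_tilde;
  # alpha_min therefore converges to the root of m1*m2 = m_tilde(alpha1)
  a2 <- -0.1; b1 <- 2; b2 <- -1; m <- 1; phi <- 0.6
  mt_of <- function(a1) m_tilde(list(alpha1 = a1, alpha2 = a2,
                                     beta1 = b1, beta2 = b2))
  m1m2 <- m^2 * phi * (1 - phi)
  a_star <- uniroot(function(a1) mt_of(a1) - m1m2, c(1e-6, 0.1),
                    tol = 1e-12)$root
  par <- model_parameters(0.05, a2, b1, b2, m = m, phi = phi,
                          canonicalize = FALSE, rho = 1)
  a_small_rho <- alpha_min_for_invasion(par, rho = 1e-5)
  expect_equal(a_small_rho, a_star, tolerance = 1e-3)
  # sanity: eigenvalue signs flip across the threshold at tiny rho
  above <- migsel2:::params_raw(1.2 * a_star, a2, b1, b2, m1 = m * phi,
                                m2 = m * (1 - phi), rho = 1e-6)
  below <- migsel2:::params_raw(0.8 * a_star, a2, b1, b2, m1 = m * phi,
                                m2 = m * (1 - phi), rho = 1e-6)
  expect_true(external_stability_PB2(above)$invades)
  expect_false(external_stability_PB2(below)$invades)
})

test_that("one-way migration lets arbitrarily small effects invade", {
  # with no back migration m1*m2 = 0 < m_tilde, so for linkage tight
  # relative to the mutant's effect PB2 is unstable for any positive
  # effect; looser linkage blocks the same mutant
  par_tight <- migsel2:::params_raw(1e-4, -0.1, 2, -1, m1 = 1, m2 = 0,
                                    rho = 1e-5)
  expect_true(external_stability_PB2(par_tight)$invades)
  par_loose <- migsel2:::params_raw(1e-4, -0.1, 2, -1, m1 = 1, m2 = 0,
                                    rho = 1e-3)
  expect_false(external_stability_PB2(par_loose)$invades)
})

test_that("the maximum recombination rate for invasion behaves as derived", {
  base <- function(phi) model_parameters(0.1, -0.1, 2, -1, m = 1, phi = phi,
                                         rho = 1, canonicalize = FALSE)
  # below phi_inv = 0.55 invasion is unconditional in rho
  expect_true(is.infinite(rho_max_for_invasion(base(0.54))))
  r57 <- rho_max_for_invasion(base(0.57))
  r65 <- rho_max_for_invasion(base(0.65))
  expect_true(is.finite(r57) && is.finite(r65))
  expect_gt(r57, r65)        # decreasing in phi
  # the threshold is a genuine sign change of the leading eigenvalue
  p_in <- model_parameters(0.1, -0.1, 2, -1, m = 1, phi = 0.57,
                           rho = 0.9 * r57, canonicalize = FALSE)
  p_out <- model_parameters(0.1, -0.1, 2, -1, m = 1, phi = 0.57,
                            rho = 1.1 * r57, canonicalize = FALSE)
  expect_true(external_stability_PB2(p_in)$invades)
  expect_false(external_stability_PB2(p_out)$invades)
  # invasion verified by integration from a rare-mutant perturbation of PB2
  p_mid <- model_parameters(0.1, -0.1, 2, -1, m = 1, phi = 0.57,
                            rho = 0.5 * r57, canonicalize = FALSE)
  pb2 <- slp_equilibria(p_mid)$PB2$state
  start <- pb2; start[c("p1", "p2")] <- 1e-6
  r <- integrate_dynamics(start, p_mid, horizon = 2e5, rhs_tol = 1e-9)
  expect_gt(min(r$state[c("p1", "p2")]), 1e-2)
})

test_that("the minimum selective advantage falls with tighter linkage", {
  par <- model_parameters(0.05, -0.1, 2, -1, m = 1, phi = 0.6,
                          canonicalize = FALSE, rho = 1)
  a_by_rho <- vapply(c(0.05, 0.5, 2, 20), function(r)
    alpha_min_for_invasion(par, rho = r), 0)
  expect_true(all(diff(a_by_rho) > 0))
  # rho -> Inf recovers the one-locus threshold
  a_inf <- alpha_min_for_invasion(par, rho = 1e5)
  one_locus <- -0.1 * 1 * 0.6 / (-0.1 - 1 * 0.4)
  expect_equal(a_inf, one_locus, tolerance = 1e-3)
  # more symmetric migration facilitates invasion
  par55 <- model_parameters(0.05, -0.1, 2, -1, m = 1, phi = 0.55,
                            canonicalize = FALSE, rho = 1)
  expect_lt(alpha_min_for_invasion(par55, rho = 1),
            alpha_min_for_invasion(par, rho = 1))
})
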