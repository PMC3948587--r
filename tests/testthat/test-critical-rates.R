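test_that("migration/selection ratios satisfy their identities", {
  par0 <- model_parameters(0.5, -1, 2, -2, m1 = 0, m2 = 0, rho = 1,
                           canonicalize = FALSE)
  expect_true(all(unlist(compute_ratios(par0)) == 0))
  set.seed(16)
  sw <- generate_sweep(300, seed = 16)
  for (i in seq_len(nrow(sw))) {
    par <- migsel2:::sweep_params(sw[i, ])
    r <- compute_ratios(par)
    expect_true(r$sigma1 > 0 && r$sigma2 < 0)
    expect_true(r$tau1 > 0 && r$tau2 < 0)
    # harmonic identity 1/kappa = 1/sigma + 1/tau
    expect_lt(abs(1 / r$kappa1 - 1 / r$sigma1 - 1 / r$tau1), 1e-12)
    expect_lt(abs(1 / r$kappa2 - 1 / r$sigma2 - 1 / r$tau2), 1e-12)
    ss <- r$sigma1 + r$sigma2; tt <- r$tau1 + r$tau2
    if (ss >= 0) expect_lt(tt, ss) else expect_lt(tt, 0)
  }
})

test_that("the migration-ratio thresholds reproduce the reference values", {
  ph <- phi_thresholds(ref_sel_strongB(), rho = 0)
  expect_equal(ph$phi_A, 1 / 3)
  expect_equal(ph$phi_B, 1 / 2)
  expect_equal(ph$phi_AB, 3 / 8)
  expect_equal(ph$phi_AB_tilde, 1 / 4)
  expect_equal(ph$phi_M1, 5 / 17)
  expect_equal(ph$phi_M4, 5 / 8)
  ph2 <- phi_thresholds(ref_sel_crossed(), rho = 0)
  expect_equal(ph2$phi_M1, 1 / 26)
  expect_equal(ph2$phi_A, 1 / 6)
  expect_equal(ph2$phi_AB, 1 / 2)
  expect_equal(ph2$phi_B, 5 / 6)
  expect_equal(ph2$phi_M4, 25 / 26)
  # symmetric selection: phi_A = phi_B = 1/2
  phs <- phi_thresholds(list(alpha1 = 0.3, alpha2 = -0.3,
                             beta1 = 0.7, beta2 = -0.7))
  expect_equal(phs$phi_A, 0.5)
  expect_equal(phs$phi_B, 0.5)
})

test_that("threshold orderings hold for random canonical draws", {
  set.seed(17)
  sw <- generate_sweep(500, seed = 17)
  for (i in seq_len(nrow(sw))) {
    s <- as.list(sw[i, 1:4])
    ph <- phi_thresholds(s, rho = 0)
    expect_true(0 < ph$phi_A && ph$phi_A < ph$phi_AF0 &&
                ph$phi_AF0 < ph$phi_AB && ph$phi_AB < ph$phi_BF0 &&
                ph$phi_BF0 < ph$phi_B && ph$phi_B < 1)
    expect_true(ph$phi_AF0 < ph$phi_F0 && ph$phi_F0 < ph$phi_BF0)
    if (s$beta2 < s$alpha2) {
      expect_true(0 < ph$phi_AB_tilde && ph$phi_AB_tilde < ph$phi_A)
      expect_lt(ph$phi_AB_tilde, ph$phi_M1)
    }
    expect_true(0 < ph$phi_M1 && ph$phi_M1 < ph$phi_A)
    expect_true(ph$phi_B < ph$phi_M4 && ph$phi_M4 < 1)
    tt <- s$alpha1 * s$alpha2 - s$beta1 * s$beta2
    if (tt > 0) expect_lt(ph$phi_AB, ph$phi_F0)
    if (tt < 0) expect_lte(ph$phi_F0, ph$phi_AB)
  }
})

test_that("critical migration rates satisfy their defining identities", {
  sel <- ref_sel_strongB()
  mt0 <- m_thresholds(sel, 0)
  expect_equal(mt0$m_A, sel$alpha2)
  mt <- m_thresholds(sel, 3 / 8)
  expect_equal(mt$m_A, 8)
  expect_equal(mt$m_B, -8)
  expect_equal(mt$m_star, 8)
  expect_equal(mt$m_tilde, 15)
  ph <- phi_thresholds(sel, rho = 0)
  # at phi_AB: m_A = -m_B = m_star
  mAB <- m_thresholds(sel, ph$phi_AB)
  expect_lt(abs(mAB$m_A + mAB$m_B), 1e-12)
  expect_lt(abs(mAB$m_A - mAB$m_star), 1e-12)
  # at phi_AB_tilde: m_A = m_B < 0
  mABt <- m_thresholds(sel, ph$phi_AB_tilde)
  expect_lt(abs(mABt$m_A - mABt$m_B), 1e-12)
  expect_lt(mABt$m_A, 0)
  # at phi_M4 (rho = 0): m_M4 = m_B and m_B = m_F0 = m_star
  mM4 <- m_thresholds(sel, ph$phi_M4)
  expect_lt(abs(mM4$m_M4 - mM4$m_B), 1e-10)
  expect_lt(abs(mM4$m_B - mM4$m_F0), 1e-10)
  expect_lt(abs(mM4$m_B - mM4$m_star), 1e-10)
  # at phi_M1 (rho = 0): -m_A = -m_F0 = m_star
  mM1 <- m_thresholds(sel, ph$phi_M1)
  expect_lt(abs(mM1$m_A - mM1$m_F0), 1e-10)
  expect_lt(abs(-mM1$m_A - mM1$m_star), 1e-10)
  # rho = 0 collapses m_F0, m_M4 and -m_M1
  m5 <- m_thresholds(sel, 0.42, rho = 0)
  expect_equal(m5$m_F0, m5$m_M4)
  expect_equal(m5$m_F0, -m5$m_M1)
  # exact infinity sentinels at the defining ratios
  expect_true(is.infinite(m_thresholds(sel, ph$phi_A)$m_A))
  expect_true(is.infinite(m_thresholds(sel, ph$phi_B)$m_B))
  expect_true(is.infinite(m_thresholds(sel, 0)$m_star))
  # bounds: alpha2 <= m_A <= alpha1 etc.
  # the reciprocal of each admissibility rate interpolates linearly between
  # the reciprocal selection bounds (attained at phi = 0 and phi = 1)
  set.seed(18)
  for (phi in runif(50)) {
    m <- m_thresholds(sel, phi)
    expect_true(1 / m$m_A >= 1 / sel$alpha2 - 1e-12 &&
                  1 / m$m_A <= 1 / sel$alpha1 + 1e-12)
    expect_true(1 / m$m_B >= 1 / sel$beta2 - 1e-12 &&
                  1 / m$m_B <= 1 / sel$beta1 + 1e-12)
    expect_true(1 / m$m_F0 >= 1 / (sel$alpha2 + sel$beta2) - 1e-12 &&
                  1 / m$m_F0 <= 1 / (sel$alpha1 + sel$beta1) + 1e-12)
    expect_gt(m$m_star, 0)
  }
  expect_equal(m_thresholds(sel, 0)$m_A, sel$alpha2)
  expect_equal(m_thresholds(sel, 1)$m_A, sel$alpha1)
  # m_star is symmetric about 1/2 and minimized there
  grid <- seq(0.05, 0.95, by = 0.05)
  ms <- vapply(grid, function(p) m_thresholds(sel, p)$m_star, 0)
  expect_equal(ms, rev(ms), tolerance = 1e-12)
  expect_equal(which.min(ms), which(grid == 0.5))
})

test_that("maximum migration rates: closed forms, shapes and inequality", {
  sel <- ref_sel_strongB()
  expect_equal(m_max_LE(sel, 3 / 8), 8)
  expect_equal(m_max_rho0(sel, 3 / 8), 8)
  expect_equal(m_max_rho0(sel, 0.45),
               min(abs(m_thresholds(sel, 0.45)$m_F0),
                   m_thresholds(sel, 0.45)$m_star))
  ph <- phi_thresholds(sel, rho = 0)
  grid <- seq(0.02, 0.98, by = 0.004)
  mle <- vapply(grid, function(p) m_max_LE(sel, p), 0)
  expect_equal(grid[which.max(mle)], ph$phi_AB, tolerance = 0.01)
  # kink (one-sided slopes differ) at phi_AB_tilde, smooth in between
  slopes_at <- function(p0, eps = 1e-5) {
    f <- function(p) m_max_LE(sel, p)
    c(left = (f(p0) - f(p0 - eps)) / eps, right = (f(p0 + eps) - f(p0)) / eps)
  }
  sk <- slopes_at(ph$phi_AB_tilde)
  expect_gt(abs(sk["right"] - sk["left"]), 0.1 * abs(sk["left"]))
  ssm <- slopes_at(0.5 * (ph$phi_AB_tilde + ph$phi_A))
  expect_lt(abs(ssm["right"] - ssm["left"]), 1e-2 * abs(ssm["left"]))
  # complete linkage dominates LE, with equality only at phi_AB
  set.seed(19)
  sw <- generate_sweep(1000, seed = 19)
  for (i in seq_len(nrow(sw))) {
    s <- as.list(sw[i, 1:4])
    phi <- sw$phi[i]
    expect_lte(m_max_LE(s, phi), m_max_rho0(s, phi) + 1e-9)
  }
  phiAB <- phi_thresholds(sel)$phi_AB
  expect_lt(abs(m_max_LE(sel, phiAB) - m_max_rho0(sel, phiAB)), 1e-9)
  # theta = 0 at phi = phi_AB: polymorphism for every migration rate
  s0 <- list(alpha1 = 0.1, alpha2 = -0.1, beta1 = 0.2, beta2 = -0.2)
  ph0 <- phi_thresholds(s0)
  expect_true(is.infinite(m_max_rho0(s0, ph0$phi_AB)))
})

test_that("the QLE collision-rate expansion behaves as derived", {
  sel <- ref_sel_strongB()
  # the correction vanishes as rho grows
  q1 <- m_max_qle(sel, 0.45, 1e8)
  expect_equal(q1$value, m_thresholds(sel, 0.45)$m_A, tolerance = 1e-6)
  expect_true(q1$positive)
  expect_false(m_max_qle(sel, 0.3, 100)$positive)
  # both signs of the O(1/rho) correction occur across parameters
  set.seed(20)
  sw <- generate_sweep(300, seed = 20)
  signs <- c()
  for (i in seq_len(nrow(sw))) {
    s <- as.list(sw[i, 1:4])
    phAB <- phi_thresholds(s)$phi_AB
    phB <- phi_thresholds(s)$phi_B
    phi <- phAB + 0.7 * (phB - phAB)
    signs <- c(signs, sign(m_max_qle(s, phi, 100)$correction))
  }
  expect_true(all(c(-1, 1) %in% signs))
})

test_that("the numerical maximum-rate search agrees with the closed forms", {
  sel <- ref_sel_strongB()
  r_le <- m_max_numeric(sel, 0.45, "LE")
  expect_equal(r_le$m_max, m_max_LE(sel, 0.45), tolerance = 1e-4)
  expect_equal(r_le$type, "boundary_exit")
  r_r0 <- m_max_numeric(sel, 0.2, 0)
  expect_equal(r_r0$m_max, m_max_rho0(sel, 0.2), tolerance = 1e-4)
  expect_equal(r_r0$type, "boundary_exit")
  # interior stability loss (the jump bifurcation) at intermediate phi
  r_r0b <- m_max_numeric(sel, 0.45, 0)
  expect_equal(r_r0b$m_max, m_max_rho0(sel, 0.45), tolerance = 1e-4)
  expect_equal(r_r0b$type, "stability_loss")
  # saddle-node detection in the bistable regime
  r_fold <- m_max_numeric(list(alpha1 = 1, alpha2 = -2,
                               beta1 = 1.2, beta2 = -1), 0.99, 1.2)
  expect_equal(r_fold$type, "fold")
  expect_gt(r_fold$m_max, 1.2)
  expect_lt(r_fold$m_max, 1.25)
})
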