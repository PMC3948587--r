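# Shared fixtures and oracles for the test suite. All fixtures are built in
# code; random draws go through generate_sweep() so they satisfy the model's
# canonical constraints by construction.

# Selection regime with locus B under stronger selection in both demes
# (theta = 1); used throughout as the first reference regime.
ref_sel_strongB <- function() list(alpha1 = 0.5, alpha2 = -1,
                                   beta1 = 2, beta2 = -2)

# Selection regime with different loci under stronger selection in the two
# demes (theta = 3.84, theta_tilde = 0).
ref_sel_crossed <- function() list(alpha1 = 0.4, alpha2 = -2,
                                   beta1 = 2, beta2 = -0.4)

ref_params <- function(sel = ref_sel_strongB(), m = 1, phi = 0.5, rho = 1,
                       ...) {
  model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                   m = m, phi = phi, rho = rho, canonicalize = FALSE, ...)
}

# Random valid (p, q, D) state: gamete frequencies drawn on the simplex.
random_state <- function() {
  x <- matrix(stats::rexp(8), 4, 2)
  x <- sweep(x, 2, colSums(x), "/")
  gametes_to_state(x)
}

# Closed-form state of a labelled equilibrium.
state_for_label <- function(label, par) {
  switch(label,
    M1 = , M2 = , M3 = , M4 = monomorphic_equilibria()[[label]]$state,
    PA1 = , PA2 = , PB1 = , PB2 = slp_equilibria(par)[[label]]$state,
    Finf = f_infinity(par)$state,
    F0 = f_zero(par)$state,
    stop("unknown label ", label))
}

# TRUE when phi is at least `dist` away from every bifurcation threshold
# phi^X relevant to the regime.
phi_away_from_thresholds <- function(sel, phi, regime, dist = 0.01) {
  ph <- phi_thresholds(sel, rho = 0)
  keys <- if (regime == "LE") c("phi_AB_tilde", "phi_A", "phi_AB", "phi_B")
          else c("phi_M1", "phi_A", "phi_AF0", "phi_F0", "phi_AB",
                 "phi_BF0", "phi_B", "phi_M4")
  all(abs(unlist(ph[keys]) - phi) > dist)
}

# Integrate the tri-gametic complete-linkage subsystem to equilibrium.
integrate_trig <- function(z0, par, horizon = 1e5) {
  fn <- function(t, z, p) list(migsel2:::trigametic_rhs(z, p))
  t_now <- 0; chunk <- 50; z <- z0
  repeat {
    sol <- suppressWarnings(deSolve::lsoda(z, c(0, chunk), fn, par,
                                           atol = 1e-12, rtol = 1e-10,
                                           maxsteps = 5e5))
    z <- pmin(pmax(sol[2, -1], 0), 1)
    t_now <- t_now + chunk; chunk <- chunk * 2
    if (max(abs(migsel2:::trigametic_rhs(z, par))) < 1e-9 || t_now > horizon)
      break
  }
  z
}

# Verify a predicted stable-equilibrium sequence by forward integration:
# for each m-interval of the diagram, integrate from random starts at n_m
# interior m-values and require convergence to the predicted equilibrium.
check_diagram_by_integration <- function(sel, phi, regime, n_m = 5,
                                         n_starts = 2, tol = 1e-4) {
  d <- if (regime == "LE") classify_LE(sel, phi) else classify_rho0(sel, phi)
  for (i in seq_len(nrow(d$intervals))) {
    lo <- d$intervals$m_lo[i]; hi <- d$intervals$m_hi[i]
    cap <- if (is.finite(hi)) hi else max(2 * lo, lo + 1)
    if (lo == 0) lo <- 1e-3 * cap
    mvals <- lo + (cap - lo) * seq(0.1, 0.9, length.out = n_m)
    for (m in mvals) {
      par <- model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                              m = m, phi = phi,
                              rho = if (regime == "LE") "LE" else 0,
                              canonicalize = FALSE)
      pred_full <- state_for_label(d$intervals$stable[i], par)
      for (j in seq_len(n_starts)) {
        if (regime == "LE") {
          y0 <- stats::runif(4, 0.05, 0.95)
          r <- integrate_dynamics(y0, par, horizon = 1e5, rhs_tol = 1e-9)
          if (max(abs(r$state - pred_full[1:4])) > tol)
            return(sprintf("phi=%g m=%g expected %s", phi, m,
                           d$intervals$stable[i]))
        } else {
          u <- stats::runif(3); u <- u / sum(u)
          v <- stats::runif(3); v <- v / sum(v)
          z <- integrate_trig(c(u[1], u[2], v[1], v[2]), par)
          pred <- migsel2:::state_to_trigametic(pred_full)
          if (max(abs(z - pred)) > tol)
            return(sprintf("phi=%g m=%g expected %s", phi, m,
                           d$intervals$stable[i]))
        }
      }
    }
  }
  TRUE
}
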