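# Dimensionless migration/selection ratios, the critical migration-ratio
# thresholds phi^X, the critical total migration rates m^X, and the maximum
# migration rates below which a stable two-locus polymorphism exists.

#' Migration/selection ratios
#'
#' `sigma_k = m_k / alpha_k`, `tau_k = m_k / beta_k`,
#' `kappa_k = m_k / (alpha_k + beta_k)`. These satisfy the harmonic identity
#' `1/kappa_k = 1/sigma_k + 1/tau_k`.
#'
#' @param params a `migsel_params` object.
#' @return list with `sigma1`, `sigma2`, `tau1`, `tau2`, `kappa1`, `kappa2`.
#' @export
compute_ratios <- function(params) {
  sel <- params$selection; mg <- params$migration
  list(sigma1 = mg$m1 / sel$alpha1, sigma2 = mg$m2 / sel$alpha2,
       tau1 = mg$m1 / sel$beta1, tau2 = mg$m2 / sel$beta2,
       kappa1 = mg$m1 / (sel$alpha1 + sel$beta1),
       kappa2 = mg$m2 / (sel$alpha2 + sel$beta2))
}

sel_of <- function(x) if (inherits(x, "migsel_params")) x$selection else x

#' Critical migration-ratio thresholds
#'
#' The eleven thresholds of the migration ratio `phi = m1/m` that organize
#' the bifurcation structure. `phi_A`, `phi_B` and `phi_F0` mark the ratios
#' at which the admissibility range of the locus-A polymorphism, the locus-B
#' polymorphism and the complete-linkage polymorphism F0 becomes unbounded;
#' `phi_AB` and `phi_AB_tilde` mark where `|m^A| = |m^B|`; `phi_M1`,
#' `phi_M1_tilde`, `phi_M4`, `phi_M4_tilde` (which depend on `rho`) and
#' `phi_AF0`, `phi_BF0` mark coincidences with the monomorphic stability
#' thresholds and with `m^F0`. For canonical parameters
#' `0 < phi_A < phi_AF0 < phi_AB < phi_BF0 < phi_B < 1`.
#'
#' @param selection a `migsel_params` object or its `selection` component.
#' @param rho recombination rate used for the `rho`-dependent thresholds
#'   (default 0).
#' @return named list of the eleven thresholds.
#' @export
phi_thresholds <- function(selection, rho = 0) {
  s <- sel_of(selection)
  a1 <- s$alpha1; a2 <- s$alpha2; b1 <- s$beta1; b2 <- s$beta2
  frac <- function(num, den2) num / (num - den2)
  list(
    phi_A = a1 / (a1 - a2),
    phi_B = b1 / (b1 - b2),
    phi_F0 = (a1 + b1) / (a1 + b1 - (a2 + b2)),
    phi_AB_tilde = frac(a1 * b1 * (a2 - b2), a2 * b2 * (a1 - b1)),
    phi_AB = frac(a1 * b1 * (a2 + b2), a2 * b2 * (a1 + b1)),
    phi_M1 = frac(a1 * (b2 + rho) * (a1 + b1 + rho),
                  a2 * (b1 + rho) * (a2 + b2 + rho)),
    phi_M1_tilde = frac(b1 * (a2 + rho) * (a1 + b1 + rho),
                        b2 * (a1 + rho) * (a2 + b2 + rho)),
    phi_M4 = frac(b1 * (a2 - rho) * (a1 + b1 - rho),
                  b2 * (a1 - rho) * (a2 + b2 - rho)),
    phi_M4_tilde = frac(a1 * (b2 - rho) * (a1 + b1 - rho),
                        a2 * (b1 - rho) * (a2 + b2 - rho)),
    phi_AF0 = frac(a1 * (a1 + b1) * (2 * a2 + b2),
                   a2 * (a2 + b2) * (2 * a1 + b1)),
    phi_BF0 = frac(b1 * (a1 + b1) * (a2 + 2 * b2),
                   b2 * (a2 + b2) * (a1 + 2 * b1))
  )
}

#' Critical total migration rates at a given migration ratio
#'
#' Signed critical rates `m^A`, `m^B`, `m^F0` (admissibility bounds of the
#' SLPs and of F0: e.g. the locus-A polymorphism is admissible iff
#' `-1 < m/m^A < 1`), `m^M1`, `m^M4` (monomorphic stability thresholds),
#' and `m^*` (stability bound of F0, `m1*m2 < m_tilde` iff `m < m^*`).
#' Following the model's conventions, `m^A`, `m^B`, `m^F0` are `Inf` exactly
#' at `phi = phi_A`, `phi_B`, `phi_F0`, and `m^* = Inf` when `theta = 0` or
#' `phi` is 0 or 1.
#'
#' @inheritParams phi_thresholds
#' @param phi migration ratio in `[0, 1]`.
#' @param rho recombination rate (used by `m^M1`, `m^M4`).
#' @return named list `m_A`, `m_B`, `m_F0`, `m_M1`, `m_M4`, `m_star`,
#'   `m_tilde`.
#' @export
m_thresholds <- function(selection, phi, rho = 0) {
  s <- sel_of(selection)
  a1 <- s$alpha1; a2 <- s$alpha2; b1 <- s$beta1; b2 <- s$beta2
  th <- a1 * b2 - a2 * b1
  ph <- phi_thresholds(s, rho)
  safe_div <- function(num, den, at_inf) {
    if (den == 0 || isTRUE(at_inf)) Inf else num / den
  }
  m_A <- safe_div(a1 * a2, a1 - phi * (a1 - a2), phi == ph$phi_A)
  m_B <- safe_div(b1 * b2, b1 - phi * (b1 - b2), phi == ph$phi_B)
  m_F0 <- safe_div((a1 + b1) * (a2 + b2),
                   a1 + b1 - phi * (a1 + b1 - a2 - b2), phi == ph$phi_F0)
  m_M1 <- safe_div(-(a1 + b1 + rho) * (a2 + b2 + rho),
                   a1 + b1 + rho - phi * (a1 + b1 - a2 - b2), FALSE)
  m_M4 <- safe_div((a1 + b1 - rho) * (a2 + b2 - rho),
                   a1 + b1 - rho - phi * (a1 + b1 - a2 - b2), FALSE)
  m_star <- if (th == 0 || phi <= 0 || phi >= 1) Inf else
    sqrt(-a1 * a2 * b1 * b2 * (a1 + b1) * (a2 + b2) / (phi * (1 - phi))) / th
  list(m_A = m_A, m_B = m_B, m_F0 = m_F0, m_M1 = m_M1, m_M4 = m_M4,
       m_star = m_star, m_tilde = m_tilde(s))
}

#' Full set of critical rates
#'
#' Convenience wrapper assembling the migration/selection ratios, the
#' `phi^X` thresholds and the `m^X` critical rates for one parameter set.
#'
#' @param params a `migsel_params` object.
#' @return an object of class `migsel_critical_rates` (a named list).
#' @export
critical_rates <- function(params) {
  out <- c(compute_ratios(params),
           phi_thresholds(params, rho = if (params$le) Inf else params$rho),
           m_thresholds(params, params$migration$phi,
                        rho = if (params$le) Inf else params$rho))
  structure(out, class = "migsel_critical_rates")
}

#' Maximum migration rate for polymorphism under linkage equilibrium
#'
#' `m_max_inf = min(|m^A|, |m^B|)`: under LE a stable fully polymorphic
#' equilibrium exists iff `m` is below this bound. As a function of `phi`
#' it is piecewise convex, maximized at `phi = phi_AB`, with a kink at
#' `phi = phi_AB_tilde` when `beta2 < alpha2`.
#'
#' @inheritParams m_thresholds
#' @return the maximum migration rate (possibly `Inf`).
#' @export
m_max_LE <- function(selection, phi) {
  mt <- m_thresholds(selection, phi, rho = 0)
  min(abs(mt$m_A), abs(mt$m_B))
}

#' Maximum migration rate for polymorphism with complete linkage
#'
#' `m_max_0 = min(|m^F0|, m^*)`: for `rho = 0` the polymorphism F0 persists
#' while it is admissible (`m < |m^F0|`) and stable (`m < m^*`). Always
#' `m_max_inf <= m_max_0`, with equality iff `phi = phi_AB`; when
#' `theta = 0` and `phi = phi_AB` the bound is infinite (polymorphism for
#' every migration rate).
#'
#' @inheritParams m_thresholds
#' @return the maximum migration rate (possibly `Inf`).
#' @export
m_max_rho0 <- function(selection, phi) {
  mt <- m_thresholds(selection, phi, rho = 0)
  min(abs(mt$m_F0), mt$m_star)
}

#' Quasi-linkage-equilibrium approximation of the maximum migration rate
#'
#' For strong recombination and `phi > phi_AB` the stable polymorphism
#' leaves the state space by colliding with the boundary equilibrium PB2 at
#' `m = m^A + O(1/rho)`; this returns the O(1/rho)-corrected collision rate.
#' The sign of the correction varies with the parameters, so the maximum
#' rate at large finite `rho` can exceed or fall below its LE value.
#'
#' @inheritParams m_thresholds
#' @param rho recombination rate (large).
#' @return list with `value` (the corrected rate), `positive` (whether
#'   `phi > phi_AB`, i.e. the collision rate is positive) and `correction`
#'   (the O(1/rho) term).
#' @export
m_max_qle <- function(selection, phi, rho) {
  s <- sel_of(selection)
  a1 <- s$alpha1; a2 <- s$alpha2; b1 <- s$beta1; b2 <- s$beta2
  mt <- m_thresholds(s, phi, rho = 0)
  mA <- mt$m_A
  ph <- phi_thresholds(s)
  corr <- -(mA^3 / rho) * ((b1 / a1) * phi - (b2 / a2) * (1 - phi)) *
    (phi / b1 - (1 - phi) / b2 - sqrt(mA^-2 - 4 * phi * (1 - phi) / (b1 * b2)))
  list(value = mA + corr, positive = phi > ph$phi_AB, correction = corr)
}

# Predicate helpers for the numerical m_max search ---------------------------

# Stable internal equilibrium of the LE dynamics at total rate m; returns the
# root (for continuation) or NULL.
stable_internal_LE <- function(sel, phi, m, seed) {
  par <- model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                          m = m, phi = phi, rho = "LE",
                          theta_zero_ok = TRUE, canonicalize = FALSE)
  f <- le_rhs(seed, par)
  y <- seed
  for (it in 1:50) {
    if (max(abs(f)) < 1e-13) break
    J <- le_jacobian(y, par)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    y <- y - step
    f <- tryCatch(le_rhs(pmin(pmax(y, -0.2), 1.2), par), error = function(e) NULL)
    if (is.null(f)) return(NULL)
  }
  if (max(abs(f)) > 1e-10) return(NULL)
  if (any(y < 1e-8 | y > 1 - 1e-8)) return(NULL)
  ev <- eigen(le_jacobian(y, par), only.values = TRUE)$values
  if (max(Re(ev)) >= 0) return(NULL)
  y
}

# Stable polymorphic equilibrium of the tri-gametic (rho = 0) dynamics.
stable_internal_rho0 <- function(sel, phi, m, seed) {
  par <- model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                          m = m, phi = phi, rho = 0,
                          theta_zero_ok = TRUE, canonicalize = FALSE)
  z <- seed
  f <- trigametic_rhs(z, par)
  for (it in 1:50) {
    if (max(abs(f)) < 1e-13) break
    J <- trigametic_jacobian(z, par)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    z <- z - step
    f <- trigametic_rhs(z, par)
  }
  if (max(abs(f)) > 1e-10) return(NULL)
  # both loci polymorphic: A1B1 and A2B2 interior, A2B1 (z[2], z[4]) ~ 0
  x1 <- z[c(1, 3)]; x4 <- 1 - z[c(1, 3)] - z[c(2, 4)]
  if (any(x1 < 1e-8) || any(x4 < 1e-8)) return(NULL)
  ev <- eigen(trigametic_jacobian(z, par), only.values = TRUE)$values
  if (max(Re(ev)) >= 0) return(NULL)
  z
}

# Stable internal equilibrium of the full finite-rho dynamics.
stable_internal_full <- function(sel, phi, m, rho, seed,
                                 integrate_fallback = TRUE) {
  par <- model_parameters(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                          m = m, phi = phi, rho = rho,
                          theta_zero_ok = TRUE, canonicalize = FALSE)
  try_root <- function(s0) {
    r <- newton_equilibrium(s0, par)
    if (!r$converged) return(NULL)
    x <- tryCatch(clip_state(r$state, tol = 1e-6), error = function(e) NULL)
    if (is.null(x)) return(NULL)
    g <- state_to_gametes(x, check = FALSE)
    if (any(g < 1e-8)) return(NULL)
    ev <- eigen(jacobian_allele_ld(r$state, par), only.values = TRUE)$values
    if (max(Re(ev)) >= 0) return(NULL)
    r$state
  }
  root <- try_root(seed)
  if (is.null(root) && integrate_fallback) {
    # integrate from the continuation seed (in the basin of the tracked
    # equilibrium for nearby m), then from the default interior start
    for (s0 in list(seed, default_start())) {
      s0 <- tryCatch(clip_state(s0, tol = Inf), error = function(e) NULL)
      if (is.null(s0)) next
      term <- integrate_dynamics(s0, par, horizon = 1e5, rhs_tol = 1e-9)
      root <- try_root(term$state)
      if (!is.null(root)) break
    }
  }
  root
}

#' Maximum migration rate for polymorphism, by continuation and bisection
#'
#' Tracks the stable fully polymorphic equilibrium as `m` grows and locates
#' (to relative tolerance `tol_rel`) the largest `m` at which it still
#' exists and is stable. The equilibrium may disappear by colliding with a
#' boundary equilibrium (exchange of stability) or in a saddle-node (fold);
#' the output distinguishes the two. For `rho = "LE"` or `rho = 0` the
#' search runs in the corresponding reduced system and agrees with the
#' closed-form bounds [m_max_LE()] / [m_max_rho0()].
#'
#' @param selection a `migsel_params` object or its `selection` component.
#' @param phi migration ratio in `(0, 1)`.
#' @param rho recombination rate, 0, positive, or `"LE"`.
#' @param m_cap upper bound for the search; if the polymorphism persists at
#'   `m_cap`, the function returns `Inf`.
#' @param tol_rel relative bisection tolerance (default 1e-6).
#' @return list with `m_max`, `type` (`"boundary_exit"`, `"fold"` or
#'   `"unbounded"`), and `n_evals`.
#' @export
m_max_numeric <- function(selection, phi, rho, m_cap = NULL, tol_rel = 1e-6) {
  s <- sel_of(selection)
  le <- identical(rho, "LE")
  mags <- abs(unlist(s[c("alpha1", "alpha2", "beta1", "beta2")]))
  if (is.null(m_cap)) {
    guess <- max(m_max_LE(s, phi),
                 if (!le && rho == 0) m_max_rho0(s, phi) else 0,
                 max(mags))
    m_cap <- if (is.finite(guess)) 4 * guess else 1e4 * max(mags)
  }
  m_lo <- 1e-3 * min(mags)
  n_evals <- 0L
  seed <- NULL
  probe <- function(m, sd) {
    n_evals <<- n_evals + 1L
    if (le) stable_internal_LE(s, phi, m, sd)
    else if (rho == 0) stable_internal_rho0(s, phi, m, sd)
    else stable_internal_full(s, phi, m, rho, sd)
  }
  seed0 <- if (le) {
    fi <- f_infinity(model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                                      m = m_lo, phi = phi, rho = "LE",
                                      theta_zero_ok = TRUE, canonicalize = FALSE))
    as.numeric(fi$state[1:4])
  } else if (rho == 0) {
    f0 <- f_zero(model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                                  m = m_lo, phi = phi, rho = 0,
                                  theta_zero_ok = TRUE, canonicalize = FALSE))
    state_to_trigametic(f0$state)
  } else {
    weak_migration_F(model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                                      m = m_lo, phi = phi, rho = rho,
                                      theta_zero_ok = TRUE, canonicalize = FALSE))$state
  }
  seed <- probe(m_lo, seed0)
  if (is.null(seed))
    stop("no stable polymorphic equilibrium at small m; parameters outside ",
         "the scope of the maximum-rate search")
  # outward continuation
  m_good <- m_lo; m_bad <- NA_real_
  m <- m_lo
  repeat {
    m_next <- min(m * 1.6, m_cap)
    r <- probe(m_next, seed)
    if (is.null(r)) { m_bad <- m_next; break }
    seed <- r; m_good <- m_next; m <- m_next
    if (m_next >= m_cap)
      return(list(m_max = Inf, type = "unbounded", n_evals = n_evals))
  }
  last_fail_root <- TRUE
  while ((m_bad - m_good) > tol_rel * m_bad) {
    mid <- 0.5 * (m_good + m_bad)
    r <- probe(mid, seed)
    if (is.null(r)) m_bad <- mid else { seed <- r; m_good <- mid }
  }
  # classify the terminating event from the last surviving equilibrium
  if (le) {
    type <- "boundary_exit"
  } else if (rho == 0) {
    x1 <- seed[c(1, 3)]; x4 <- 1 - seed[c(1, 3)] - seed[c(2, 4)]
    # interior stability loss at m* (the jump bifurcation) vs collision
    # with a monomorphic equilibrium
    type <- if (min(x1, x4) < 1e-3) "boundary_exit" else "stability_loss"
  } else {
    # a saddle-node is signalled by the coexistence of a second (unstable)
    # internal equilibrium just below m_max; at an exchange of stability
    # the tracked equilibrium has already merged into the boundary
    dist <- tryCatch(min(state_to_gametes(clip_state(seed, tol = 1e-4),
                                          check = FALSE)),
                     error = function(e) 0)
    if (dist < 1e-5) {
      type <- "boundary_exit"
    } else {
      par_g <- model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                                m = m_good, phi = phi, rho = rho,
                                theta_zero_ok = TRUE, canonicalize = FALSE)
      ints <- suppressWarnings(find_internal(par_g, n_starts = 40))
      type <- if (length(ints) >= 2) "fold" else "boundary_exit"
    }
  }
  list(m_max = 0.5 * (m_good + m_bad), type = type, n_evals = n_evals)
}
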