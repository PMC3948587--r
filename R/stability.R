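# Jacobians and stability classification: numerical eigenvalue analysis and
# the closed-form stability conditions for boundary equilibria.

#' Analytic Jacobian of the allele-frequency/LD dynamics
#'
#' The 6 x 6 matrix of partial derivatives of the `(p1,p2,q1,q2,D1,D2)`
#' system, evaluated analytically.
#'
#' @param state named state vector.
#' @param params a `migsel_params` object with finite `rho`.
#' @return 6 x 6 Jacobian matrix (rows/columns ordered as the state).
#' @export
jacobian_allele_ld <- function(state, params) {
  if (params$le) stop("use le_jacobian for the LE dynamics")
  s <- as_state(state)
  sel <- params$selection
  a <- c(sel$alpha1, sel$alpha2); b <- c(sel$beta1, sel$beta2)
  m <- c(params$migration$m1, params$migration$m2)
  rho <- params$rho
  J <- matrix(0, 6, 6, dimnames = list(state_names, state_names))
  for (k in 1:2) {
    o <- 3 - k
    p <- s[paste0("p", k)]; q <- s[paste0("q", k)]; D <- s[paste0("D", k)]
    po <- s[paste0("p", o)]; qo <- s[paste0("q", o)]
    ip <- k; ipo <- o; iq <- 2 + k; iqo <- 2 + o; iD <- 4 + k; iDo <- 4 + o
    J[ip, ip] <- a[k] * (1 - 2 * p) - m[k]
    J[ip, ipo] <- m[k]
    J[ip, iD] <- b[k]
    J[iq, iq] <- b[k] * (1 - 2 * q) - m[k]
    J[iq, iqo] <- m[k]
    J[iq, iD] <- a[k]
    J[iD, ip] <- -2 * a[k] * D - m[k] * (qo - q)
    J[iD, iq] <- -2 * b[k] * D - m[k] * (po - p)
    J[iD, iD] <- a[k] * (1 - 2 * p) + b[k] * (1 - 2 * q) - rho - m[k]
    J[iD, ipo] <- m[k] * (qo - q)
    J[iD, iqo] <- m[k] * (po - p)
    J[iD, iDo] <- m[k]
  }
  J
}

#' Jacobian of the linkage-equilibrium dynamics
#'
#' 4 x 4 Jacobian of the decoupled one-locus systems at `(p1, p2, q1, q2)`.
#'
#' @param freqs numeric vector `(p1, p2, q1, q2)`.
#' @param params a `migsel_params` object.
#' @return 4 x 4 block-diagonal Jacobian.
#' @export
le_jacobian <- function(freqs, params) {
  f <- as.numeric(freqs)
  sel <- params$selection
  m <- c(params$migration$m1, params$migration$m2)
  s <- c(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2)
  J <- matrix(0, 4, 4, dimnames = list(c("p1", "p2", "q1", "q2"),
                                       c("p1", "p2", "q1", "q2")))
  for (blk in 0:1) for (k in 1:2) {
    i <- 2 * blk + k; o <- 2 * blk + (3 - k)
    J[i, i] <- s[2 * blk + k] * (1 - 2 * f[i]) - m[k]
    J[i, o] <- m[k]
  }
  J
}

# Tri-gametic subsystem for rho = 0: gametes A1B1 (x1), A2B1 (x3), A2B2
# (x4 = 1 - x1 - x3) per deme, after discarding A1B2, which is always lost
# under complete linkage. Coordinates z = (x1_d1, x3_d1, x1_d2, x3_d2).
trigametic_rhs <- function(z, params) {
  sel <- params$selection
  m <- c(params$migration$m1, params$migration$m2)
  out <- numeric(4)
  for (k in 1:2) {
    a <- if (k == 1) sel$alpha1 else sel$alpha2
    b <- if (k == 1) sel$beta1 else sel$beta2
    v <- c(0.5 * (a + b), 0.5 * (b - a), -0.5 * (a + b))
    i1 <- 2 * k - 1; i3 <- 2 * k
    x1 <- z[i1]; x3 <- z[i3]; x4 <- 1 - x1 - x3
    vbar <- x1 * v[1] + x3 * v[2] + x4 * v[3]
    o1 <- 2 * (3 - k) - 1; o3 <- 2 * (3 - k)
    out[i1] <- x1 * (v[1] - vbar) + m[k] * (z[o1] - x1)
    out[i3] <- x3 * (v[2] - vbar) + m[k] * (z[o3] - x3)
  }
  out
}

trigametic_jacobian <- function(z, params) {
  sel <- params$selection
  m <- c(params$migration$m1, params$migration$m2)
  J <- matrix(0, 4, 4)
  for (k in 1:2) {
    a <- if (k == 1) sel$alpha1 else sel$alpha2
    b <- if (k == 1) sel$beta1 else sel$beta2
    v <- c(0.5 * (a + b), 0.5 * (b - a), -0.5 * (a + b))
    i1 <- 2 * k - 1; i3 <- 2 * k
    o1 <- 2 * (3 - k) - 1; o3 <- 2 * (3 - k)
    x1 <- z[i1]; x3 <- z[i3]; x4 <- 1 - x1 - x3
    vbar <- x1 * v[1] + x3 * v[2] + x4 * v[3]
    J[i1, i1] <- (v[1] - vbar) - x1 * (v[1] - v[3]) - m[k]
    J[i1, i3] <- -x1 * (v[2] - v[3])
    J[i1, o1] <- m[k]
    J[i3, i3] <- (v[2] - vbar) - x3 * (v[2] - v[3]) - m[k]
    J[i3, i1] <- -x3 * (v[1] - v[3])
    J[i3, o3] <- m[k]
  }
  J
}

# Map a (p,q,D) state with x2 = 0 into tri-gametic coordinates.
state_to_trigametic <- function(state) {
  x <- state_to_gametes(as_state(state), check = FALSE)
  if (max(abs(x[2, ])) > 1e-7)
    stop("state carries gamete A1B2; not in the tri-gametic subsystem")
  c(x[1, 1], x[3, 1], x[1, 2], x[3, 2])
}

stability_verdict <- function(eigvals, tol, method) {
  lead <- max(Re(eigvals))
  cls <- if (lead < -tol) "asymptotically_stable"
         else if (lead > tol) "unstable" else "marginal"
  list(classification = cls, leading_real_part = lead,
       method = method, eigenvalues = eigvals)
}

#' Classify the stability of an equilibrium by eigenvalue analysis
#'
#' Evaluates the Jacobian of the appropriate dynamical system at the
#' equilibrium and classifies it from the eigenvalue real parts. For
#' `subsystem = "full"` the 6 x 6 Jacobian of the allele/LD system is used;
#' `"le"` uses the 4 x 4 LE Jacobian; `"trigametic"` uses the 4 x 4
#' complete-linkage subsystem in which the always-lost gamete A1B2 is
#' discarded (the appropriate setting for `rho = 0` equilibria, which lie on
#' the boundary of the full state space).
#'
#' @param equilibrium an equilibrium record or a named state vector.
#' @param params a `migsel_params` object.
#' @param tol marginality tolerance on eigenvalue real parts (default 1e-8).
#' @param subsystem which dynamics to linearize.
#' @param max_residual equilibria whose dynamics residual exceeds this bound
#'   are rejected.
#' @return a stability verdict: `classification`
#'   (`asymptotically_stable` / `unstable` / `marginal`),
#'   `leading_real_part`, `method`, `eigenvalues`.
#' @export
classify_equilibrium <- function(equilibrium, params, tol = 1e-8,
                                 subsystem = c("full", "le", "trigametic"),
                                 max_residual = 1e-6) {
  subsystem <- match.arg(subsystem)
  st <- if (inherits(equilibrium, "migsel_equilibrium")) equilibrium$state
        else equilibrium
  if (subsystem == "le" || (params$le && subsystem == "full")) {
    f <- as.numeric(st)[1:4]
    if (max(abs(le_rhs(f, params))) > max_residual)
      stop("state is not an equilibrium of the LE dynamics")
    ev <- eigen(le_jacobian(f, params), only.values = TRUE)$values
    return(stability_verdict(ev, tol, "eigenvalue"))
  }
  if (subsystem == "trigametic") {
    z <- if (length(st) == 4L) as.numeric(st) else state_to_trigametic(st)
    if (max(abs(trigametic_rhs(z, params))) > max_residual)
      stop("state is not an equilibrium of the tri-gametic dynamics")
    ev <- eigen(trigametic_jacobian(z, params), only.values = TRUE)$values
    return(stability_verdict(ev, tol, "eigenvalue"))
  }
  s <- as_state(st)
  if (max(abs(allele_ld_rhs(s, params))) > max_residual)
    stop("state is not an equilibrium (residual too large)")
  ev <- eigen(jacobian_allele_ld(s, params), only.values = TRUE)$values
  stability_verdict(ev, tol, "eigenvalue")
}

# Build a verdict from slacks of strict stability conditions: all positive
# => stable, any decisively negative => unstable, boundary => marginal.
verdict_from_slacks <- function(slacks, tol) {
  mn <- min(slacks)
  cls <- if (mn > tol) "asymptotically_stable"
         else if (mn < -tol) "unstable" else "marginal"
  list(classification = cls, leading_real_part = NA_real_,
       method = "closed_form", eigenvalues = NULL, slack = mn)
}

#' Closed-form stability of the monomorphic equilibria
#'
#' At each monomorphic equilibrium the characteristic polynomial factors
#' into the two marginal one-locus quadratics and the quadratic of the
#' decoupled linkage-disequilibrium block. M1 is asymptotically stable iff
#' `sigma1 + sigma2 < -1`, `tau1 + tau2 < -1` and its LD block is stable
#' (automatic for `rho >= min(-alpha2, -beta2)`); M2 is always unstable;
#' M3 is stable iff `sigma1 + sigma2 > 1` and `tau1 + tau2 < -1`,
#' independently of `rho`; M4 is stable iff `sigma1 + sigma2 > 1`,
#' `tau1 + tau2 > 1` and its LD block is stable (automatic for
#' `rho >= alpha1`). Reversed inequalities give instability; equalities a
#' marginal verdict. At most one of M1, M3, M4 can be stable for any
#' parameter set.
#'
#' @param params a `migsel_params` object.
#' @param tol marginality tolerance on the condition slacks.
#' @return named list of verdicts for `M1`, `M2`, `M3`, `M4`.
#' @export
monomorphic_stability <- function(params, tol = 1e-10) {
  r <- compute_ratios(params)
  sel <- params$selection; mg <- params$migration
  a1 <- sel$alpha1; a2 <- sel$alpha2; b1 <- sel$beta1; b2 <- sel$beta2
  rho <- params$rho
  ss <- r$sigma1 + r$sigma2; tt <- r$tau1 + r$tau2
  # Transversal (LD-direction) conditions for M1 and M4: the characteristic
  # polynomial factors into the two marginal one-locus quadratics and the
  # quadratic of the decoupled 2 x 2 LD block; that block is stable iff its
  # determinant is positive and its trace negative. (At M1 the determinant
  # condition is equivalent to the familiar bound
  # m2 > -(alpha1+beta1+rho+m1)(alpha2+beta2+rho)/(alpha1+beta1+rho).)
  ld_block_slack <- function(d1, d2) {
    # diagonal entries d_k - m_k, off-diagonal m_k, m_{k*}
    det <- (d1 - mg$m1) * (d2 - mg$m2) - mg$m1 * mg$m2
    tr <- (d1 - mg$m1) + (d2 - mg$m2)
    min(det, -tr)
  }
  m1_trans <- if (params$le) 1
    else ld_block_slack(-(a1 + b1) - rho, -(a2 + b2) - rho)
  m4_trans <- if (params$le) 1
    else ld_block_slack((a1 + b1) - rho, (a2 + b2) - rho)
  list(
    M1 = verdict_from_slacks(c(-1 - ss, -1 - tt, m1_trans), tol),
    M2 = list(classification = "unstable", leading_real_part = NA_real_,
              method = "closed_form", eigenvalues = NULL, slack = -1),
    M3 = verdict_from_slacks(c(ss - 1, -1 - tt), tol),
    M4 = verdict_from_slacks(c(ss - 1, tt - 1, m4_trans), tol)
  )
}

#' Critical product of migration rates for complete linkage
#'
#' `m_tilde = -alpha1*alpha2*beta1*beta2*(alpha1+beta1)*(alpha2+beta2) /
#' theta^2`; the complete-linkage polymorphism F0 is stable iff
#' `m1 * m2 < m_tilde`. Infinite when `theta = 0`.
#'
#' @param selection selection component of a `migsel_params` object (or the
#'   object itself).
#' @return the threshold (possibly `Inf`).
#' @export
m_tilde <- function(selection) {
  s <- if (inherits(selection, "migsel_params")) selection$selection else selection
  th <- s$alpha1 * s$beta2 - s$alpha2 * s$beta1
  if (th == 0) return(Inf)
  -s$alpha1 * s$alpha2 * s$beta1 * s$beta2 *
    (s$alpha1 + s$beta1) * (s$alpha2 + s$beta2) / th^2
}

#' Closed-form stability of the complete-linkage polymorphism F0
#'
#' For `rho = 0`, F0 is asymptotically stable iff `m1 * m2 < m_tilde` and
#' unstable if the inequality is reversed; at equality there is a line of
#' equilibria and the verdict is marginal.
#'
#' @param params a `migsel_params` object (interpreted at `rho = 0`); F0
#'   must be admissible.
#' @inheritParams monomorphic_stability
#' @return a stability verdict with the threshold in `$m_tilde`.
#' @export
f_zero_stability <- function(params, tol = 1e-10) {
  f0 <- f_zero(params)
  if (!f0$admissible)
    stop("F0 is not admissible for these parameters")
  mt <- m_tilde(params)
  prod_m <- params$migration$m1 * params$migration$m2
  v <- verdict_from_slacks(mt - prod_m, tol)
  v$m_tilde <- mt
  v
}

#' Closed-form stability of the single-locus polymorphisms at rho = 0
#'
#' In the tri-gametic complete-linkage system only PA1 and PB2 can be
#' stable: PA1 iff `tau1 + tau2 < -1`, `|sigma1 + sigma2| < 1` and
#' `m1*m2 > m_tilde`; PB2 iff `sigma1 + sigma2 > 1`, `|tau1 + tau2| < 1`
#' and `m1*m2 > m_tilde`. At `m1*m2 = m_tilde` both have a zero eigenvalue.
#'
#' @inheritParams monomorphic_stability
#' @return named list of verdicts for `PA1` and `PB2`.
#' @export
slp_stability_rho0 <- function(params, tol = 1e-10) {
  r <- compute_ratios(params)
  mt <- m_tilde(params)
  prod_m <- params$migration$m1 * params$migration$m2
  ss <- r$sigma1 + r$sigma2; tt <- r$tau1 + r$tau2
  list(
    PA1 = verdict_from_slacks(c(-1 - tt, 1 - abs(ss), prod_m - mt), tol),
    PB2 = verdict_from_slacks(c(ss - 1, 1 - abs(tt), prod_m - mt), tol)
  )
}
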