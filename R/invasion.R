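# Invasion of a locally beneficial mutant at locus A linked to locus B in
# migration-selection balance.
#
# The studied regime: the resident population sits at the boundary
# equilibrium PB2 (locus B polymorphic, allele A2 fixed), and a mutant A1
# that is beneficial in deme 1 (alpha1 > 0 > alpha2) arises. Invasion is
# governed by the leading eigenvalue of the Jacobian transversal to the
# marginal one-locus system at PB2.

#' One-locus invasion condition
#'
#' For an isolated locus A, the mutant A1 invades and establishes a
#' protected polymorphism iff `m < |m^A|`, equivalently (in the regime
#' `phi > phi^A` of strong influx of the wild type into deme 1)
#' `phi^A < phi < phi_inv` with
#' `phi_inv = ((m - alpha2)/m) * phi^A`. `phi_inv > 1` iff `m < alpha1`:
#' a mutant with advantage exceeding the total migration rate invades for
#' every migration pattern (and at `phi = 1` the condition reduces to the
#' classical one-way-migration threshold `m < alpha1`).
#'
#' @param alpha1,alpha2 selection coefficients of A1 in demes 1 and 2
#'   (`alpha1 > 0 > alpha2`).
#' @param m total migration rate (> 0).
#' @param phi migration ratio; must satisfy `phi > phi^A` (the symmetric
#'   case is handled by relabelling demes).
#' @return list with `invades`, `phi_A`, `phi_inv`, `m_A` and
#'   `unconditional` (`TRUE` when `m < alpha1`).
#' @export
one_locus_invasion <- function(alpha1, alpha2, m, phi) {
  stopifnot(alpha1 > 0, alpha2 < 0, m > 0)
  phi_A <- alpha1 / (alpha1 - alpha2)
  if (phi <= phi_A)
    stop("phi <= phi^A: relabel demes/alleles to study invasion of the ",
         "allele under influx (the mirrored regime)")
  phi_inv <- ((m - alpha2) / m) * phi_A
  den <- alpha1 - phi * (alpha1 - alpha2)
  m_A <- if (den == 0) Inf else alpha1 * alpha2 / den
  list(invades = phi < phi_inv, phi_A = phi_A, phi_inv = phi_inv,
       m_A = m_A, unconditional = m < alpha1)
}

#' External stability of the boundary equilibrium PB2
#'
#' At PB2 (`p1 = p2 = 0`, `D1 = D2 = 0`, locus B at its polymorphic
#' frequencies) the `(p1, p2, D1, D2)` directions decouple from the marginal
#' `(q1, q2)` system, so the four transversal eigenvalues are those of the
#' corresponding 4 x 4 block of the analytic Jacobian (they are roots of a
#' quartic with no useful closed form). The mutant A1 invades iff the
#' leading transversal eigenvalue is positive.
#'
#' @param params a `migsel_params` object with finite `rho`; PB2 must be
#'   admissible (`|tau1 + tau2| < 1`).
#' @return list with `leading` (largest real part), `eigenvalues` (the four
#'   transversal eigenvalues), `invades`.
#' @export
external_stability_PB2 <- function(params) {
  if (params$le) stop("use the LE criterion (admissibility of Finf) for LE")
  r <- compute_ratios(params)
  if (abs(r$tau1 + r$tau2) >= 1)
    stop("PB2 is not admissible: the locus-B polymorphism is not protected")
  pb2 <- slp_equilibria(params)$PB2
  J <- jacobian_allele_ld(pb2$state, params)
  idx <- c(1, 2, 5, 6)                 # p1, p2, D1, D2
  ev <- eigen(J[idx, idx], only.values = TRUE)$values
  lead <- max(Re(ev))
  list(leading = lead, eigenvalues = ev, invades = lead > 0)
}

#' Maximum recombination rate permitting invasion
#'
#' Below `phi_inv` the mutant invades for every recombination rate
#' (`rho_max = Inf`). Above it, invasion requires sufficiently tight
#' linkage to the selected background locus B; the threshold is found by
#' bisection on the sign of the leading transversal eigenvalue at PB2.
#'
#' @param params a `migsel_params` object; its `rho` is ignored (the rate is
#'   the bisection variable).
#' @param rho_hi initial upper bracket (expanded as needed).
#' @param tol_rel relative bisection tolerance.
#' @return `Inf`, or the finite maximum recombination rate.
#' @export
rho_max_for_invasion <- function(params, rho_hi = NULL, tol_rel = 1e-8) {
  s <- params$selection; mg <- params$migration
  oli <- one_locus_invasion(s$alpha1, s$alpha2, mg$m, mg$phi)
  if (mg$phi <= oli$phi_inv) return(Inf)
  at_rho <- function(rho) {
    p <- model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                          m1 = mg$m1, m2 = mg$m2, rho = rho,
                          theta_zero_ok = TRUE, canonicalize = FALSE)
    external_stability_PB2(p)$leading
  }
  if (at_rho(0) <= 0) return(0)
  if (is.null(rho_hi))
    rho_hi <- 10 * max(abs(unlist(s[c("alpha1", "alpha2", "beta1", "beta2")])),
                       mg$m)
  while (at_rho(rho_hi) > 0) {
    rho_hi <- rho_hi * 4
    if (rho_hi > 1e12) return(Inf)
  }
  lo <- 0; hi <- rho_hi
  while ((hi - lo) > tol_rel * hi) {
    mid <- 0.5 * (lo + hi)
    if (at_rho(mid) > 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' Minimum selective advantage permitting invasion
#'
#' The smallest `alpha1` for which the mutant A1 invades at fixed `rho`,
#' `m`, `phi` and background parameters, found by bisection on the leading
#' transversal eigenvalue at PB2. Tighter linkage lowers the threshold
#' (`alpha_min -> 0` as `rho -> 0`: mutants of arbitrarily small effect can
#' invade if sufficiently tightly linked), and as `rho -> Inf` it
#' approaches the one-locus threshold `alpha2*m*phi / (alpha2 - m(1-phi))`.
#'
#' @param params a `migsel_params` object carrying `alpha2`, `beta1`,
#'   `beta2` and the migration rates; its `alpha1` is ignored.
#' @param rho recombination rate at which invasion is probed.
#' @param alpha_hi upper bracket for `alpha1` (default `beta1`).
#' @param tol_rel relative bisection tolerance.
#' @return the minimal `alpha1` (0 if even infinitesimal effects invade;
#'   `NA` if no `alpha1 <= alpha_hi` invades).
#' @export
alpha_min_for_invasion <- function(params, rho, alpha_hi = NULL,
                                   tol_rel = 1e-8) {
  s <- params$selection; mg <- params$migration
  if (is.null(alpha_hi)) alpha_hi <- s$beta1
  at_a1 <- function(a1) {
    p <- params_raw(a1, s$alpha2, s$beta1, s$beta2,
                    m1 = mg$m1, m2 = mg$m2, rho = rho)
    external_stability_PB2(p)$leading
  }
  eps <- 1e-10 * alpha_hi
  if (at_a1(eps) > 0) return(0)
  if (at_a1(alpha_hi) <= 0) return(NA_real_)
  lo <- eps; hi <- alpha_hi
  while ((hi - lo) > tol_rel * hi) {
    mid <- 0.5 * (lo + hi)
    if (at_a1(mid) > 0) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}
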