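# Three-locus extension A - N - B with a neutral middle locus, and the
# effective migration rate experienced by the neutral site.
#
# Internal representation: 8 gamete frequencies per deme (alleles at A, N, B
# in lexicographic order A1N1B1, A1N1B2, A1N2B1, ..., A2N2B2), with
# single-crossover recombination in the intervals A-N (rate rho_AN) and N-B
# (rate rho_NB), so that the total A-B rate is rho = rho_AN + rho_NB. The
# (frequency, disequilibrium) coordinates are
# y = (p1, p2, q1, q2, DAB1, DAB2, n1, n2, DAN1, DAN2, DNB1, DNB2,
#      DANB1, DANB2), selected block first.

gam8_alleles <- as.matrix(expand.grid(B = 1:2, N = 1:2, A = 1:2))[, 3:1]
# rows: (A,N,B) = (1,1,1), (1,1,2), (1,2,1), (1,2,2), (2,1,1), ...
gam8_eps <- 3 - 2 * gam8_alleles   # +1 for allele 1, -1 for allele 2

#' Construct the neutral-site geometry
#'
#' @param rho_AN,rho_NB recombination rates between the neutral locus and
#'   the selected loci A and B; both must be positive (the neutral site is
#'   not completely linked to either selected site).
#' @return list with `rho_AN`, `rho_NB` and the total rate `rho`.
#' @export
neutral_geometry <- function(rho_AN, rho_NB) {
  if (!(rho_AN > 0) || !(rho_NB > 0))
    stop("rho_AN and rho_NB must both be positive")
  list(rho_AN = rho_AN, rho_NB = rho_NB, rho = rho_AN + rho_NB)
}

# Marginal block frequencies used by the single-crossover recombination
# operator: splitting A | NB (interval A-N) and AN | B (interval N-B).
gamete8_rhs <- function(x, params, geometry) {
  sel <- params$selection
  m <- c(params$migration$m1, params$migration$m2)
  rAN <- geometry$rho_AN; rNB <- geometry$rho_NB
  A <- gam8_alleles[, 1]; N <- gam8_alleles[, 2]; B <- gam8_alleles[, 3]
  out <- x * (0 + 0i)
  for (k in 1:2) {
    a <- if (k == 1) sel$alpha1 else sel$alpha2
    b <- if (k == 1) sel$beta1 else sel$beta2
    v <- 0.5 * (gam8_eps[, 1] * a + gam8_eps[, 3] * b)
    xk <- x[, k]
    vbar <- sum(xk * v)
    # marginals
    pA <- c(sum(xk[A == 1]), sum(xk[A == 2]))
    pNB <- matrix(0 + 0i, 2, 2)
    pAN <- matrix(0 + 0i, 2, 2)
    pB <- c(sum(xk[B == 1]), sum(xk[B == 2]))
    for (i in 1:2) for (j in 1:2) {
      pNB[i, j] <- sum(xk[N == i & B == j])
      pAN[i, j] <- sum(xk[A == i & N == j])
    }
    rec <- rAN * (pA[A] * pNB[cbind(N, B)] - xk) +
           rNB * (pAN[cbind(A, N)] * pB[B] - xk)
    out[, k] <- xk * (v - vbar) + rec + m[k] * (x[, 3 - k] - xk)
  }
  if (all(Im(x) == 0)) Re(out) else out
}

# (frequency, LD) coordinates from 8-gamete frequencies, one deme.
gam8_to_coords <- function(xk) {
  A <- gam8_alleles[, 1]; N <- gam8_alleles[, 2]; B <- gam8_alleles[, 3]
  p <- sum(xk[A == 1]); n <- sum(xk[N == 1]); q <- sum(xk[B == 1])
  DAB <- sum(xk[A == 1 & B == 1]) - p * q
  DAN <- sum(xk[A == 1 & N == 1]) - p * n
  DNB <- sum(xk[N == 1 & B == 1]) - n * q
  DANB <- xk[1] - p * n * q - p * DNB - n * DAB - q * DAN
  c(p = p, n = n, q = q, DAB = DAB, DAN = DAN, DNB = DNB, DANB = DANB)
}

# Inverse map (Bennett decomposition for three diallelic loci), one deme.
coords_to_gam8 <- function(co) {
  p <- co[["p"]]; n <- co[["n"]]; q <- co[["q"]]
  PA <- c(p, 1 - p); PN <- c(n, 1 - n); PB <- c(q, 1 - q)
  A <- gam8_alleles[, 1]; N <- gam8_alleles[, 2]; B <- gam8_alleles[, 3]
  eA <- gam8_eps[, 1]; eN <- gam8_eps[, 2]; eB <- gam8_eps[, 3]
  PA[A] * PN[N] * PB[B] +
    PA[A] * eN * eB * co[["DNB"]] +
    PN[N] * eA * eB * co[["DAB"]] +
    PB[B] * eA * eN * co[["DAN"]] +
    eA * eN * eB * co[["DANB"]]
}

y_names <- c("p1", "p2", "q1", "q2", "DAB1", "DAB2",
             "n1", "n2", "DAN1", "DAN2", "DNB1", "DNB2", "DANB1", "DANB2")

#' Assemble a three-locus state
#'
#' Builds the 14-coordinate state of the A-N-B system from a two-locus
#' state and neutral-locus frequencies/disequilibria (which default to a
#' point on the neutral manifold: equal frequencies, no associations).
#'
#' @param state two-locus state `(p1,p2,q1,q2,D1,D2)`.
#' @param n1,n2 frequencies of the neutral variant N1 in each deme.
#' @param DAN,DNB,DANB per-deme disequilibria involving the neutral locus
#'   (length-2 vectors).
#' @return named 14-vector.
#' @export
neutral_state <- function(state, n1 = 0.5, n2 = n1,
                          DAN = c(0, 0), DNB = c(0, 0), DANB = c(0, 0)) {
  s <- as_state(state)
  stats::setNames(c(s[["p1"]], s[["p2"]], s[["q1"]], s[["q2"]],
                    s[["D1"]], s[["D2"]], n1, n2, DAN, DNB, DANB), y_names)
}

y_to_gam8 <- function(y) {
  x <- matrix(0, 8, 2)
  for (k in 1:2) {
    co <- c(p = y[[k]], n = y[[6 + k]], q = y[[2 + k]],
            DAB = y[[4 + k]], DAN = y[[8 + k]], DNB = y[[10 + k]],
            DANB = y[[12 + k]])
    x[, k] <- coords_to_gam8(co)
  }
  x
}

#' Dynamics of the three-locus system with a neutral middle locus
#'
#' Time derivatives of the 14 (frequency, disequilibrium) coordinates,
#' derived from the 8-gamete selection-recombination-migration dynamics
#' with no selection at N and at most one crossover per event. The selected
#' coordinates `(p, q, DAB)` evolve exactly as in the two-locus model (the
#' neutral locus is invisible to them), and any state with equal neutral
#' frequencies and vanishing neutral disequilibria is stationary in its
#' neutral coordinates.
#'
#' @param y named 14-vector (see [neutral_state()]).
#' @param params a `migsel_params` object whose `rho` equals
#'   `rho_AN + rho_NB`.
#' @param geometry a [neutral_geometry()] list.
#' @return named 14-vector of time derivatives.
#' @export
three_locus_rhs <- function(y, params, geometry) {
  if (is.null(geometry$rho_AN) || is.null(geometry$rho_NB))
    stop("geometry must provide rho_AN and rho_NB")
  x <- y_to_gam8(y)   # y may be complex (complex-step differentiation)
  xd <- gamete8_rhs(x, params, geometry)
  A <- gam8_alleles[, 1]; N <- gam8_alleles[, 2]; B <- gam8_alleles[, 3]
  out <- numeric(14)
  for (k in 1:2) {
    xk <- x[, k]; dk <- xd[, k]
    p <- sum(xk[A == 1]); n <- sum(xk[N == 1]); q <- sum(xk[B == 1])
    DAB <- sum(xk[A == 1 & B == 1]) - p * q
    DAN <- sum(xk[A == 1 & N == 1]) - p * n
    DNB <- sum(xk[N == 1 & B == 1]) - n * q
    dp <- sum(dk[A == 1]); dn <- sum(dk[N == 1]); dq <- sum(dk[B == 1])
    dDAB <- sum(dk[A == 1 & B == 1]) - dp * q - p * dq
    dDAN <- sum(dk[A == 1 & N == 1]) - dp * n - p * dn
    dDNB <- sum(dk[N == 1 & B == 1]) - dn * q - n * dq
    dDANB <- dk[1] - (dp * n * q + p * dn * q + p * n * dq) -
      (dp * DNB + p * dDNB) - (dn * DAB + n * dDAB) - (dq * DAN + q * dDAN)
    out[c(k, 2 + k, 4 + k, 6 + k, 8 + k, 10 + k, 12 + k)] <-
      c(dp, dq, dDAB, dn, dDAN, dDNB, dDANB)
  }
  stats::setNames(out, y_names)
}

#' Equilibrium frequency at the neutral locus
#'
#' With migration mixing the demes, the neutral frequencies converge in
#' both demes to the initial frequencies averaged over the demes:
#' `n_hat = (m2 * n1(0) + m1 * n2(0)) / m`.
#'
#' @param n1_0,n2_0 initial frequencies of N1 per deme.
#' @param m1,m2 migration rates; `m1 + m2` must be positive.
#' @return the common equilibrium frequency.
#' @export
neutral_equilibrium <- function(n1_0, n2_0, m1, m2) {
  m <- m1 + m2
  if (m <= 0)
    stop("m = 0: no mixing, the initial frequencies persist in each deme")
  (m2 * n1_0 + m1 * n2_0) / m
}

#' Weak-migration approximation of the effective migration rate
#'
#' To leading order in the migration rates, the rate at which neutral
#' differentiation decays is
#' \deqn{m_\mathrm{eff} = m_1\frac{\rho_{AN}\rho_{NB}}
#'   {(\rho_{AN}+\alpha_1)(\rho_{NB}+\beta_1)} +
#'   m_2\frac{\rho_{AN}\rho_{NB}}{(\rho_{AN}-\alpha_2)(\rho_{NB}-\beta_2)},}
#' the sum of the two effective one-way migration rates. With no selection
#' it reduces to `m`; a neutral site between two selected loci in
#' migration-selection balance experiences a far stronger barrier to gene
#' flow than one linked to a single selected locus.
#'
#' @param params a `migsel_params` object (only selection and migration are
#'   used).
#' @param geometry a [neutral_geometry()] list.
#' @return the approximate effective migration rate.
#' @export
m_eff_weak <- function(params, geometry) {
  s <- params$selection; mg <- params$migration
  rAN <- geometry$rho_AN; rNB <- geometry$rho_NB
  mg$m1 * rAN * rNB / ((rAN + s$alpha1) * (rNB + s$beta1)) +
    mg$m2 * rAN * rNB / ((rAN - s$alpha2) * (rNB - s$beta2))
}

# Complex-step Jacobian (machine-precision derivatives for the polynomial
# three-locus dynamics).
cs_jacobian <- function(f, x, h = 1e-20) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xc <- as.complex(x)
    xc[j] <- xc[j] + 1i * h
    J[, j] <- Im(f(xc)) / h
  }
  J
}

#' Effective migration rate at the neutral site, exact (numerical)
#'
#' At the stable fully polymorphic equilibrium F of the selected loci, the
#' Jacobian of the 14-coordinate system is block diagonal: a selected block
#' governing convergence to F and a neutral block `J_N` governing decay of
#' neutral differentiation. `J_N` has a structural zero eigenvalue along
#' the neutral manifold (identified by eigenvector alignment with the
#' manifold tangent, not by magnitude); the next eigenvalue `lambda_N`
#' gives the effective migration rate `m_eff = -lambda_N`.
#'
#' @param params a `migsel_params` object with `rho = rho_AN + rho_NB`.
#' @param geometry a [neutral_geometry()] list.
#' @param F_state optional two-locus equilibrium state; located numerically
#'   (and required to be stable) when omitted.
#' @param n_hat neutral frequency at which the Jacobian is evaluated
#'   (immaterial: the neutral block is independent of it).
#' @return list with `m_eff`, `lambda_N`, `approx` (the weak-migration
#'   value), `n_hat`, `offdiag_norm` (max |entry| of the coupling blocks)
#'   and `eigenvalues` (spectrum of `J_N`).
#' @export
m_eff_numeric <- function(params, geometry, F_state = NULL, n_hat = 0.5) {
  if (abs(params$rho - geometry$rho) > 1e-12 * max(1, geometry$rho))
    stop("params$rho must equal rho_AN + rho_NB")
  if (is.null(F_state)) {
    cand <- find_internal(params)
    stab <- NULL
    for (e in cand) {
      v <- classify_equilibrium(e, params)
      if (v$classification == "asymptotically_stable") { stab <- e$state; break }
    }
    if (is.null(stab)) {
      term <- integrate_dynamics(default_start(), params, horizon = 1e6,
                                 rhs_tol = 1e-11)
      r <- newton_equilibrium(term$state, params)
      if (r$converged) {
        g <- state_to_gametes(clip_state(r$state, 1e-6), check = FALSE)
        v <- classify_equilibrium(r$state, params)
        if (all(g > 1e-8) && v$classification == "asymptotically_stable")
          stab <- r$state
      }
    }
    if (is.null(stab))
      stop("no stable fully polymorphic equilibrium found; the effective ",
           "migration rate at F is undefined for these parameters")
    F_state <- stab
  }
  y0 <- neutral_state(F_state, n1 = n_hat)
  J <- cs_jacobian(function(y) three_locus_rhs(y, params, geometry),
                   as.numeric(y0))
  selected <- 1:6; neutral <- 7:14
  offdiag <- max(abs(J[selected, neutral]), abs(J[neutral, selected]))
  JN <- J[neutral, neutral]
  eg <- eigen(JN)
  tangent <- c(1, 1, rep(0, 6)) / sqrt(2)
  align <- apply(eg$vectors, 2, function(v) abs(sum(Conj(v) * tangent)) /
                   sqrt(sum(Mod(v)^2)))
  zero_idx <- which.max(align)
  rest <- Re(eg$values[-zero_idx])
  lambda_N <- max(rest)
  list(m_eff = -lambda_N, lambda_N = lambda_N,
       approx = m_eff_weak(params, geometry), n_hat = n_hat,
       offdiag_norm = offdiag, eigenvalues = eg$values)
}
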