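# Right-hand sides of the two-locus two-deme dynamics, state representations
# and the numerical integrator.
#
# Two equivalent state representations are used: per-deme gamete frequencies
# (x1, x2, x3, x4) of A1B1, A1B2, A2B1, A2B2 on the simplex, and per-deme
# allele frequencies with linkage disequilibrium (p, q, D), where
# x1 = pq + D, x2 = p(1-q) - D, x3 = (1-p)q - D, x4 = (1-p)(1-q) + D and
# D = x1*x4 - x2*x3.

state_names <- c("p1", "p2", "q1", "q2", "D1", "D2")

as_state <- function(state) {
  s <- as.numeric(state)
  if (length(s) != 6L) stop("state must have 6 coordinates (p1,p2,q1,q2,D1,D2)")
  names(s) <- state_names
  s
}

#' Validate a (p, q, D) state
#'
#' Checks `0 <= p, q <= 1` and the box constraint
#' `-min(pq, (1-p)(1-q)) <= D <= min(p(1-q), (1-p)q)` in both demes.
#'
#' @param state named state vector `(p1, p2, q1, q2, D1, D2)`.
#' @param tol tolerance for constraint violation.
#' @return `TRUE` invisibly; errors if the state is invalid.
#' @export
validate_state <- function(state, tol = 1e-9) {
  s <- as_state(state)
  for (k in 1:2) {
    p <- s[paste0("p", k)]; q <- s[paste0("q", k)]; D <- s[paste0("D", k)]
    if (p < -tol || p > 1 + tol || q < -tol || q > 1 + tol)
      stop("allele frequency outside [0, 1] in deme ", k)
    lo <- -min(p * q, (1 - p) * (1 - q))
    hi <- min(p * (1 - q), (1 - p) * q)
    if (D < lo - tol || D > hi + tol)
      stop("linkage disequilibrium outside its admissible box in deme ", k)
  }
  invisible(TRUE)
}

#' Convert between gamete frequencies and (p, q, D) coordinates
#'
#' @param state for `state_to_gametes`, a named `(p1,p2,q1,q2,D1,D2)` vector.
#' @param x for `gametes_to_state`, a 4 x 2 matrix of gamete frequencies
#'   (rows: A1B1, A1B2, A2B1, A2B2; columns: demes).
#' @param check validate the input representation.
#' @return `state_to_gametes` returns the 4 x 2 gamete-frequency matrix;
#'   `gametes_to_state` returns the named state vector. The two maps are a
#'   bijection on the constrained set and invert each other to machine
#'   precision.
#' @export
state_to_gametes <- function(state, check = TRUE) {
  s <- as_state(state)
  if (check) validate_state(s)
  x <- matrix(0, 4, 2, dimnames = list(c("x1", "x2", "x3", "x4"), c("deme1", "deme2")))
  for (k in 1:2) {
    p <- s[paste0("p", k)]; q <- s[paste0("q", k)]; D <- s[paste0("D", k)]
    x[, k] <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D,
                (1 - p) * (1 - q) + D)
  }
  x
}

#' @rdname state_to_gametes
#' @export
gametes_to_state <- function(x, check = TRUE) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(4, 2))) stop("gamete frequencies must form a 4 x 2 matrix")
  if (check) {
    if (any(x < -1e-9)) stop("negative gamete frequency")
    if (any(abs(colSums(x) - 1) > 1e-8)) stop("gamete frequencies must sum to 1 per deme")
  }
  s <- c(p1 = x[1, 1] + x[2, 1], p2 = x[1, 2] + x[2, 2],
         q1 = x[1, 1] + x[3, 1], q2 = x[1, 2] + x[3, 2],
         D1 = x[1, 1] * x[4, 1] - x[2, 1] * x[3, 1],
         D2 = x[1, 2] * x[4, 2] - x[2, 2] * x[3, 2])
  s
}

#' Gamete-frequency dynamics
#'
#' Time derivatives of the per-deme gamete frequencies:
#' `xdot_ik = x_ik (w_ik - wbar_k) - eta_i rho D_k + m_k (x_ik* - x_ik)`,
#' with `eta = (1, -1, -1, 1)` and `D_k = x1 x4 - x2 x3`. Under
#' `fitness = "diploid"`, marginal fitnesses are computed from the additive
#' genotype fitness matrix (no dominance, no epistasis); under
#' `fitness = "haploid"` each gamete carries the constant fitness
#' `(±alpha_k ± beta_k)/2` (allelic contributions `±alpha_k/2`, `±beta_k/2`).
#' Both assignments produce identical dynamics, since without dominance the
#' diploid marginal-fitness deviations reduce to the haploid ones.
#'
#' @param x 4 x 2 gamete-frequency matrix.
#' @param params a `migsel_params` object with finite `rho`.
#' @param fitness fitness bookkeeping, `"diploid"` or `"haploid"`.
#' @param check validate the state (simplex within tolerance).
#' @return 4 x 2 matrix of time derivatives; columns sum to zero.
#' @export
gamete_rhs <- function(x, params, fitness = c("diploid", "haploid"),
                       check = TRUE) {
  fitness <- match.arg(fitness)
  if (params$le) stop("gamete dynamics require finite rho; use le_rhs for LE")
  x <- as.matrix(x)
  if (check) {
    if (any(x < -1e-8) || any(abs(colSums(x) - 1) > 1e-8))
      stop("state outside the simplex")
  }
  sel <- params$selection
  eta <- c(1, -1, -1, 1)
  out <- x * 0
  mrate <- c(params$migration$m1, params$migration$m2)
  for (k in 1:2) {
    a <- if (k == 1) sel$alpha1 else sel$alpha2
    b <- if (k == 1) sel$beta1 else sel$beta2
    v <- 0.5 * c(a + b, a - b, -a + b, -a - b)
    xk <- x[, k]
    if (fitness == "diploid") {
      W <- outer(v, v, "+")      # additive genotype fitnesses
      w <- as.numeric(W %*% xk)  # marginal fitness of each gamete
      wbar <- sum(xk * w)
    } else {
      w <- v
      wbar <- sum(xk * v)
    }
    Dk <- xk[1] * xk[4] - xk[2] * xk[3]
    out[, k] <- xk * (w - wbar) - eta * params$rho * Dk +
      mrate[k] * (x[, 3 - k] - xk)
  }
  out
}

#' Allele-frequency / linkage-disequilibrium dynamics
#'
#' The coupled ODE system for `(p_k, q_k, D_k)` in demes `k = 1, 2`:
#' \deqn{\dot p_k = \alpha_k p_k(1-p_k) + \beta_k D_k + m_k(p_{k^*}-p_k)}
#' \deqn{\dot q_k = \beta_k q_k(1-q_k) + \alpha_k D_k + m_k(q_{k^*}-q_k)}
#' \deqn{\dot D_k = [\alpha_k(1-2p_k)+\beta_k(1-2q_k)-\rho] D_k +
#'       m_k[(D_{k^*}-D_k)+(p_{k^*}-p_k)(q_{k^*}-q_k)]}
#'
#' @param state named state vector `(p1, p2, q1, q2, D1, D2)`.
#' @param params a `migsel_params` object with finite `rho`.
#' @param check validate the state.
#' @return named vector of time derivatives.
#' @export
allele_ld_rhs <- function(state, params, check = FALSE) {
  if (params$le) stop("use le_rhs for the linkage-equilibrium dynamics")
  s <- as_state(state)
  if (check) validate_state(s)
  sel <- params$selection
  a <- c(sel$alpha1, sel$alpha2); b <- c(sel$beta1, sel$beta2)
  m <- c(params$migration$m1, params$migration$m2)
  p <- s[c("p1", "p2")]; q <- s[c("q1", "q2")]; D <- s[c("D1", "D2")]
  po <- p[2:1]; qo <- q[2:1]; Do <- D[2:1]
  dp <- a * p * (1 - p) + b * D + m * (po - p)
  dq <- b * q * (1 - q) + a * D + m * (qo - q)
  dD <- (a * (1 - 2 * p) + b * (1 - 2 * q) - params$rho) * D +
    m * ((Do - D) + (po - p) * (qo - q))
  c(p1 = dp[[1]], p2 = dp[[2]], q1 = dq[[1]], q2 = dq[[2]],
    D1 = dD[[1]], D2 = dD[[2]])
}

#' Linkage-equilibrium dynamics
#'
#' The strong-recombination limit, in which the loci decouple into two
#' independent one-locus two-deme systems:
#' `pdot_k = alpha_k p_k (1 - p_k) + m_k (p_k* - p_k)` and analogously for
#' `q` with `beta`.
#'
#' @param freqs numeric vector `(p1, p2, q1, q2)` in `[0, 1]^4`.
#' @param params a `migsel_params` object.
#' @return named 4-vector of time derivatives.
#' @export
le_rhs <- function(freqs, params) {
  f <- as.numeric(freqs)
  if (length(f) != 4L) stop("freqs must be (p1, p2, q1, q2)")
  if (any(f < -1e-6 | f > 1 + 1e-6)) stop("allele frequency outside [0, 1]")
  sel <- params$selection
  m <- c(params$migration$m1, params$migration$m2)
  p <- f[1:2]; q <- f[3:4]
  dp <- c(sel$alpha1, sel$alpha2) * p * (1 - p) + m * (p[2:1] - p)
  dq <- c(sel$beta1, sel$beta2) * q * (1 - q) + m * (q[2:1] - q)
  c(p1 = dp[1], p2 = dp[2], q1 = dq[1], q2 = dq[2])
}

# Clip a state onto the constraint set; violations above `tol` abort, since
# silent clipping can mask solver failure.
clip_state <- function(s, tol = 1e-9) {
  s <- as_state(s)
  viol <- max(0, -s[c("p1", "p2", "q1", "q2")], s[c("p1", "p2", "q1", "q2")] - 1)
  for (k in 1:2) {
    p <- min(max(s[paste0("p", k)], 0), 1)
    q <- min(max(s[paste0("q", k)], 0), 1)
    D <- s[paste0("D", k)]
    lo <- -min(p * q, (1 - p) * (1 - q)); hi <- min(p * (1 - q), (1 - p) * q)
    viol <- max(viol, lo - D, D - hi)
    s[paste0("p", k)] <- p; s[paste0("q", k)] <- q
    s[paste0("D", k)] <- min(max(D, lo), hi)
  }
  if (viol > tol)
    stop(sprintf("state constraint violated by %.3g (> %.3g); integration aborted",
                 viol, tol))
  s
}

#' Integrate the model dynamics to (or towards) equilibrium
#'
#' Solves the allele-frequency/LD system (or the linkage-equilibrium system
#' when `params$le` is `TRUE`) with an adaptive stiff-capable solver
#' ([deSolve::lsoda]). Integration proceeds in doubling time chunks until the
#' sup-norm of the right-hand side falls below `rhs_tol` (convergence) or the
#' horizon is exhausted.
#'
#' @param state0 initial state: `(p1,p2,q1,q2,D1,D2)`, or `(p1,p2,q1,q2)` in
#'   LE mode.
#' @param params a `migsel_params` object.
#' @param horizon maximum integration time (default `1e6` time units).
#' @param rhs_tol convergence threshold on the rhs sup-norm (default `1e-10`).
#' @param atol,rtol solver tolerances.
#' @param keep_trajectory return the full time course as a data frame.
#' @return a list with `state` (terminal state), `converged` (logical),
#'   `time` (final time reached), and optionally `trajectory`.
#' @export
integrate_dynamics <- function(state0, params, horizon = 1e6,
                               rhs_tol = 1e-10, atol = 1e-12, rtol = 1e-10,
                               keep_trajectory = FALSE) {
  le <- params$le
  if (le) {
    y <- as.numeric(state0)
    if (length(y) == 6L) y <- y[1:4]
    names(y) <- c("p1", "p2", "q1", "q2")
    fn <- function(t, y, p) list(le_rhs(y, p))
    clip <- function(s) pmin(pmax(s, 0), 1)
    rhs_now <- function(y) le_rhs(y, params)
  } else {
    y <- as_state(state0)
    validate_state(y)
    fn <- function(t, y, p) list(allele_ld_rhs(y, p))
    clip <- function(s) clip_state(s)
    rhs_now <- function(y) allele_ld_rhs(y, params)
  }
  traj <- NULL
  t_now <- 0
  # chunk length scaled to the slowest rate in the system
  rates <- abs(unlist(params$selection[c("alpha1", "alpha2", "beta1", "beta2")]))
  rates <- c(rates, params$migration$m1, params$migration$m2)
  rates <- rates[rates > 0]
  chunk <- if (length(rates)) 10 / min(rates) else 10
  # cap the chunk length so a single solver call stays within its step
  # budget even when the fastest rate dictates small steps
  chunk_cap <- if (length(rates)) max(5e4 / max(rates), chunk) else Inf
  chunk <- min(chunk, horizon)
  converged <- max(abs(rhs_now(y))) < rhs_tol
  while (!converged && t_now < horizon) {
    dt <- min(chunk, horizon - t_now)
    times <- seq(0, dt, length.out = if (keep_trajectory) 21 else 2)
    sol <- suppressWarnings(
      deSolve::lsoda(y, times, fn, params, atol = atol, rtol = rtol,
                     maxsteps = 500000))
    if (keep_trajectory) {
      block <- as.data.frame(sol)
      block$time <- block$time + t_now
      traj <- rbind(traj, block)
    }
    y <- clip(sol[nrow(sol), -1])
    if (!le) names(y) <- state_names else names(y) <- c("p1", "p2", "q1", "q2")
    t_now <- t_now + dt
    chunk <- min(chunk * 2, chunk_cap)
    converged <- max(abs(rhs_now(y))) < rhs_tol
  }
  out <- list(state = y, converged = converged, time = t_now)
  if (keep_trajectory) out$trajectory <- traj
  out
}

#' Default interior starting state
#'
#' Both demes near (1/2, 1/2) with a small perturbation towards the deme's
#' locally favoured haplotype and no initial LD.
#'
#' @param eps perturbation size.
#' @return a named state vector.
#' @export
default_start <- function(eps = 0.01) {
  c(p1 = 0.5 + eps, p2 = 0.5 - eps, q1 = 0.5 + eps, q2 = 0.5 - eps,
    D1 = 0, D2 = 0)
}
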