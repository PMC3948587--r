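# Closed-form equilibria, perturbation approximations and a numerical
# internal-equilibrium finder.
#
# Equilibrium labels: M1..M4 (monomorphic, one gamete fixed), PA1/PA2/PB1/PB2
# (single-locus polymorphisms; e.g. PA1 = locus A polymorphic, B1 fixed),
# Finf (fully polymorphic equilibrium of the linkage-equilibrium dynamics),
# F0 (fully polymorphic equilibrium with complete linkage, only the locally
# adapted gametes A1B1 and A2B2 present), F (the stable fully polymorphic
# equilibrium at finite rho, located numerically).

equilibrium_record <- function(label, state, admissible, source,
                               extra = NULL) {
  structure(c(list(label = label, state = as_state(state),
                   admissible = admissible, source = source,
                   stability = NULL), extra),
            class = "migsel_equilibrium")
}

#' @export
print.migsel_equilibrium <- function(x, ...) {
  cat(sprintf("<%s> (%s)%s\n", x$label, x$source,
              if (isTRUE(x$admissible)) "" else "  [not admissible]"))
  print(round(x$state, 8))
  if (!is.null(x$stability))
    cat(sprintf("  stability: %s (leading Re = %.3g)\n",
                x$stability$classification, x$stability$leading_real_part))
  invisible(x)
}

#' Monomorphic equilibria
#'
#' The four fixation states M1 (A1B1), M2 (A1B2), M3 (A2B1), M4 (A2B2); all
#' exist for every parameter set.
#'
#' @return list of four equilibrium records.
#' @export
monomorphic_equilibria <- function() {
  pq <- list(M1 = c(1, 1), M2 = c(1, 0), M3 = c(0, 1), M4 = c(0, 0))
  lapply(names(pq), function(lab) {
    v <- pq[[lab]]
    equilibrium_record(lab, c(v[1], v[1], v[2], v[2], 0, 0),
                       admissible = TRUE, source = "closed_form")
  }) |> stats::setNames(names(pq))
}

# One-locus two-deme polymorphic frequencies given ratios r1 = m1/s1,
# r2 = m2/s2 (protected polymorphism iff |r1 + r2| < 1).
one_locus_poly <- function(r1, r2) {
  disc <- 1 - 4 * r1 * r2
  root <- sqrt(max(disc, 0))
  c(0.5 * (1 - 2 * r1 + root), 0.5 * (1 - 2 * r2 - root))
}

#' Single-locus polymorphisms
#'
#' Closed-form coordinates and admissibility of the four boundary equilibria
#' at which one locus is polymorphic and the other fixed. The locus-A
#' frequencies are roots of the marginal one-locus dynamics with ratios
#' `sigma_k = m_k / alpha_k`; admissibility (= protected polymorphism at the
#' polymorphic locus) requires `|sigma1 + sigma2| < 1` for the A
#' polymorphisms and `|tau1 + tau2| < 1` (with `tau_k = m_k / beta_k`) for
#' the B polymorphisms. Inadmissible records are returned flagged, not
#' omitted, together with the monomorphic equilibrium through which each SLP
#' leaves the state space as migration increases.
#'
#' @param params a `migsel_params` object.
#' @return named list of four equilibrium records (`PA1`, `PA2`, `PB1`,
#'   `PB2`), each with an `exit_target` field.
#' @export
slp_equilibria <- function(params) {
  r <- compute_ratios(params)
  pA <- one_locus_poly(r$sigma1, r$sigma2)
  qB <- one_locus_poly(r$tau1, r$tau2)
  admA <- abs(r$sigma1 + r$sigma2) < 1
  admB <- abs(r$tau1 + r$tau2) < 1
  exitA <- if (r$sigma1 + r$sigma2 >= 0) c(PA1 = "M3", PA2 = "M4")
           else c(PA1 = "M1", PA2 = "M2")
  exitB <- if (r$tau1 + r$tau2 >= 0) c(PB1 = "M2", PB2 = "M4")
           else c(PB1 = "M1", PB2 = "M3")
  list(
    PA1 = equilibrium_record("PA1", c(pA[1], pA[2], 1, 1, 0, 0), admA,
                             "closed_form", list(exit_target = exitA[["PA1"]])),
    PA2 = equilibrium_record("PA2", c(pA[1], pA[2], 0, 0, 0, 0), admA,
                             "closed_form", list(exit_target = exitA[["PA2"]])),
    PB1 = equilibrium_record("PB1", c(1, 1, qB[1], qB[2], 0, 0), admB,
                             "closed_form", list(exit_target = exitB[["PB1"]])),
    PB2 = equilibrium_record("PB2", c(0, 0, qB[1], qB[2], 0, 0), admB,
                             "closed_form", list(exit_target = exitB[["PB2"]]))
  )
}

#' Fully polymorphic equilibrium under linkage equilibrium
#'
#' Under the LE dynamics the full system is the Cartesian product of the two
#' one-locus systems, so the only possible internal equilibrium combines the
#' locus-A and locus-B single-locus polymorphic frequencies. It is admissible
#' if and only if all four SLPs are admissible, and globally asymptotically
#' stable whenever admissible.
#'
#' @param params a `migsel_params` object.
#' @return an equilibrium record labelled `Finf` (with `D1 = D2 = 0`).
#' @export
f_infinity <- function(params) {
  r <- compute_ratios(params)
  pA <- one_locus_poly(r$sigma1, r$sigma2)
  qB <- one_locus_poly(r$tau1, r$tau2)
  adm <- abs(r$sigma1 + r$sigma2) < 1 && abs(r$tau1 + r$tau2) < 1
  equilibrium_record("Finf", c(pA[1], pA[2], qB[1], qB[2], 0, 0), adm,
                     "closed_form")
}

#' Fully polymorphic equilibrium with complete linkage
#'
#' For `rho = 0` the gametes behave as four alleles of one locus, and a
#' polymorphic equilibrium at which only the locally adapted gametes A1B1 and
#' A2B2 segregate exists iff `|kappa1 + kappa2| < 1`, where
#' `kappa_k = m_k / (alpha_k + beta_k)`. Its coordinates satisfy
#' `p_k = q_k` and `D_k = p_k (1 - p_k)` (maximal positive LD).
#'
#' @param params a `migsel_params` object (its `rho` should be 0; the record
#'   is an equilibrium of the dynamics only in that case).
#' @return an equilibrium record labelled `F0`.
#' @export
f_zero <- function(params) {
  r <- compute_ratios(params)
  pp <- one_locus_poly(r$kappa1, r$kappa2)
  adm <- abs(r$kappa1 + r$kappa2) < 1
  equilibrium_record("F0", c(pp[1], pp[2], pp[1], pp[2],
                             pp[1] * (1 - pp[1]), pp[2] * (1 - pp[2])),
                     adm, "closed_form")
}

#' Unstable complete-linkage equilibrium on the M2--M3 edge
#'
#' With `rho = 0` a second two-gamete polymorphic equilibrium exists on the
#' edge spanned by the intermediate gametes A1B2 and A2B1. It is unstable for
#' every parameter choice and leaves the state space under any positive
#' recombination; it is computed for completeness but excluded from
#' bifurcation diagrams.
#'
#' @param params a `migsel_params` object.
#' @return an equilibrium record labelled `E23` (`y` = frequency of A1B2).
#' @export
edge_fp_rho0 <- function(params) {
  sel <- params$selection
  lam1 <- params$migration$m1 / (sel$alpha1 - sel$beta1)
  lam2 <- params$migration$m2 / (sel$alpha2 - sel$beta2)
  y <- one_locus_poly(lam1, lam2)   # frequency of A1B2 per deme
  adm <- abs(lam1 + lam2) < 1
  # state: x2 = y, x3 = 1 - y  =>  p = y, q = 1 - y, D = -y(1-y)
  equilibrium_record("E23", c(y[1], y[2], 1 - y[1], 1 - y[2],
                              -y[1] * (1 - y[1]), -y[2] * (1 - y[2])),
                     adm, "closed_form")
}

#' Weak-migration approximation of the fully polymorphic equilibrium
#'
#' Leading-order coordinates in `m1`, `m2` of the perturbation of the
#' no-migration equilibrium (deme 1 fixed for A1B1, deme 2 for A2B2):
#' \deqn{\hat p_1 = 1 - \frac{m_1}{\alpha_1}\frac{\alpha_1+\rho}{\alpha_1+\beta_1+\rho},\quad
#'   \hat D_1 = \frac{m_1}{\alpha_1+\beta_1+\rho}}
#' and symmetrically for deme 2 with `D2 = m2/(rho - alpha2 - beta2)`. Both
#' LD values are positive: weak migration always generates an excess of the
#' locally adapted haplotypes. The approximation error is O(m^2).
#'
#' @param params a `migsel_params` object with finite `rho`.
#' @return an equilibrium record labelled `F` with source
#'   `"weak_migration_approx"`.
#' @export
weak_migration_F <- function(params) {
  if (params$le) stop("weak-migration approximation requires finite rho")
  sel <- params$selection; mg <- params$migration
  a1 <- sel$alpha1; a2 <- sel$alpha2; b1 <- sel$beta1; b2 <- sel$beta2
  rho <- params$rho
  p1 <- 1 - (mg$m1 / a1) * (a1 + rho) / (a1 + b1 + rho)
  q1 <- 1 - (mg$m1 / b1) * (b1 + rho) / (a1 + b1 + rho)
  D1 <- mg$m1 / (a1 + b1 + rho)
  p2 <- (mg$m2 / (-a2)) * (rho - a2) / (rho - a2 - b2)
  q2 <- (mg$m2 / (-b2)) * (rho - b2) / (rho - a2 - b2)
  D2 <- mg$m2 / (rho - a2 - b2)
  equilibrium_record("F", c(p1, p2, q1, q2, D1, D2), TRUE,
                     "weak_migration_approx")
}

# Deme-1 quasi-linkage-equilibrium corrections for arbitrary raw parameters;
# deme 2 is obtained by the deme-exchange symmetry.
qle_deme1 <- function(a1, a2, b1, b2, m1, m2, rho) {
  s1 <- m1 / a1; s2 <- m2 / a2
  t1 <- m1 / b1; t2 <- m2 / b2
  pA <- one_locus_poly(s1, s2)
  qB <- one_locus_poly(t1, t2)
  rs <- sqrt(1 - 4 * s1 * s2); rt <- sqrt(1 - 4 * t1 * t2)
  p1 <- pA[1] + (s1 / rho) * (s2 * (b1 - b2) + b1 * rs) / rs * (qB[1] - qB[2])
  q1 <- qB[1] + (t1 / rho) * (t2 * (a1 - a2) + a1 * rt) / rt * (pA[1] - pA[2])
  D1 <- (m1 / rho) * (pA[1] - pA[2]) * (qB[1] - qB[2])
  c(p1 = p1, q1 = q1, D1 = D1)
}

#' Quasi-linkage-equilibrium approximation of the fully polymorphic equilibrium
#'
#' O(1/rho) corrections to the LE equilibrium `Finf` for strong but finite
#' recombination. The linkage disequilibria are
#' `D_k = (m_k / rho)(p1inf - p2inf)(q1inf - q2inf) >= 0`, positive whenever
#' the demes are differentiated at both loci. The approximation error is
#' O(rho^-2).
#'
#' @param params a `migsel_params` object with finite `rho > 0`; the LE
#'   equilibrium `Finf` must be admissible.
#' @return an equilibrium record labelled `F` with source `"qle_approx"`.
#' @export
qle_F <- function(params) {
  if (params$le || params$rho <= 0)
    stop("QLE approximation requires finite rho > 0")
  fi <- f_infinity(params)
  if (!fi$admissible)
    stop("the LE equilibrium Finf is not admissible for these parameters")
  sel <- params$selection; mg <- params$migration
  d1 <- qle_deme1(sel$alpha1, sel$alpha2, sel$beta1, sel$beta2,
                  mg$m1, mg$m2, params$rho)
  d2x <- qle_deme1(-sel$alpha2, -sel$alpha1, -sel$beta2, -sel$beta1,
                   mg$m2, mg$m1, params$rho)
  equilibrium_record("F", c(d1[["p1"]], 1 - d2x[["p1"]],
                            d1[["q1"]], 1 - d2x[["q1"]],
                            d1[["D1"]], d2x[["D1"]]),
                     TRUE, "qle_approx")
}

# Damped Newton iteration for the 6-dimensional equilibrium condition,
# using the analytic Jacobian.
newton_equilibrium <- function(x0, params, tol = 1e-13, maxit = 60) {
  x <- as_state(x0)
  f <- allele_ld_rhs(x, params)
  for (it in seq_len(maxit)) {
    nf <- max(abs(f))
    if (nf < tol) return(list(state = x, residual = nf, converged = TRUE))
    J <- jacobian_allele_ld(x, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(list(state = x, residual = nf, converged = FALSE))
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- tryCatch(allele_ld_rhs(xn, params), error = function(e) NULL)
      if (!is.null(fn) && max(abs(fn)) < nf) break
      lam <- lam / 2
      if (lam < 1e-8) return(list(state = x, residual = nf, converged = FALSE))
    }
    x <- as_state(xn); f <- fn
  }
  list(state = x, residual = max(abs(f)), converged = max(abs(f)) < 1e-10)
}

#' Locate internal (fully polymorphic) equilibria numerically
#'
#' Multi-start damped-Newton search on the six-dimensional equilibrium
#' condition, seeded from the weak-migration and QLE approximations, the
#' complete-linkage equilibrium, and a coarse interior grid. Roots closer
#' than `merge_tol` in state space are merged. At any internal equilibrium
#' both linkage disequilibria are nonzero (an internal equilibrium in LE
#' would require identical allele frequencies across demes, which only occurs
#' on the boundary).
#'
#' @param params a `migsel_params` object with finite `rho > 0`.
#' @param n_starts number of additional grid seeds (default 32).
#' @param merge_tol merging tolerance for duplicate roots.
#' @param interior_tol minimal distance of every gamete frequency from 0.
#' @return list of equilibrium records (possibly empty), each with a
#'   `near_singular` flag set when the Jacobian at the root is close to
#'   singular (proximity to a saddle-node bifurcation).
#' @export
find_internal <- function(params, n_starts = 32, merge_tol = 1e-8,
                          interior_tol = 1e-9) {
  if (params$le) stop("find_internal requires finite rho")
  seeds <- list()
  add_seed <- function(s) {
    s <- tryCatch(clip_state(as_state(s), tol = Inf), error = function(e) NULL)
    if (!is.null(s)) seeds[[length(seeds) + 1L]] <<- s
  }
  add_seed(weak_migration_F(params)$state)
  fi <- f_infinity(params)
  if (fi$admissible) {
    add_seed(fi$state)
    if (params$rho > 0)
      try(add_seed(qle_F(params)$state), silent = TRUE)
  }
  f0 <- f_zero(params)
  if (f0$admissible) add_seed(f0$state)
  grid <- seq(0.15, 0.85, length.out = max(2L, ceiling(sqrt(n_starts))))
  for (u in grid) for (v in grid) {
    if (length(seeds) >= n_starts + 4L) break
    add_seed(c(u, 1 - u, v, 1 - v, 0, 0))
  }
  roots <- list()
  for (s in seeds) {
    r <- newton_equilibrium(s, params)
    if (!r$converged) next
    x <- r$state
    g <- tryCatch(state_to_gametes(clip_state(x, tol = 1e-7), check = FALSE),
                  error = function(e) NULL)
    if (is.null(g) || any(g < interior_tol)) next      # boundary root
    dup <- FALSE
    for (rr in roots) if (max(abs(rr$state - x)) < merge_tol) { dup <- TRUE; break }
    if (dup) next
    J <- jacobian_allele_ld(x, params)
    sv <- svd(J, nu = 0, nv = 0)$d
    roots[[length(roots) + 1L]] <- equilibrium_record(
      "F", x, TRUE, "numeric",
      list(near_singular = min(sv) < 1e-8 * max(sv), residual = r$residual))
  }
  if (length(roots) > 2L)
    warning("more than two internal equilibria located; reporting all")
  roots
}
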