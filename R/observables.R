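# Migration load and the haplotype-based multilocus fixation index.

#' Migration load
#'
#' Deviation of each deme's mean fitness from its local optimum
#' (`alpha_k + beta_k` in deme 1, `-(alpha_2 + beta_2)` in deme 2):
#' `L1 = 2(alpha1(1-p1) + beta1(1-q1))`, `L2 = 2(-alpha2 p2 - beta2 q2)`,
#' and, for demes of equal size, the total load `L = (L1 + L2)/2`.
#'
#' @param state named state vector `(p1, p2, q1, q2, D1, D2)`.
#' @param selection a `migsel_params` object or its `selection` component.
#' @return list with `L1`, `L2`, `L` (fitness units).
#' @export
migration_load <- function(state, selection) {
  s <- sel_of(selection)
  st <- as_state(state)
  L1 <- 2 * (s$alpha1 * (1 - st[["p1"]]) + s$beta1 * (1 - st[["q1"]]))
  L2 <- 2 * (-s$alpha2 * st[["p2"]] - s$beta2 * st[["q2"]])
  list(L1 = L1, L2 = L2, L = 0.5 * (L1 + L2))
}

#' Weak-migration approximation of the migration load
#'
#' At the weakly perturbed polymorphic equilibrium,
#' `L1 ~ 2 m1 (alpha1 + beta1 + 2 rho) / (alpha1 + beta1 + rho)` and the
#' deme-exchange analogue for deme 2. Both loads increase with the
#' migration rates and with the recombination rate: tighter linkage keeps
#' the locally adapted haplotypes together and lowers the load. The error
#' is O(m^2).
#'
#' @param params a `migsel_params` object with finite `rho`.
#' @return list with `L1`, `L2`, `L`.
#' @export
load_weak_approx <- function(params) {
  if (params$le) stop("the weak-migration load requires finite rho")
  s <- params$selection; mg <- params$migration
  rho <- params$rho
  L1 <- 2 * mg$m1 * (s$alpha1 + s$beta1 + 2 * rho) / (s$alpha1 + s$beta1 + rho)
  L2 <- 2 * mg$m2 * (-(s$alpha2 + s$beta2) + 2 * rho) /
    (-(s$alpha2 + s$beta2) + rho)
  list(L1 = L1, L2 = L2, L = 0.5 * (L1 + L2))
}

#' Multilocus (haplotype) fixation index
#'
#' Haplotype-based generalization of the classical F_ST: with deme weights
#' `c_k` and mean haplotype frequencies `xbar_i = sum_k c_k x_ik`,
#' \deqn{F_{ST} = 1 - \bar h_S / h_T =
#'   \frac{\sum_i \mathrm{Var}(x_i)}{\sum_i \bar x_i (1 - \bar x_i)},}
#' where `h_T` is the haplotype heterozygosity the total population would
#' have under panmixia and `hbar_S` the actual one. The variances are
#' population (weighted) variances over the two demes. The full pairwise
#' matrix `F_ST[i, j]` standardizes the covariance of haplotype
#' frequencies: `mean(x_i^2) = xbar_i^2 + F_ST[i,i] xbar_i(1 - xbar_i)` and
#' `mean(x_i x_j) = (1 - F_ST[i,j]) xbar_i xbar_j` for `i != j`.
#'
#' @param state a `(p1,p2,q1,q2,D1,D2)` state vector or a 4 x 2 gamete
#'   matrix.
#' @param weights deme weights `c(c1, c2)` (non-negative, summing to 1).
#' @return list with `FST` (scalar in `[0, 1]`), `h_S_bar`, `h_T`, `xbar`,
#'   `FST_matrix`, `FST_single_locus` (per-locus classical values and their
#'   heterozygosity-weighted average). `FST` is `NA` (flagged via
#'   `monomorphic = TRUE`) when the total population is monomorphic.
#' @export
fst <- function(state, weights = c(0.5, 0.5)) {
  stopifnot(length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-12)
  x <- if (is.matrix(state)) state else state_to_gametes(as_state(state))
  xbar <- as.numeric(x %*% weights)
  x2bar <- as.numeric((x^2) %*% weights)
  h_T <- sum(xbar * (1 - xbar))
  h_S_bar <- sum(xbar - x2bar)
  vx <- x2bar - xbar^2
  Fmat <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) {
      den <- xbar[i] * (1 - xbar[i])
      Fmat[i, i] <- if (den > 0) (x2bar[i] - xbar[i]^2) / den else NA_real_
    } else {
      xij <- sum(weights * x[i, ] * x[j, ])
      den <- xbar[i] * xbar[j]
      Fmat[i, j] <- if (den > 0) 1 - xij / den else NA_real_
    }
  }
  mono <- h_T <= 0
  # single-locus values for comparison with the multilocus index
  p <- x[1, ] + x[2, ]; q <- x[1, ] + x[3, ]
  fst1 <- function(f) {
    fb <- sum(weights * f); den <- fb * (1 - fb)
    if (den > 0) (sum(weights * f^2) - fb^2) / den else NA_real_
  }
  fA <- fst1(p); fB <- fst1(q)
  hA <- { pb <- sum(weights * p); 2 * pb * (1 - pb) }
  hB <- { qb <- sum(weights * q); 2 * qb * (1 - qb) }
  avg <- if ((hA + hB) > 0) (fA * hA + fB * hB) / (hA + hB) else NA_real_
  list(FST = if (mono) NA_real_ else sum(vx) / h_T,
       h_S_bar = h_S_bar, h_T = h_T, xbar = xbar, FST_matrix = Fmat,
       FST_single_locus = list(A = fA, B = fB, weighted_average = avg),
       monomorphic = mono)
}

#' Weak-migration approximation of the multilocus fixation index
#'
#' To leading order in `m`, at the stable polymorphic equilibrium,
#' \deqn{F_{ST} = 1 - m\Big[\frac{\phi}{c_2}
#'   \frac{\alpha_1\beta_1+(\alpha_1+\beta_1)\rho}{\alpha_1\beta_1(\alpha_1+\beta_1+\rho)}
#'   - \frac{1-\phi}{c_1}
#'   \frac{\alpha_2\beta_2-(\alpha_2+\beta_2)\rho}{\alpha_2\beta_2(\alpha_2+\beta_2-\rho)}\Big].}
#' Differentiation decreases with `m` and increases as `rho` decreases:
#' linkage amplifies divergence under weak migration.
#'
#' @param params a `migsel_params` object with finite `rho`.
#' @param weights deme weights `c(c1, c2)`.
#' @return the approximate F_ST (scalar).
#' @export
fst_weak_approx <- function(params, weights = c(0.5, 0.5)) {
  if (params$le) stop("the weak-migration F_ST requires finite rho")
  s <- params$selection; mg <- params$migration
  rho <- params$rho
  a1 <- s$alpha1; a2 <- s$alpha2; b1 <- s$beta1; b2 <- s$beta2
  if (mg$m == 0) return(1)
  1 - mg$m * ((mg$phi / weights[2]) *
                (a1 * b1 + (a1 + b1) * rho) / (a1 * b1 * (a1 + b1 + rho)) -
              ((1 - mg$phi) / weights[1]) *
                (a2 * b2 - (a2 + b2) * rho) / (a2 * b2 * (a2 + b2 - rho)))
}
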