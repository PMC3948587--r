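# Parameter objects and canonicalization for the two-locus two-deme model.
#
# The model follows the usual sign conventions for divergent genic selection:
# alleles A1 and B1 are favoured in deme 1, A2 and B2 in deme 2, so that
# alpha1 > 0 > alpha2 and beta1 > 0 > beta2 after relabelling.  Locus B is,
# by convention, the locus under stronger selection in deme 1 (beta1 >= alpha1)
# and the selection asymmetry theta = alpha1*beta2 - alpha2*beta1 is
# non-negative.  Any parameter set in which each allele is favoured in exactly
# one deme can be brought into this normal form by relabelling alleles,
# exchanging loci, or exchanging demes; the applied transform is recorded so
# results can be mapped back to the user's labels.

#' Construct a model parameter set
#'
#' Builds (and by default canonicalizes) the full parameter set of the
#' two-locus two-deme migration-selection model: Malthusian selection
#' coefficients `alpha1`, `alpha2` (locus A) and `beta1`, `beta2` (locus B),
#' immigration rates `m1`, `m2` (or total rate `m` and ratio `phi = m1/m`),
#' and the recombination rate `rho`.
#'
#' @param alpha1,alpha2 selection coefficients of allele A1 in demes 1 and 2
#'   (rates per unit time).
#' @param beta1,beta2 selection coefficients of allele B1 in demes 1 and 2.
#' @param m1,m2 immigration replacement rates into demes 1 and 2. Supply
#'   either both of these or `m` together with `phi`.
#' @param m total migration rate `m1 + m2`.
#' @param phi migration ratio `m1 / m` in `[0, 1]`.
#' @param rho recombination rate between the two selected loci (>= 0), or the
#'   string `"LE"` for the linkage-equilibrium dynamics (the strong-
#'   recombination limit, in which the loci evolve independently).
#' @param theta_zero_ok allow the degenerate case `theta == 0` (e.g. the
#'   super-symmetric model). By default parameter sets with `theta == 0` are
#'   rejected because several closed-form results require `theta > 0`.
#' @param canonicalize apply the label normal form (default). If `FALSE`, the
#'   supplied values must already satisfy the canonical sign conventions.
#'
#' @return An object of class `migsel_params`: a list with components
#'   `selection` (`alpha1`, `alpha2`, `beta1`, `beta2`, `theta`,
#'   `theta_tilde`), `migration` (`m1`, `m2`, `m`, `phi`), `rho`, `le`
#'   (logical linkage-equilibrium flag) and `transform` (the relabelling
#'   applied during canonicalization).
#' @examples
#' par <- model_parameters(0.5, -1, 2, -2, m1 = 0.1, m2 = 0.1, rho = 1)
#' par$selection$theta   # = 1
#' @export
model_parameters <- function(alpha1, alpha2, beta1, beta2,
                             m1 = NULL, m2 = NULL, m = NULL, phi = NULL,
                             rho = 0, theta_zero_ok = FALSE,
                             canonicalize = TRUE) {
  if (is.null(m1) != is.null(m2))
    stop("supply both `m1` and `m2`, or `m` and `phi`")
  if (is.null(m1)) {
    if (is.null(m) || is.null(phi))
      stop("supply either (m1, m2) or (m, phi)")
    stopifnot(m >= 0, phi >= 0, phi <= 1)
    m1 <- m * phi
    m2 <- m * (1 - phi)
  }
  if (m1 < 0 || m2 < 0) stop("migration rates must be non-negative")
  le <- identical(rho, "LE")
  if (le) rho <- Inf
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0)
    stop("`rho` must be a single non-negative number or \"LE\"")

  raw <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
              m1 = m1, m2 = m2)
  if (canonicalize) {
    can <- canonical_form(raw, theta_zero_ok = theta_zero_ok)
  } else {
    can <- list(values = raw,
                transform = list(allele_A = FALSE, allele_B = FALSE,
                                 locus_swap = FALSE, deme_swap = FALSE))
    check_canonical(can$values, theta_zero_ok)
  }
  v <- can$values
  mm <- v$m1 + v$m2
  out <- structure(list(
    selection = list(alpha1 = v$alpha1, alpha2 = v$alpha2,
                     beta1 = v$beta1, beta2 = v$beta2,
                     theta = v$alpha1 * v$beta2 - v$alpha2 * v$beta1,
                     theta_tilde = v$alpha1 * v$alpha2 - v$beta1 * v$beta2),
    migration = list(m1 = v$m1, m2 = v$m2, m = mm,
                     phi = if (mm > 0) v$m1 / mm else NA_real_),
    rho = rho, le = le,
    theta_zero_ok = theta_zero_ok,
    transform = can$transform
  ), class = "migsel_params")
  out
}

#' @export
print.migsel_params <- function(x, ...) {
  s <- x$selection; g <- x$migration
  cat("Two-locus two-deme migration-selection parameters\n")
  cat(sprintf("  alpha = (%.6g, %.6g)   beta = (%.6g, %.6g)\n",
              s$alpha1, s$alpha2, s$beta1, s$beta2))
  cat(sprintf("  theta = %.6g   theta_tilde = %.6g\n", s$theta, s$theta_tilde))
  cat(sprintf("  m1 = %.6g  m2 = %.6g  (m = %.6g, phi = %.6g)\n",
              g$m1, g$m2, g$m, g$phi))
  cat(if (x$le) "  rho = LE (linkage-equilibrium dynamics)\n"
      else sprintf("  rho = %.6g\n", x$rho))
  tr <- x$transform
  applied <- names(tr)[vapply(tr, isTRUE, logical(1))]
  if (length(applied))
    cat("  canonical transform:", paste(applied, collapse = ", "), "\n")
  invisible(x)
}

# Internal constructor bypassing the canonical-form checks: the dynamics are
# well defined for any sign pattern (used e.g. when bisecting on alpha1 in
# invasion analyses, where probe values may leave the canonical region).
params_raw <- function(alpha1, alpha2, beta1, beta2, m1, m2, rho = 0) {
  le <- identical(rho, "LE")
  if (le) rho <- Inf
  mm <- m1 + m2
  structure(list(
    selection = list(alpha1 = alpha1, alpha2 = alpha2,
                     beta1 = beta1, beta2 = beta2,
                     theta = alpha1 * beta2 - alpha2 * beta1,
                     theta_tilde = alpha1 * alpha2 - beta1 * beta2),
    migration = list(m1 = m1, m2 = m2, m = mm,
                     phi = if (mm > 0) m1 / mm else NA_real_),
    rho = rho, le = le, theta_zero_ok = TRUE,
    transform = list(allele_A = FALSE, allele_B = FALSE,
                     locus_swap = FALSE, deme_swap = FALSE)
  ), class = "migsel_params")
}

check_canonical <- function(v, theta_zero_ok) {
  theta <- v$alpha1 * v$beta2 - v$alpha2 * v$beta1
  ok <- v$alpha1 > 0 && v$alpha2 < 0 && v$beta1 > 0 && v$beta2 < 0 &&
    v$beta1 >= v$alpha1 && (theta > 0 || (theta_zero_ok && theta == 0))
  if (!ok)
    stop("parameters do not satisfy the canonical sign conventions; ",
         "use canonicalize = TRUE")
  invisible(TRUE)
}

# Relabelling transforms acting on the raw parameter list. Deme exchange is
# the combined map alpha_k -> -alpha_{k*}, beta_k -> -beta_{k*} (demes and
# allele labels exchanged together), which also swaps the migration rates.
tr_allele_A <- function(v) { v$alpha1 <- -v$alpha1; v$alpha2 <- -v$alpha2; v }
tr_allele_B <- function(v) { v$beta1 <- -v$beta1; v$beta2 <- -v$beta2; v }
tr_locus <- function(v) {
  list(alpha1 = v$beta1, alpha2 = v$beta2, beta1 = v$alpha1, beta2 = v$alpha2,
       m1 = v$m1, m2 = v$m2)
}
tr_deme <- function(v) {
  list(alpha1 = -v$alpha2, alpha2 = -v$alpha1,
       beta1 = -v$beta2, beta2 = -v$beta1,
       m1 = v$m2, m2 = v$m1)
}

canonical_form <- function(raw, theta_zero_ok = FALSE) {
  v <- raw
  sel <- unlist(v[c("alpha1", "alpha2", "beta1", "beta2")])
  if (any(sel == 0) && !theta_zero_ok)
    stop("zero selection coefficient: each allele must be under selection ",
         "in both demes (set theta_zero_ok = TRUE only relaxes theta > 0, ",
         "not zero coefficients)")
  if (any(sel == 0))
    stop("zero selection coefficients are not supported")
  tr <- list(allele_A = FALSE, allele_B = FALSE,
             locus_swap = FALSE, deme_swap = FALSE)
  if (v$alpha1 < 0 && v$alpha2 > 0) { v <- tr_allele_A(v); tr$allele_A <- TRUE }
  if (v$beta1 < 0 && v$beta2 > 0) { v <- tr_allele_B(v); tr$allele_B <- TRUE }
  if (sign(v$alpha1) == sign(v$alpha2) || sign(v$beta1) == sign(v$beta2))
    stop("each allele must be favoured in exactly one deme ",
         "(alpha1, alpha2 and beta1, beta2 must have opposite signs)")
  # Remaining freedom: locus exchange and/or deme exchange (both preserve the
  # sign pattern; each flips the sign of theta). Pick the least transformed
  # combination that gives beta1 >= alpha1 and theta >= 0.
  combos <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  best <- NULL
  for (cmb in combos) {
    w <- v
    if (cmb[1]) w <- tr_locus(w)
    if (cmb[2]) w <- tr_deme(w)
    theta <- w$alpha1 * w$beta2 - w$alpha2 * w$beta1
    if (w$beta1 >= w$alpha1 && theta >= 0) { best <- list(w = w, cmb = cmb); break }
  }
  if (is.null(best))
    stop("internal error: no canonical relabelling found")  # unreachable
  v <- best$w
  tr$locus_swap <- best$cmb[1]
  tr$deme_swap <- best$cmb[2]
  theta <- v$alpha1 * v$beta2 - v$alpha2 * v$beta1
  if (theta == 0 && !theta_zero_ok)
    stop("theta = alpha1*beta2 - alpha2*beta1 is zero; this degenerate case ",
         "must be requested explicitly with theta_zero_ok = TRUE")
  list(values = v, transform = tr)
}

#' Canonicalize raw model parameters
#'
#' Applies allele, locus and deme relabellings to bring a raw parameter set
#' into the canonical form `alpha1 > 0 > alpha2`, `beta1 > 0 > beta2`,
#' `beta1 >= alpha1`, `theta >= 0`, and records which relabellings were used.
#'
#' @param params a `migsel_params` object or a list with entries `alpha1`,
#'   `alpha2`, `beta1`, `beta2`, `m1`, `m2` (plus `rho`).
#' @inheritParams model_parameters
#' @return a canonical `migsel_params` object.
#' @export
canonicalize <- function(params, theta_zero_ok = FALSE) {
  if (inherits(params, "migsel_params")) {
    s <- params$selection; g <- params$migration
    model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                     m1 = g$m1, m2 = g$m2,
                     rho = if (params$le) "LE" else params$rho,
                     theta_zero_ok = theta_zero_ok || params$theta_zero_ok)
  } else {
    model_parameters(params$alpha1, params$alpha2, params$beta1, params$beta2,
                     m1 = params$m1, m2 = params$m2,
                     rho = if (is.null(params$rho)) 0 else params$rho,
                     theta_zero_ok = theta_zero_ok)
  }
}

#' Map a state between the user's labels and the canonical labels
#'
#' The canonicalization transform acts on states as follows: an allele
#' relabelling at locus A maps `p -> 1 - p` and `D -> -D`; at locus B,
#' `q -> 1 - q` and `D -> -D`; a locus exchange swaps `p` and `q`; a deme
#' exchange swaps the demes and replaces `(p, q) -> (1 - p, 1 - q)` (leaving
#' `D` unchanged). `direction = "from_canonical"` applies the inverse, mapping
#' results computed under the canonical labels back to the original labels.
#'
#' @param state named state vector `(p1, p2, q1, q2, D1, D2)`.
#' @param transform a transform record as stored in `migsel_params$transform`.
#' @param direction `"to_canonical"` or `"from_canonical"`.
#' @return the transformed state vector.
#' @export
apply_state_transform <- function(state, transform,
                                  direction = c("to_canonical", "from_canonical")) {
  direction <- match.arg(direction)
  st <- as_state(state)
  flipA <- function(s) { s[c("p1", "p2")] <- 1 - s[c("p1", "p2")]
    s[c("D1", "D2")] <- -s[c("D1", "D2")]; s }
  flipB <- function(s) { s[c("q1", "q2")] <- 1 - s[c("q1", "q2")]
    s[c("D1", "D2")] <- -s[c("D1", "D2")]; s }
  locus <- function(s) { s[c("p1", "p2", "q1", "q2")] <-
    s[c("q1", "q2", "p1", "p2")]; s }
  deme <- function(s) { s[c("p1", "p2", "q1", "q2", "D1", "D2")] <-
    c(1 - s["p2"], 1 - s["p1"], 1 - s["q2"], 1 - s["q1"], s["D2"], s["D1"]); s }
  ops <- list()
  if (isTRUE(transform$allele_A)) ops <- c(ops, list(flipA))
  if (isTRUE(transform$allele_B)) ops <- c(ops, list(flipB))
  if (isTRUE(transform$locus_swap)) ops <- c(ops, list(locus))
  if (isTRUE(transform$deme_swap)) ops <- c(ops, list(deme))
  if (direction == "from_canonical") ops <- rev(ops)  # each op is an involution
  for (f in ops) st <- f(st)
  st
}
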