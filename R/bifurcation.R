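# Bifurcation-diagram classification with the total migration rate m as the
# bifurcation parameter, at fixed selection coefficients, migration ratio phi
# and recombination regime.
#
# Under linkage equilibrium there are three diagram shapes (a, b, c) and five
# role assignments (L1..L5) mapping the abstract equilibria P_X, P_Y, M_i and
# rates m^X, m^Y to concrete ones. With complete linkage (rho = 0) there are
# ten shapes (a..j) with role assignments R1..R4 and R1'..R4'. In both
# regimes exactly one equilibrium is stable in each open m-interval, and the
# intervals are delimited by the critical rates of m_thresholds().

le_roles <- list(
  L1 = list(P_X = "PB1", P_Y = "PA1", M_i = "M1", m_X = "-m_B", m_Y = "-m_A"),
  L2 = list(P_X = "PA1", P_Y = "PB1", M_i = "M1", m_X = "-m_A", m_Y = "-m_B"),
  L3 = list(P_X = "PA1", P_Y = "PB2", M_i = "M3", m_X = "m_A", m_Y = "-m_B"),
  L4 = list(P_X = "PB2", P_Y = "PA1", M_i = "M3", m_X = "-m_B", m_Y = "m_A"),
  L5 = list(P_X = "PB2", P_Y = "PA2", M_i = "M4", m_X = "m_B", m_Y = "m_A")
)

rho0_roles <- list(
  R1 = list(P_X = "PA1", P_Y = "PB2", M_i = "M1", m_X = "|m_A|", m_Y = "|m_B|"),
  R2 = list(P_X = "PB2", P_Y = "PA1", M_i = "M4", m_X = "|m_B|", m_Y = "|m_A|"),
  R3 = list(P_X = "PA1", P_Y = "PB2", M_i = "M4", m_X = "|m_A|", m_Y = "|m_B|"),
  R4 = list(P_X = "PB2", P_Y = "PA1", M_i = "M1", m_X = "|m_B|", m_Y = "|m_A|"),
  "R1p" = list(P_X = "PA1", M_i = "M1", m_X = "|m_A|"),
  "R2p" = list(P_X = "PB2", M_i = "M4", m_X = "|m_B|"),
  "R3p" = list(P_X = "PA1", P_Y = "PB2", m_X = "|m_A|", m_Y = "|m_B|"),
  "R4p" = list(P_X = "PB2", P_Y = "PA1", m_X = "|m_B|", m_Y = "|m_A|")
)

near_eq <- function(a, b, tol = 1e-12) {
  if (!is.finite(a) || !is.finite(b)) return(is.infinite(a) && is.infinite(b))
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

new_bifurcation <- function(regime, diagram, role, intervals, events, extra = NULL) {
  structure(c(list(regime = regime, diagram = diagram, role = role,
                   role_map = switch(regime, LE = le_roles[[role]],
                                     rho0 = rho0_roles[[role]], NULL),
                   intervals = intervals, events = events), extra),
            class = "migsel_bifurcation")
}

#' @export
print.migsel_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation diagram [%s]: shape (%s), roles %s\n",
              x$regime, x$diagram, if (is.null(x$role)) "-" else x$role))
  cat("stable equilibrium by m-interval:\n")
  print(x$intervals, row.names = FALSE)
  if (nrow(x$events)) { cat("events:\n"); print(x$events, row.names = FALSE) }
  invisible(x)
}

#' Classify the bifurcation diagram under linkage equilibrium
#'
#' Determines, for fixed canonical selection coefficients and migration
#' ratio `phi`, the LE bifurcation-diagram shape (`a`, `b` or `c`), the role
#' assignment (`L1`..`L5`), the ordered m-intervals with their globally
#' stable equilibrium, and the bifurcation events. The stable sequence is
#' always `Finf` (for `m` below `min(|m^A|, |m^B|)`), then a single-locus
#' polymorphism, then a monomorphic equilibrium; in the degenerate shapes
#' the middle (`b`) or last (`c`) stage is absent.
#'
#' @param selection a `migsel_params` object or its `selection` component.
#' @param phi migration ratio in `[0, 1]`.
#' @param tol relative tolerance for detecting the degenerate equalities
#'   `phi = phi^X` (default 1e-12).
#' @return an object of class `migsel_bifurcation`.
#' @export
classify_LE <- function(selection, phi, tol = 1e-12) {
  s <- sel_of(selection)
  ph <- phi_thresholds(s)
  mt <- m_thresholds(s, phi, rho = 0)
  b2_lt_a2 <- s$beta2 < s$alpha2
  role <- diagram <- NULL
  if (b2_lt_a2 && near_eq(phi, ph$phi_AB_tilde, tol)) { diagram <- "b"; role <- "L1" }
  else if (near_eq(phi, ph$phi_AB, tol)) { diagram <- "b"; role <- "L4" }
  else if (near_eq(phi, ph$phi_A, tol)) { diagram <- "c"; role <- "L2" }
  else if (near_eq(phi, ph$phi_B, tol)) { diagram <- "c"; role <- "L5" }
  else if (b2_lt_a2 && phi < ph$phi_AB_tilde) { diagram <- "a"; role <- "L1" }
  else if (phi < ph$phi_A) { diagram <- "a"; role <- "L2" }
  else if (phi < ph$phi_AB) { diagram <- "a"; role <- "L3" }
  else if (phi < ph$phi_B) { diagram <- "a"; role <- "L4" }
  else { diagram <- "a"; role <- "L5" }

  absA <- abs(mt$m_A); absB <- abs(mt$m_B)
  lo <- min(absA, absB); hi <- max(absA, absB)
  term_me <- if (mt$m_A < 0) "M1" else if (mt$m_B < 0) "M3" else "M4"
  iv <- data.frame(m_lo = 0, m_hi = lo, stable = "Finf",
                   stringsAsFactors = FALSE)
  ev <- data.frame(m = numeric(0), type = character(0),
                   participants = character(0), stringsAsFactors = FALSE)
  if (diagram == "b" || near_eq(absA, absB, tol)) {
    iv <- rbind(iv, data.frame(m_lo = lo, m_hi = Inf, stable = term_me))
    ev <- rbind(ev, data.frame(m = lo, type = "exchange_of_stability",
                               participants = paste("Finf", term_me)))
  } else {
    slp <- if (absA > absB) "PA1" else if (mt$m_A < 0) "PB1" else "PB2"
    ev <- rbind(ev, data.frame(m = lo, type = "exchange_of_stability",
                               participants = paste("Finf", slp)))
    if (is.finite(hi)) {
      iv <- rbind(iv,
                  data.frame(m_lo = lo, m_hi = hi, stable = slp),
                  data.frame(m_lo = hi, m_hi = Inf, stable = term_me))
      ev <- rbind(ev, data.frame(m = hi, type = "exchange_of_stability",
                                 participants = paste(slp, term_me)))
    } else {
      iv <- rbind(iv, data.frame(m_lo = lo, m_hi = Inf, stable = slp))
    }
  }
  new_bifurcation("LE", diagram, role, iv, ev,
                  extra = list(phi = phi, thresholds = ph, m_rates = mt))
}

#' Classify the bifurcation diagram with complete linkage
#'
#' Determines, for fixed canonical selection and migration ratio `phi`, the
#' `rho = 0` bifurcation-diagram shape (`a`..`j`), the role assignment
#' (`R1`..`R4`, `R1p`..`R4p`), the stable m-intervals and the events. The
#' stable sequence starts with the maximal-LD polymorphism `F0` (for
#' `m < min(|m^F0|, m^*)`). If `|m^F0| <= m^*`, `F0` exits through a
#' monomorphic equilibrium; otherwise it loses stability at `m = m^*` while
#' still admissible (the line-of-equilibria degeneracy), a single-locus
#' polymorphism takes over, and a monomorphic equilibrium is stable for
#' large `m`.
#'
#' @inheritParams classify_LE
#' @return an object of class `migsel_bifurcation`.
#' @export
classify_rho0 <- function(selection, phi, tol = 1e-12) {
  s <- sel_of(selection)
  ph <- phi_thresholds(s, rho = 0)
  mt <- m_thresholds(s, phi, rho = 0)
  eqv <- function(x) near_eq(phi, x, tol)
  diagram <- role <- NULL
  if (eqv(ph$phi_M1)) { diagram <- "b"; role <- "R1p" }
  else if (eqv(ph$phi_M4)) { diagram <- "b"; role <- "R2p" }
  else if (eqv(ph$phi_A)) { diagram <- "d"; role <- "R1p" }
  else if (eqv(ph$phi_B)) { diagram <- "d"; role <- "R2p" }
  else if (eqv(ph$phi_AF0)) { diagram <- "f"; role <- "R2" }
  else if (eqv(ph$phi_BF0)) { diagram <- "f"; role <- "R1" }
  else if (eqv(ph$phi_F0) && eqv(ph$phi_AB)) { diagram <- "h"; role <- NA_character_ }
  else if (eqv(ph$phi_F0)) {
    diagram <- "i"; role <- if (ph$phi_F0 > ph$phi_AB) "R3p" else "R4p"
  } else if (eqv(ph$phi_AB)) {
    diagram <- "j"
    role <- if (ph$phi_AB < ph$phi_F0) "R1" else "R2"  # M_i = M1 resp. M4
  } else if (phi < ph$phi_M1) { diagram <- "a"; role <- "R1p" }
  else if (phi > ph$phi_M4) { diagram <- "a"; role <- "R2p" }
  else if (phi < ph$phi_A) { diagram <- "c"; role <- "R1p" }
  else if (phi > ph$phi_B) { diagram <- "c"; role <- "R2p" }
  else if (phi < ph$phi_AF0) { diagram <- "e"; role <- "R4" }
  else if (phi > ph$phi_BF0) { diagram <- "e"; role <- "R3" }
  else if (phi < min(ph$phi_F0, ph$phi_AB)) { diagram <- "g"; role <- "R4" }
  else if (ph$phi_F0 < ph$phi_AB && phi < ph$phi_AB) { diagram <- "g"; role <- "R2" }
  else if (ph$phi_AB < ph$phi_F0 && phi < ph$phi_F0) { diagram <- "g"; role <- "R1" }
  else { diagram <- "g"; role <- "R3" }

  absF0 <- abs(mt$m_F0); mstar <- mt$m_star
  iv <- data.frame(m_lo = numeric(0), m_hi = numeric(0), stable = character(0),
                   stringsAsFactors = FALSE)
  ev <- data.frame(m = numeric(0), type = character(0),
                   participants = character(0), stringsAsFactors = FALSE)
  bound1 <- min(absF0, mstar)
  iv <- rbind(iv, data.frame(m_lo = 0, m_hi = bound1, stable = "F0"))
  if (!is.finite(bound1)) {
    # F0 admissible and stable for every m (theta = 0 with phi = phi_AB)
  } else if (absF0 <= mstar) {
    me <- if (phi < ph$phi_F0) "M1" else "M4"
    iv <- rbind(iv, data.frame(m_lo = absF0, m_hi = Inf, stable = me))
    ev <- rbind(ev, data.frame(m = absF0, type = "exchange_of_stability",
                               participants = paste("F0", me)))
  } else {
    # F0 loses stability at m* while admissible; line of equilibria at m*
    if (eqv(ph$phi_AB)) {
      iv <- rbind(iv, data.frame(m_lo = mstar, m_hi = Inf, stable = "M3"))
      ev <- rbind(ev, data.frame(m = mstar, type = "marginal_line",
                                 participants = "F0 M3"))
    } else if (phi < ph$phi_AB) {
      ev <- rbind(ev, data.frame(m = mstar, type = "marginal_line",
                                 participants = "F0 PA1"))
      mexit <- abs(mt$m_A)
      if (is.finite(mexit)) {
        me <- if (phi < ph$phi_A) "M1" else "M3"
        iv <- rbind(iv,
                    data.frame(m_lo = mstar, m_hi = mexit, stable = "PA1"),
                    data.frame(m_lo = mexit, m_hi = Inf, stable = me))
        ev <- rbind(ev, data.frame(m = mexit, type = "exchange_of_stability",
                                   participants = paste("PA1", me)))
      } else {
        iv <- rbind(iv, data.frame(m_lo = mstar, m_hi = Inf, stable = "PA1"))
      }
    } else {
      ev <- rbind(ev, data.frame(m = mstar, type = "marginal_line",
                                 participants = "F0 PB2"))
      mexit <- abs(mt$m_B)
      if (is.finite(mexit)) {
        me <- if (phi < ph$phi_B) "M3" else "M4"
        iv <- rbind(iv,
                    data.frame(m_lo = mstar, m_hi = mexit, stable = "PB2"),
                    data.frame(m_lo = mexit, m_hi = Inf, stable = me))
        ev <- rbind(ev, data.frame(m = mexit, type = "exchange_of_stability",
                                   participants = paste("PB2", me)))
      } else {
        iv <- rbind(iv, data.frame(m_lo = mstar, m_hi = Inf, stable = "PB2"))
      }
    }
    if (is.finite(absF0)) {
      ev <- rbind(ev, data.frame(m = absF0, type = "exit",
                                 participants = paste("F0", if (phi < ph$phi_F0) "M1" else "M4")))
      ev <- ev[order(ev$m), ]
    }
  }
  new_bifurcation("rho0", diagram, role, iv, ev,
                  extra = list(phi = phi, thresholds = ph, m_rates = mt))
}

#' Sequence of bifurcation diagrams along the migration-ratio axis
#'
#' Classifies the diagram on a grid that includes all thresholds `phi^X`
#' lying in `(0, 1)` and the midpoints between consecutive thresholds,
#' yielding the ordered succession of diagram shapes as `phi` increases
#' from 0 to 1.
#'
#' @inheritParams classify_LE
#' @param regime `"LE"` or `"rho0"`.
#' @return data frame with columns `phi`, `diagram`, `role`.
#' @export
diagram_sequence <- function(selection, regime = c("LE", "rho0")) {
  regime <- match.arg(regime)
  s <- sel_of(selection)
  ph <- phi_thresholds(s, rho = 0)
  keys <- if (regime == "LE") c("phi_AB_tilde", "phi_A", "phi_AB", "phi_B")
          else c("phi_M1", "phi_A", "phi_AF0", "phi_F0", "phi_AB",
                 "phi_BF0", "phi_B", "phi_M4")
  th <- sort(unique(unlist(ph[keys])))
  th <- th[th > 0 & th < 1]
  pts <- sort(unique(c(th, (c(0, th) + c(th, 1)) / 2)))
  cls <- lapply(pts, function(p) {
    d <- if (regime == "LE") classify_LE(s, p) else classify_rho0(s, p)
    data.frame(phi = p, diagram = d$diagram,
               role = if (is.null(d$role)) NA_character_ else d$role,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, cls)
}

#' Numerical bifurcation scan over a grid of total migration rates
#'
#' For each `m` on the grid, assembles the closed-form boundary equilibria
#' and numerically located internal equilibria, classifies their stability
#' by eigenvalues, and records the set of stable equilibria. Changes of this
#' set between neighbouring grid points are localized by bisection. Windows
#' in which an internal equilibrium coexists with a stable boundary
#' equilibrium (the pattern arising under highly asymmetric migration with
#' intermediate recombination) are reported as bistable; disappearance of an
#' internal equilibrium without a boundary collision is typed as a
#' saddle-node.
#'
#' @inheritParams classify_LE
#' @param rho finite recombination rate (> 0).
#' @param m_grid increasing vector of total migration rates.
#' @param bisect_depth maximal number of bisection steps per event.
#' @param n_starts seeds for the internal-equilibrium search at each point.
#' @return an object of class `migsel_bifurcation` with `regime =
#'   "numeric"`; its `table` field holds the per-m equilibrium inventory.
#' @export
scan_numeric <- function(selection, phi, rho, m_grid, bisect_depth = 25,
                         n_starts = 12) {
  s <- sel_of(selection)
  snapshot <- function(m) {
    par <- model_parameters(s$alpha1, s$alpha2, s$beta1, s$beta2,
                            m = m, phi = phi, rho = rho,
                            theta_zero_ok = TRUE, canonicalize = FALSE)
    eqs <- c(monomorphic_equilibria(), slp_equilibria(par))
    eqs <- Filter(function(e) isTRUE(e$admissible), eqs)
    ints <- find_internal(par, n_starts = n_starts)
    if (length(ints))
      names(ints) <- paste0("F", seq_along(ints))
    eqs <- c(eqs, ints)
    stab <- vapply(eqs, function(e) {
      v <- tryCatch(classify_equilibrium(e, par), error = function(err) NULL)
      if (is.null(v)) NA_character_ else v$classification
    }, character(1))
    list(m = m, labels = names(eqs), stability = stab,
         n_internal = length(ints),
         states = lapply(eqs, `[[`, "state"),
         stable_set = sort(names(eqs)[stab == "asymptotically_stable"]))
  }
  snaps <- lapply(m_grid, snapshot)
  rows <- do.call(rbind, lapply(snaps, function(sn)
    data.frame(m = sn$m, label = sn$labels, stability = unname(sn$stability),
               stringsAsFactors = FALSE)))
  ev <- data.frame(m = numeric(0), type = character(0),
                   participants = character(0), stringsAsFactors = FALSE)
  iv <- data.frame(m_lo = numeric(0), m_hi = numeric(0), stable = character(0),
                   stringsAsFactors = FALSE)
  # internal equilibria are unordered; collapse their numbered labels
  sig <- function(sn) paste(sub("^F[0-9]+$", "FP", sn$stable_set), collapse = "+")
  cur_lo <- m_grid[1]
  for (i in seq_len(length(snaps) - 1)) {
    a <- snaps[[i]]; b <- snaps[[i + 1]]
    if (identical(sig(a), sig(b))) next
    lo <- a; hi <- b; depth <- 0
    while (depth < bisect_depth) {
      mid <- snapshot(0.5 * (lo$m + hi$m))
      if (identical(sig(mid), sig(lo))) lo <- mid else hi <- mid
      depth <- depth + 1
    }
    m_ev <- 0.5 * (lo$m + hi$m)
    bnd <- function(sn) sn$stable_set[!grepl("^F[0-9]", sn$stable_set)]
    type <- if (lo$n_internal > hi$n_internal && identical(bnd(lo), bnd(hi)))
      "saddle_node" else "exchange_of_stability"
    if (abs(hi$m - lo$m) > 1e-4 * max(1, abs(hi$m)))
      type <- paste0(type, "_unresolved")
    chg <- union(setdiff(lo$stable_set, hi$stable_set),
                 setdiff(hi$stable_set, lo$stable_set))
    ev <- rbind(ev, data.frame(m = m_ev, type = type,
                               participants = paste(sub("^F[0-9]+$", "FP", chg),
                                                    collapse = " ")))
    iv <- rbind(iv, data.frame(m_lo = cur_lo, m_hi = m_ev, stable = sig(a)))
    cur_lo <- m_ev
  }
  iv <- rbind(iv, data.frame(m_lo = cur_lo, m_hi = m_grid[length(m_grid)],
                             stable = sig(snaps[[length(snaps)]])))
  new_bifurcation("numeric", NA_character_, NULL, iv, ev,
                  extra = list(phi = phi, rho = rho, table = rows))
}
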