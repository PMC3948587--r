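# Configuration files, structured output, the parameter-sweep generator and
# the command-line dispatcher.

#' Read model parameters from a configuration file
#'
#' JSON (`.json`) and YAML (`.yml`/`.yaml`) configurations are supported,
#' with keys `alpha1`, `alpha2`, `beta1`, `beta2`, either `m1`/`m2` or
#' `m`/`phi`, and `rho` (a number or the string `"LE"`); optional
#' `theta_zero_ok`.
#'
#' @param path path to the configuration file.
#' @return a canonical `migsel_params` object.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, " (use JSON or YAML)"))
  rho <- cfg$rho
  if (is.null(rho)) stop("config must set rho (a number or \"LE\")")
  model_parameters(cfg$alpha1, cfg$alpha2, cfg$beta1, cfg$beta2,
                   m1 = cfg$m1, m2 = cfg$m2, m = cfg$m, phi = cfg$phi,
                   rho = if (identical(rho, "LE")) "LE" else as.numeric(rho),
                   theta_zero_ok = isTRUE(cfg$theta_zero_ok))
}

#' Write a table as tab-separated values
#'
#' @param df data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize equilibrium records to JSON
#'
#' @param records a list of equilibrium records (optionally carrying
#'   stability verdicts).
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
equilibria_to_json <- function(records, path = NULL) {
  rec <- lapply(records, function(e) {
    r <- list(label = e$label, coordinates = as.list(e$state),
              admissible = e$admissible, source = e$source)
    if (!is.null(e$stability))
      r$stability <- list(classification = e$stability$classification,
                          leading_real_part = e$stability$leading_real_part)
    r
  })
  js <- jsonlite::toJSON(unname(rec), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Generate a reproducible parameter sweep
#'
#' Draws random parameter sets satisfying the requested constraint mode:
#' `"canonical"` (divergent selection with `beta1 > alpha1` and
#' `theta > 0`), `"theta_zero"` (`theta = 0` exactly, `|alpha_k| <=
#' |beta_k|`), or `"super_symmetric"` (`alpha_k = beta_k`,
#' `alpha_1 = -alpha_2`, `m1 = m2`). Identical seeds yield identical
#' sweeps; the global random-number state is left untouched.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param mode constraint mode.
#' @param alpha1_range,alpha2_range,beta1_max ranges for the selection
#'   draws (the `beta` draws are derived to respect the mode's
#'   constraints).
#' @param m_range,phi_range,rho_range ranges for migration and
#'   recombination draws.
#' @return data frame with columns `alpha1`, `alpha2`, `beta1`, `beta2`,
#'   `m1`, `m2`, `m`, `phi`, `rho`; every row passes canonicalization as an
#'   identity transform.
#' @export
generate_sweep <- function(n, seed,
                           mode = c("canonical", "theta_zero", "super_symmetric"),
                           alpha1_range = c(0.1, 1), alpha2_range = c(-3, -0.1),
                           beta1_max = 3, m_range = c(0.01, 2),
                           phi_range = c(0.02, 0.98), rho_range = c(0, 3)) {
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runifr <- function(r) stats::runif(n, r[1], r[2])
  if (mode == "canonical") {
    alpha1 <- runifr(alpha1_range)
    beta1 <- stats::runif(n, alpha1, beta1_max)
    alpha2 <- runifr(alpha2_range)
    # beta2 strictly inside (alpha2*beta1/alpha1, 0) ensures theta > 0
    beta2 <- (alpha2 * beta1 / alpha1) * stats::runif(n, 0.05, 0.95)
  } else if (mode == "theta_zero") {
    alpha1 <- runifr(alpha1_range)
    beta1 <- stats::runif(n, alpha1, beta1_max)
    alpha2 <- runifr(alpha2_range)
    beta2 <- alpha2 * beta1 / alpha1      # theta = 0 exactly
  } else {
    s <- runifr(alpha1_range)
    alpha1 <- beta1 <- s
    alpha2 <- beta2 <- -s
  }
  m <- runifr(m_range)
  phi <- if (mode == "super_symmetric") rep(0.5, n) else runifr(phi_range)
  rho <- runifr(rho_range)
  data.frame(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
             m1 = m * phi, m2 = m * (1 - phi), m = m, phi = phi, rho = rho)
}

sweep_params <- function(row, rho = row$rho, theta_zero_ok = FALSE) {
  model_parameters(row$alpha1, row$alpha2, row$beta1, row$beta2,
                   m1 = row$m1, m2 = row$m2, rho = rho,
                   theta_zero_ok = theta_zero_ok)
}

# --- command-line dispatcher -------------------------------------------------

parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- sub("^--", "", a)
      k <- sub("=.*$", "", kv); v <- sub("^[^=]*=", "", kv)
      i <- i + 1
    } else {
      k <- sub("^--", "", a)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        v <- args[i + 1]; i <- i + 2
      } else { v <- "TRUE"; i <- i + 1 }
    }
    out[[gsub("-", "_", k)]] <- v
  }
  out
}

flag_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

cli_params <- function(flags) {
  if (!is.null(flags$config)) return(read_model_config(flags$config))
  rho <- flags$rho
  model_parameters(flag_num(flags, "alpha1"), flag_num(flags, "alpha2"),
                   flag_num(flags, "beta1"), flag_num(flags, "beta2"),
                   m1 = flag_num(flags, "m1"), m2 = flag_num(flags, "m2"),
                   m = flag_num(flags, "m"), phi = flag_num(flags, "phi"),
                   rho = if (identical(rho, "LE")) "LE"
                         else flag_num(flags, "rho", 0),
                   theta_zero_ok = isTRUE(as.logical(flags$theta_zero_ok)))
}

# Stable equilibrium by integration from the default interior start.
terminal_state <- function(params, horizon = 1e5) {
  integrate_dynamics(default_start(), params, horizon = horizon,
                     rhs_tol = 1e-10)$state
}

#' Command-line dispatcher
#'
#' Implements the `migsel` command-line tool (see `inst/cli/migsel`):
#' subcommands `simulate`, `equilibria`, `bifurcate`, `mmax`, `fst`,
#' `load`, `invasion`, `meff`, `sweep`. Parameters are supplied via
#' `--config FILE` (JSON/YAML) or individual flags (`--alpha1`, ...,
#' `--m`/`--phi` or `--m1`/`--m2`, `--rho`); outputs are written to
#' `--out` as TSV or JSON depending on the subcommand.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(argv) {
  usage <- paste(
    "usage: migsel <subcommand> [--config FILE | --alpha1 .. --rho ..] [--out FILE]",
    "subcommands: simulate equilibria bifurcate mmax fst load invasion meff sweep",
    sep = "\n")
  if (length(argv) < 1) { message(usage); return(invisible(1L)) }
  sub <- argv[1]
  res <- tryCatch({
    flags <- parse_flags(argv[-1])
    out <- flags$out
    switch(sub,
      simulate = {
        par <- cli_params(flags)
        sim <- integrate_dynamics(default_start(), par,
                                  horizon = flag_num(flags, "horizon", 1e5),
                                  keep_trajectory = !is.null(out))
        if (!is.null(out) && !is.null(sim$trajectory))
          write_tsv(sim$trajectory, out)
        message(sprintf("converged: %s at t = %.4g", sim$converged, sim$time))
        print(round(sim$state, 8))
      },
      equilibria = {
        par <- cli_params(flags)
        eqs <- c(monomorphic_equilibria(), slp_equilibria(par))
        if (par$le) eqs$Finf <- f_infinity(par)
        else if (par$rho == 0) eqs$F0 <- f_zero(par)
        else eqs <- c(eqs, find_internal(par))
        eqs <- lapply(eqs, function(e) {
          e$stability <- tryCatch(
            classify_equilibrium(e, par,
              subsystem = if (par$le) "le"
                          else if (par$rho == 0) "trigametic" else "full"),
            error = function(err) NULL)
          e
        })
        js <- equilibria_to_json(eqs, out)
        if (is.null(out)) cat(js, "\n")
      },
      bifurcate = {
        par <- cli_params(flags)
        regime <- if (is.null(flags$regime)) {
          if (par$le) "LE" else if (par$rho == 0) "rho0" else "numeric"
        } else flags$regime
        d <- switch(regime,
          LE = classify_LE(par, par$migration$phi),
          rho0 = classify_rho0(par, par$migration$phi),
          numeric = {
            mg <- seq(flag_num(flags, "m_min", 0.05),
                      flag_num(flags, "m_max", 2 * m_max_LE(par, par$migration$phi)),
                      length.out = flag_num(flags, "m_steps", 15))
            scan_numeric(par, par$migration$phi, par$rho, mg)
          },
          stop("unknown regime: ", regime))
        print(d)
        if (!is.null(out)) {
          js <- jsonlite::toJSON(list(regime = d$regime, diagram = d$diagram,
                                      role = d$role, intervals = d$intervals,
                                      events = d$events),
                                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
          writeLines(js, out)
        }
      },
      mmax = {
        par <- cli_params(flags)
        phis <- seq(flag_num(flags, "phi_min", 0.02),
                    flag_num(flags, "phi_max", 0.98),
                    length.out = flag_num(flags, "phi_steps", 25))
        tab <- data.frame(phi = phis,
                          m_max_LE = vapply(phis, function(p) m_max_LE(par, p), 0),
                          m_max_rho0 = vapply(phis, function(p) m_max_rho0(par, p), 0))
        if (!par$le && par$rho > 0)
          tab$m_max_numeric <- vapply(phis, function(p)
            tryCatch(m_max_numeric(par, p, par$rho)$m_max,
                     error = function(e) NA_real_), 0)
        if (!is.null(out)) write_tsv(tab, out) else print(tab)
      },
      fst = ,
      load = {
        par <- cli_params(flags)
        ms <- seq(flag_num(flags, "m_min", 0.05),
                  flag_num(flags, "m_max", 1),
                  length.out = flag_num(flags, "m_steps", 10))
        rows <- lapply(ms, function(m) {
          p <- model_parameters(par$selection$alpha1, par$selection$alpha2,
                                par$selection$beta1, par$selection$beta2,
                                m = m, phi = par$migration$phi,
                                rho = if (par$le) "LE" else par$rho,
                                theta_zero_ok = TRUE)
          st <- terminal_state(p)
          if (p$le) st <- c(st, D1 = 0, D2 = 0)
          fs <- fst(as_state(st))
          ld <- migration_load(as_state(st), p)
          data.frame(m = m, FST = fs$FST, L1 = ld$L1, L2 = ld$L2, L = ld$L)
        })
        tab <- do.call(rbind, rows)
        if (!is.null(out)) write_tsv(tab, out) else print(tab)
      },
      invasion = {
        par <- cli_params(flags)
        phis <- seq(flag_num(flags, "phi_min", 0.52),
                    flag_num(flags, "phi_max", 0.7),
                    length.out = flag_num(flags, "phi_steps", 8))
        tab <- data.frame(phi = phis, rho_max = vapply(phis, function(p) {
          pp <- model_parameters(par$selection$alpha1, par$selection$alpha2,
                                 par$selection$beta1, par$selection$beta2,
                                 m = par$migration$m, phi = p, rho = par$rho,
                                 theta_zero_ok = TRUE, canonicalize = FALSE)
          tryCatch(rho_max_for_invasion(pp), error = function(e) NA_real_)
        }, 0))
        if (!is.null(out)) write_tsv(tab, out) else print(tab)
      },
      meff = {
        par <- cli_params(flags)
        geom <- neutral_geometry(flag_num(flags, "rho_AN", par$rho / 2),
                                 flag_num(flags, "rho_NB", par$rho / 2))
        ms <- seq(flag_num(flags, "m_min", 0.01),
                  flag_num(flags, "m_max", 0.2),
                  length.out = flag_num(flags, "m_steps", 5))
        rows <- lapply(ms, function(m) {
          p <- model_parameters(par$selection$alpha1, par$selection$alpha2,
                                par$selection$beta1, par$selection$beta2,
                                m = m, phi = par$migration$phi, rho = par$rho,
                                theta_zero_ok = TRUE)
          me <- m_eff_numeric(p, geom)
          data.frame(m = m, m_eff_numeric = me$m_eff, m_eff_weak = me$approx)
        })
        tab <- do.call(rbind, rows)
        if (!is.null(out)) write_tsv(tab, out) else print(tab)
      },
      sweep = {
        tab <- generate_sweep(flag_num(flags, "n", 100),
                              seed = flag_num(flags, "seed", 1),
                              mode = if (is.null(flags$mode)) "canonical"
                                     else flags$mode)
        if (!is.null(out)) write_tsv(tab, out) else print(utils::head(tab))
      },
      { message(usage); stop("unknown subcommand: ", sub) }
    )
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(res)
}
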