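# keys a run configuration may carry, by mode
.config_keys <- list(
  common = c("mode", "seed", "out_dir", "time_unit"),
  profile = c("N", "a", "gamma1", "gamma2", "delta_mu", "kBT", "n_points"),
  mfpt = c("N", "a", "gamma1", "gamma2", "delta_mu", "kBT", "k0"),
  sweep = c("N_values", "a", "gamma1", "gamma2", "delta_mu", "kBT", "k0"),
  fpe = c("v", "D", "L", "n_x", "dt", "t_end", "scheme", "x0", "t_cutoff"),
  simulate = c("v", "D", "L", "n_events", "dt", "t_cap", "x0", "binning"),
  crossval = c("v", "D", "L", "n_events", "dt", "n_x", "dt_fpe", "t_end",
               "scheme", "x0")
)

.config_defaults <- list(seed = 1L, time_unit = "dimensionless",
                         a = 1, gamma2 = NULL, kBT = 1, delta_mu = 0,
                         k0 = 1, scheme = "crank-nicolson")

#' Build and validate a run configuration
#'
#' Assembles the configuration of a reproducible run from a YAML file
#' and/or direct arguments (direct arguments take precedence; overrides
#' are reported). Unknown keys are a hard error -- there are no silent
#' defaults for misspelled parameters.
#'
#' @param mode one of `"profile"`, `"mfpt"`, `"sweep"`, `"fpe"`,
#'   `"simulate"`, `"crossval"`.
#' @param ... configuration keys for the chosen mode (see Details).
#' @param file optional YAML file of keys; `mode` may come from the file.
#' @details Mode keys: `profile`/`mfpt` take the chain and thermodynamic
#'   parameters (`N`, `a`, `gamma1`, `gamma2`, `delta_mu`, `kBT`, plus
#'   `k0` or `n_points`); `sweep` takes `N_values`; `fpe` and `simulate`
#'   take the transport parameters (`v`, `D`, `L`) and numeric controls;
#'   `crossval` combines them. Common keys: `seed`, `out_dir`,
#'   `time_unit`.
#' @return An object of class `run_config` (a validated named list).
#' @examples
#' run_config("mfpt", N = 64, gamma1 = 0.5, delta_mu = 0)
#' @export
run_config <- function(mode = NULL, ..., file = NULL) {
  cfg <- list()
  if (!is.null(file)) {
    # quote bare top-level keys before parsing: YAML 1.1 would otherwise
    # read the key "N" as the boolean FALSE
    txt <- sub("^([A-Za-z_][A-Za-z0-9_.]*)([ \t]*):", "\"\\1\"\\2:",
               readLines(file))
    cfg <- yaml::yaml.load(paste(txt, collapse = "\n"))
    if (!is.list(cfg) || is.null(names(cfg)))
      stop("config file must contain a mapping of keys")
  }
  dots <- list(...)
  if (length(dots) && is.null(names(dots)))
    stop("configuration arguments must be named")
  overridden <- intersect(names(dots), names(cfg))
  if (length(overridden))
    message("direct arguments override file values for: ",
            paste(overridden, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.null(mode)) cfg$mode <- mode
  if (is.null(cfg$mode)) stop("'mode' is required")
  cfg$mode <- match.arg(cfg$mode, names(.config_keys)[-1])
  allowed <- c(.config_keys$common, .config_keys[[cfg$mode]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s) for mode '", cfg$mode, "': ",
         paste(unknown, collapse = ", "))
  for (k in intersect(names(.config_defaults), allowed)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- .config_defaults[[k]]
  }
  if (!is.null(cfg$gamma1) && is.null(cfg$gamma2)) cfg$gamma2 <- cfg$gamma1
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config (mode = %s)\n", x$mode))
  for (k in setdiff(names(x), "mode"))
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

write_json_17 <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

write_csv_17 <- function(df, path) {
  df[] <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Execute a configured run and write its artifacts
#'
#' Dispatches to the module matching `config$mode`, writes the CSV/JSON
#' artifacts into `config$out_dir` together with a manifest echoing the
#' fully resolved configuration (tool version, seed), and appends a
#' plain-text log. All floating-point output is serialized with 17
#' significant digits, so identical configuration and seed reproduce
#' byte-identical CSV/JSON artifacts (timestamps are confined to the
#' log).
#'
#' @param config a [run_config()].
#' @param quiet suppress the one-line completion message.
#' @return Invisibly, a list with `results` (the computed objects) and
#'   `files` (paths written).
#' @export
run_translocation <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (is.null(out)) stop("'out_dir' is required to run")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out, f)
  log_lines <- character()
  logit <- function(...) {
    log_lines <<- c(log_lines,
                    paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                           sprintf(...)))
  }
  manifest <- c(unclass(config),
                list(tool = "poretime",
                     version = as.character(utils::packageVersion("poretime"))))
  write_json_17(manifest, path("manifest.json"))
  logit("mode %s started (seed %s)", config$mode, config$seed)

  files <- c(manifest = path("manifest.json"))
  results <- switch(config$mode,
    profile = {
      sp <- polymer_spec(config$N, config$a, config$gamma1, config$gamma2)
      th <- thermo_state(config$delta_mu, config$kBT)
      np <- if (is.null(config$n_points)) 2048 else config$n_points
      pr <- free_energy_profile(sp, th, n_points = np)
      files <- c(files, write_profile(pr, path("profile.csv")))
      list(profile = pr)
    },
    mfpt = {
      sp <- polymer_spec(config$N, config$a, config$gamma1, config$gamma2)
      th <- thermo_state(config$delta_mu, config$kBT)
      r <- mfpt_quadrature(sp, th, k0 = config$k0)
      write_json_17(list(tau = r$tau, tau_k0 = r$tau_k0,
                         tau_k0_over_N2 = r$tau_k0_over_N2,
                         k0 = r$k0, method = r$method),
                    path("mfpt.json"))
      files <- c(files, mfpt = path("mfpt.json"))
      list(mfpt = r)
    },
    sweep = {
      th <- thermo_state(config$delta_mu, config$kBT)
      Ns <- as.numeric(config$N_values)
      taus <- vapply(Ns, function(N) {
        mfpt_quadrature(polymer_spec(N, config$a, config$gamma1,
                                     config$gamma2),
                        th, k0 = config$k0)$tau
      }, numeric(1))
      write_csv_17(data.frame(N = Ns, tau_k0 = taus * config$k0),
                   path("sweep.csv"))
      fit <- scaling_exponent(Ns, taus)
      write_json_17(list(exponent = fit$exponent,
                         exponent_se = fit$exponent_se,
                         exp_rate = fit$exp_rate,
                         preferred = fit$preferred),
                    path("sweep.json"))
      files <- c(files, sweep_csv = path("sweep.csv"),
                 sweep_json = path("sweep.json"))
      list(taus = taus, fit = fit)
    },
    fpe = {
      tp <- transport_params(config$v, config$D, config$L)
      gr <- spatial_grid(n_x = config$n_x, dt = config$dt,
                         t_end = config$t_end, scheme = config$scheme)
      fp <- first_passage(tp, gr, x0 = config$x0)
      write_csv_17(data.frame(t = fp$times, f = fp$density,
                              S = stats::approx(fp$survival_times,
                                                fp$survival,
                                                xout = fp$times)$y),
                   path("first_passage.csv"))
      tc <- if (is.null(config$t_cutoff)) max(fp$survival_times)
            else config$t_cutoff
      write_json_17(list(t_p = fp$t_p, t_mean = fp$t_mean,
                         P_e = translocation_probability_curve(fp, tc),
                         t_cutoff = tc, S_end = fp$S_end,
                         peclet = fp$peclet, scheme = fp$scheme,
                         n_x = gr$n_x, dt = gr$dt),
                    path("first_passage.json"))
      files <- c(files, fpt_csv = path("first_passage.csv"),
                 fpt_json = path("first_passage.json"))
      list(first_passage = fp)
    },
    simulate = {
      tp <- transport_params(config$v, config$D, config$L)
      x0 <- if (is.null(config$x0)) 0 else config$x0
      ne <- if (is.null(config$n_events)) 5000 else config$n_events
      ev <- simulate_drift_diffusion_escapes(tp, n_events = ne,
                                             dt = config$dt,
                                             seed = config$seed,
                                             t_cap = config$t_cap, x0 = x0)
      write_csv_17(data.frame(t_e = ev$times), path("events.csv"))
      hs <- histogram_mode(ev, binning = if (is.null(config$binning)) "FD"
                                         else config$binning)
      nb <- length(hs$counts)
      write_csv_17(data.frame(bin_left = hs$bin_edges[seq_len(nb)],
                              bin_right = hs$bin_edges[seq_len(nb) + 1L],
                              count = hs$counts),
                   path("histogram.csv"))
      write_json_17(list(t_p_hat = hs$t_p_hat, se_mode = hs$se_mode,
                         t_mean_hat = hs$t_mean_hat,
                         n_completed = ev$n_completed,
                         censored = ev$censored, seed = ev$seed),
                    path("summary.json"))
      files <- c(files, events = path("events.csv"),
                 histogram = path("histogram.csv"),
                 summary = path("summary.json"))
      list(events = ev, histogram = hs)
    },
    crossval = {
      tp <- transport_params(config$v, config$D, config$L)
      gr <- spatial_grid(n_x = config$n_x,
                         dt = if (is.null(config$dt_fpe)) config$dt
                              else config$dt_fpe,
                         t_end = config$t_end, scheme = config$scheme)
      ne <- if (is.null(config$n_events)) 5000 else config$n_events
      cv <- cross_validate(tp, n_events = ne, dt_sim = config$dt,
                           grid = gr, seed = config$seed, x0 = config$x0)
      write_json_17(list(sim_mean = cv$sim_mean, sim_se = cv$sim_se,
                         fpe_t_mean = cv$fpe_t_mean, quad_tau = cv$quad_tau,
                         z_sim_fpe = cv$z_sim_fpe,
                         z_sim_quad = cv$z_sim_quad,
                         z_fpe_quad = cv$z_fpe_quad,
                         ks_stat = cv$ks_stat, ks_crit = cv$ks_crit,
                         n_events = cv$n_events),
                    path("crossval.json"))
      files <- c(files, crossval = path("crossval.json"))
      list(crossval = cv)
    })

  logit("mode %s finished; %d artifact(s)", config$mode, length(files))
  writeLines(log_lines, path("run.log"))
  files <- c(files, log = path("run.log"))
  if (!quiet)
    message(sprintf("run '%s' complete: %d file(s) in %s",
                    config$mode, length(files), out))
  invisible(list(results = results, files = files))
}
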