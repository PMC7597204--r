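#' JSON serialisation of model objects
#'
#' Compact JSON for provenance: trees serialise to `{p, n}`, balls to their
#' prefix list, hop models to tree + barrier profile + rate scale.
#'
#' @param x a `social_tree`, `social_ball`, `barrier_profile` or
#'   `hop_model`.
#' @return A JSON string.
#' @export
uw_json <- function(x) UseMethod("uw_json")

uw_spec <- function(x) UseMethod("uw_spec")

#' @export
uw_spec.social_tree <- function(x) list(p = x$p, n = x$n)

#' @export
uw_spec.social_ball <- function(x) list(prefix = as.integer(x$prefix),
                                        radius = x$radius)

#' @export
uw_spec.barrier_profile <- function(x) {
  if (x$mode == "linear") list(mode = "linear", delta = x$delta)
  else list(mode = "custom", heights = x$heights)
}

#' @export
uw_spec.hop_model <- function(x) list(tree = uw_spec(x$tree),
                                      profile = uw_spec(x$profile),
                                      rate_scale = x$rate_scale)

#' @export
uw_json.default <- function(x) {
  jsonlite::toJSON(uw_spec(x), auto_unbox = TRUE, digits = NA)
}

#' Assemble and validate a run configuration
#'
#' Configuration for the reporting entry points ([run_exact()],
#' [run_simulate()], [run_figures()], [run_newick()]) and the command-line
#' wrapper.  Unspecified fields take the defaults of the small demo run
#' (`p = 2`, `n = 3`, `delta = 1`).  Configurations round-trip through YAML
#' via [read_run_config()].
#'
#' @param ... fields overriding the defaults: `mode`, `p`, `n`, `delta`,
#'   `heights` (custom barriers), `rate_scale`, `origin`, `subjects` (list
#'   of ball prefixes; `NULL` for the origin singleton), `t_min`, `t_max`,
#'   `points` (`NULL` for a spectrum-adapted grid), `walkers`, `seed`,
#'   `out` (output directory; `NULL` writes nothing).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(
    list(mode = "exact", p = 2L, n = 3L, delta = 1, heights = NULL,
         rate_scale = 1, origin = 0, subjects = NULL,
         t_min = NULL, t_max = NULL, points = 200L,
         walkers = 1000L, seed = 1L, out = NULL),
    list(...)
  )
  cfg$mode <- match.arg(cfg$mode, c("exact", "simulate", "fit", "figures", "newick"))
  tree <- social_tree(cfg$p, cfg$n) # validates p, n
  profile <- if (is.null(cfg$heights)) barrier_profile(delta = cfg$delta)
             else barrier_profile(heights = cfg$heights)
  model <- hop_model(tree, profile, rate_scale = cfg$rate_scale)
  if (cfg$origin < 0 || cfg$origin >= tree$n_states)
    stop("`origin` outside 0..p^n-1", call. = FALSE)
  cfg$p <- tree$p; cfg$n <- tree$n
  structure(cfg, class = "run_config")
}

config_model <- function(cfg) {
  profile <- if (is.null(cfg$heights)) barrier_profile(delta = cfg$delta)
             else barrier_profile(heights = cfg$heights)
  hop_model(social_tree(cfg$p, cfg$n), profile, rate_scale = cfg$rate_scale)
}

config_times <- function(cfg, model) {
  if (is.null(cfg$t_min) || is.null(cfg$t_max)) {
    recommended_time_grid(model, points = cfg$points)
  } else {
    log_time_grid(cfg$t_min, cfg$t_max, cfg$points)
  }
}

config_subjects <- function(cfg, model) {
  if (is.null(cfg$subjects)) return(NULL)
  lapply(cfg$subjects, function(s) {
    if (is.list(s)) s <- unlist(s)
    social_ball(model$tree, as.integer(s))
  })
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file.
#' @return [read_run_config()]: a `run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1L))], path)
  invisible(path)
}

resolved_config_list <- function(cfg, extra = list()) {
  c(cfg[!vapply(cfg, is.null, logical(1L))],
    list(package_version = as.character(utils::packageVersion("umwalk"))),
    extra)
}

write_report_json <- function(payload, path) {
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

out_path <- function(cfg, file) {
  if (is.null(cfg$out)) return(NULL)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  file.path(cfg$out, file)
}

#' Exact-trajectory run
#'
#' Solves the master equation for the configured tree, barriers, origin and
#' subjects and (optionally) writes the trajectory CSV plus a JSON report
#' embedding the full resolved configuration.
#'
#' @param cfg a [run_config()].
#' @return The `uw_trajectory`, invisibly when writing files.
#' @export
run_exact <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- config_model(cfg)
  times <- config_times(cfg, model)
  traj <- solve_master(model, times, origin = cfg$origin,
                       subjects = config_subjects(cfg, model))
  message(sprintf("solver: analytic spectrum, %s states, %d grid times",
                  format(model$tree$n_states, scientific = FALSE), length(times)))
  csv <- out_path(cfg, "trajectory.csv")
  if (!is.null(csv)) {
    write_trajectory_csv(traj, csv)
    write_report_json(resolved_config_list(cfg, list(
      solver = "analytic-spectrum",
      t_range = range(times)
    )), out_path(cfg, "trajectory.json"))
    return(invisible(traj))
  }
  traj
}

#' Stochastic-ensemble run with exact-vs-empirical comparison
#'
#' Simulates the configured walker ensemble, writes the occupancy CSV and a
#' comparison report against the exact solution: per-time z-scores of the
#' empirical return probability under the binomial sampling standard error.
#'
#' @param cfg a [run_config()] (fields `walkers`, `seed`).
#' @return List with the `uw_ensemble` run, the comparison tibble and
#'   `max_z`; invisibly when writing files.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- config_model(cfg)
  times <- config_times(cfg, model)
  run <- walk_ensemble(model, times, walkers = cfg$walkers,
                       origin = cfg$origin, seed = cfg$seed)
  emp <- empirical_trajectory(run)
  ref <- solve_master(model, times, origin = cfg$origin)
  z <- (emp$probability - ref$probability) /
    sqrt(pmax(ref$probability * (1 - ref$probability), 1e-300) / cfg$walkers)
  cmp <- dplyr::tibble(
    time = times,
    exact = ref$probability,
    empirical = emp$probability,
    z = z
  )
  max_z <- max(abs(z[ref$probability > 0 & ref$probability < 1]))
  message(sprintf("ensemble: %d walkers, seed %d, max |z| = %.2f",
                  cfg$walkers, cfg$seed, max_z))
  res <- list(run = run, comparison = cmp, max_z = max_z)
  csv <- out_path(cfg, "occupancy.csv")
  if (!is.null(csv)) {
    utils::write.csv(ensemble_occupancy(run), csv, row.names = FALSE)
    utils::write.csv(cmp, out_path(cfg, "comparison.csv"), row.names = FALSE)
    write_report_json(resolved_config_list(cfg, list(max_z = max_z)),
                      out_path(cfg, "simulate.json"))
    return(invisible(res))
  }
  res
}

#' Power-law fit run
#'
#' Solves the configured return probability on a spectrum-adapted grid and
#' fits the decay exponent, writing the fit report JSON.
#'
#' @param cfg a [run_config()].
#' @return The `uw_powerfit`; invisibly when writing files.
#' @export
run_fit <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- config_model(cfg)
  times <- config_times(cfg, model)
  traj <- if (model$profile$mode == "linear")
    solve_return_closed(model, times, origin = cfg$origin)
  else solve_master(model, times, origin = cfg$origin)
  fit <- fit_power_law(traj)
  message(sprintf("fit: a_hat = %.4f over t in [%.3g, %.3g] (%d points)",
                  fit$exponent_hat, fit$window[1], fit$window[2], fit$n_points))
  json <- out_path(cfg, "fit.json")
  if (!is.null(json)) {
    write_fit_json(fit, json)
    write_report_json(resolved_config_list(cfg), out_path(cfg, "fit_config.json"))
    return(invisible(fit))
  }
  fit
}

#' Barrier-regime comparison data
#'
#' Infection and herd-immunity curves for the three canonical barrier
#' strengths `Delta = B, 5B, 50B` with `B = 2 ln p`, on one shared
#' log-spaced time grid wide enough to cover all three relaxation spectra.
#' Weak barriers give the fastest decay of infection probability (lowest
#' curve) and the quickest rise of immunity; each fivefold barrier increase
#' slows both by shrinking the exponent `ln(p)/Delta`.
#'
#' @param p branching index.
#' @param n hierarchy depth.
#' @param points grid points.
#' @return A tibble with columns `delta_label` (`"B"`, `"5B"`, `"50B"`),
#'   `delta`, `exponent` (theoretical `ln p / Delta`), `time`, `infection`,
#'   `immunity`.
#' @export
figure_regimes <- function(p = 2, n = 8, points = 300) {
  B <- 2 * log(p)
  deltas <- c(B = B, `5B` = 5 * B, `50B` = 50 * B)
  models <- lapply(deltas, function(d)
    hop_model(social_tree(p, n), barrier_profile(delta = d)))
  spans <- lapply(models, function(m)
    range(recommended_time_grid(m, points = 2L)))
  times <- log_time_grid(min(unlist(spans)), max(unlist(spans)), points)
  purrr::imap_dfr(models, function(m, lab) {
    traj <- infection_probability(solve_return_closed(m, times))
    tibble::tibble(
      delta_label = lab,
      delta = m$profile$delta,
      exponent = theoretical_exponent(p, m$profile$delta),
      time = times,
      infection = traj$probability,
      immunity = 1 - traj$probability
    )
  })
}

#' Figure-regime run
#'
#' Generates [figure_regimes()] data, writes it as CSV with a JSON report
#' (including the three theoretical exponents), and optionally renders the
#' two plots.
#'
#' @param cfg a [run_config()]; `cfg$points` controls grid resolution.
#' @param plot also write `infection.png` / `immunity.png` (requires an
#'   output directory).
#' @return The regime tibble; invisibly when writing files.
#' @export
run_figures <- function(cfg, plot = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dat <- figure_regimes(p = cfg$p, n = cfg$n, points = cfg$points)
  csv <- out_path(cfg, "figure_regimes.csv")
  if (!is.null(csv)) {
    utils::write.csv(dat, csv, row.names = FALSE)
    exps <- dat |> dplyr::distinct(.data$delta_label, .data$delta, .data$exponent)
    write_report_json(resolved_config_list(cfg, list(
      B = 2 * log(cfg$p),
      exponents = as.list(stats::setNames(exps$exponent, exps$delta_label))
    )), out_path(cfg, "figure_regimes.json"))
    if (plot) {
      ggplot2::ggsave(out_path(cfg, "infection.png"),
                      plot_regimes(dat, "infection"), width = 7, height = 5)
      ggplot2::ggsave(out_path(cfg, "immunity.png"),
                      plot_regimes(dat, "immunity"), width = 7, height = 5)
    }
    return(invisible(dat))
  }
  dat
}

#' Newick-export run
#'
#' @param cfg a [run_config()].
#' @return The Newick string; invisibly when writing files.
#' @export
run_newick <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- config_model(cfg)
  nwk <- tree_newick(model$tree, profile = model$profile)
  path <- out_path(cfg, "social_tree.nwk")
  if (!is.null(path)) {
    writeLines(nwk, path)
    write_report_json(resolved_config_list(cfg), out_path(cfg, "newick.json"))
    return(invisible(nwk))
  }
  nwk
}

#' Dispatch a configured run
#'
#' Runs the entry point selected by `cfg$mode`; backbone of the
#' command-line wrapper in `inst/cli/umwalk.R`.
#'
#' @param cfg a [run_config()].
#' @return The mode's return value.
#' @export
run_mode <- function(cfg) {
  switch(cfg$mode,
    exact = run_exact(cfg),
    simulate = run_simulate(cfg),
    fit = run_fit(cfg),
    figures = run_figures(cfg),
    newick = run_newick(cfg)
  )
}
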