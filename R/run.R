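# Subcommand layer: each stage of the analysis is runnable from a single
# validated configuration, writing CSV artifacts plus a JSON metadata file
# that records the config hash, master seed and package version, so a
# re-run with the same config is byte-identical.

#' Run one stage of the analysis
#'
#' Executes a subcommand against a validated configuration and writes its
#' artifacts into `out_dir`:
#'
#' * `"ode"`: integrates the humans-forest system for each `beta` in the
#'   experiment block (baseline `a0`), writing one trajectory CSV per
#'   `beta` plus a `no_return.csv` summary.
#' * `"tech"`: samples first-passage times of the technology process under
#'   the configured noise and writes `fpt_samples.csv`.
#' * `"fpt-validate"`: for symmetric noise (uses the config's `gamma`, or
#'   4 if unset), writes the closed-form density table and empirical
#'   histogram (`fpt_analytic.csv`, `fpt_empirical.csv`) and a
#'   `fpt_validation.json` summary with the KS distance.
#' * `"survival"`: single-cell success estimate at the configured `beta`,
#'   `a0` and `alpha`, written to `survival.json`.
#' * `"sweep"`: full grid sweep, written to `sweep.csv`.
#'
#' @param subcommand one of `"ode"`, `"tech"`, `"fpt-validate"`,
#'   `"survival"`, `"sweep"`.
#' @param config a [load_config()] object (or path to a YAML config).
#' @param overrides named list applied over the experiment block (e.g.
#'   `list(n_trials = 100)`); `master_seed` may also be overridden.
#' @param out_dir output directory (default: the config's `output_dir`).
#' @return (invisibly) a named list of the artifact paths written.
#' @export
run_command <- function(subcommand = c("ode", "tech", "fpt-validate",
                                       "survival", "sweep"),
                        config = NULL, overrides = list(), out_dir = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  for (nm in names(overrides)) {
    if (nm == "master_seed") cfg$master_seed <- overrides[[nm]]
    else if (nm %in% names(cfg$experiment)) cfg$experiment[[nm]] <- overrides[[nm]]
    else if (nm %in% names(cfg$tech)) {
      cfg$tech[[nm]] <- overrides[[nm]]
      cfg$tech_params <- do.call(tech_params, cfg$tech)
    } else stop(sprintf("unknown override '%s'", nm))
  }
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- cfg$experiment
  seed <- cfg$master_seed
  artifacts <- list()

  if (subcommand == "ode") {
    summary_rows <- list()
    for (beta in exp$beta_values) {
      fp <- do.call(forest_params, modifyList(cfg$forest, list(beta = beta)))
      traj <- integrate_humans_forest(fp, horizon = exp$horizon,
                                      step = exp$step)
      nr <- find_no_return(traj)
      path <- file.path(out_dir, sprintf("trajectory_beta%g.csv", beta))
      write_trajectory_csv(traj, path, every = max(1L, round(1 / exp$step)))
      artifacts[[sprintf("trajectory_beta%g", beta)]] <- path
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        beta = beta, found = nr$found, t_nr = nr$t_nr, N_max = nr$N_max)
    }
    path <- file.path(out_dir, "no_return.csv")
    utils::write.csv(format_numeric_df(do.call(rbind, summary_rows)), path,
                     row.names = FALSE, quote = FALSE)
    artifacts$no_return <- path
  }

  if (subcommand == "tech") {
    fpt <- empirical_fpt_distribution(cfg$noise_spec, cfg$tech_params,
                                      n = exp$n_trials,
                                      seed = mix_seed(seed, 2L))
    path <- file.path(out_dir, "fpt_samples.csv")
    write_fpt_csv(fpt, path, seed = mix_seed(seed, 2L))
    artifacts$fpt_samples <- path
  }

  if (subcommand == "fpt-validate") {
    gamma <- if (!is.null(cfg$noise$gamma)) cfg$noise$gamma else 4
    spec <- dichotomous_spec(mode = "symmetric-rate", gamma = gamma,
                             initial_state_rule = "fixed-on")
    tp <- cfg$tech_params
    x <- mean_fpt(tp$T_target, tp$T_init, tp$alpha) # x - x1 on the W scale
    dist <- fpt_dist(x = x, x1 = 0, gamma = gamma)
    apath <- file.path(out_dir, "fpt_analytic.csv")
    write_density_csv(dist, apath)
    fpt <- empirical_fpt_distribution(spec, tp, n = exp$n_trials,
                                      seed = mix_seed(seed, 3L))
    epath <- file.path(out_dir, "fpt_empirical.csv")
    write_fpt_csv(fpt, epath, seed = mix_seed(seed, 3L))
    ks <- ks_distance(fpt$times[!fpt$censored], dist$cdf)
    jpath <- file.path(out_dir, "fpt_validation.json")
    jsonlite::write_json(list(gamma = gamma, n = exp$n_trials, ks = ks,
                              mean_empirical = mean(fpt$times, na.rm = TRUE),
                              mean_analytic = dist$mean),
                         jpath, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, list(fpt_analytic = apath, fpt_empirical = epath,
                                   fpt_validation = jpath))
  }

  if (subcommand == "survival") {
    est <- estimate_success_probability(cfg$forest_params, cfg$tech_params,
                                        cfg$noise_spec,
                                        n_trials = exp$n_trials,
                                        seed = mix_seed(seed, 4L),
                                        horizon = exp$horizon, step = exp$step)
    path <- file.path(out_dir, "survival.json")
    jsonlite::write_json(unclass(est), path, auto_unbox = TRUE, digits = NA)
    artifacts$survival <- path
  }

  if (subcommand == "sweep") {
    sw <- sweep_success(alpha_grid = exp$alpha_grid, a_grid = exp$a_grid,
                        beta_values = exp$beta_values,
                        n_trials = exp$n_trials, seed = seed,
                        spec = cfg$noise_spec, tech = cfg$tech_params,
                        forest = cfg$forest_params,
                        horizon = exp$horizon, step = exp$step)
    path <- file.path(out_dir, "sweep.csv")
    write_sweep_csv(sw, path)
    artifacts$sweep <- path
  }

  meta <- list(subcommand = subcommand, master_seed = seed,
               config_hash = config_hash(cfg),
               package_version = as.character(utils::packageVersion("forestcollapse")),
               artifacts = lapply(artifacts, basename))
  mpath <- file.path(out_dir, sprintf("%s_metadata.json",
                                      gsub("-", "_", subcommand)))
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA)
  artifacts$metadata <- mpath
  invisible(artifacts)
}
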