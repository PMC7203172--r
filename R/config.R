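# Run configuration: a single YAML file drives every stage. Unknown keys
# are rejected so typos fail loudly; missing keys fall back to the
# world-scale baseline defaults.

config_defaults <- function() {
  list(
    forest = list(r = 0.01, r_prime = 0.001, beta = 170, a0 = 1e-12,
                  R_c = 6e7, N0 = 6e9, R0 = 4e7, t0 = 2000, R_W = 1.5e8),
    tech = list(alpha = 0.345, T_init = 1e13, T_target = 4e26),
    noise = list(mean_off = 4, mean_on = 1, mode = "asymmetric-means",
                 gamma = NULL, initial_state_rule = "stationary"),
    experiment = list(
      alpha_grid = seq(0.25, 4.25, by = 0.25),
      a_grid = c(1e-5, 2e-5, 5e-5, 1e-4, 1.5e-4, 2e-4, 2.5e-4, 3e-4),
      beta_values = c(170, 300, 700),
      n_trials = 10000, horizon = 500, step = 0.01),
    master_seed = 1,
    output_dir = "."
  )
}

merge_block <- function(defaults, given, block) {
  if (is.null(given)) return(defaults)
  if (!is.list(given)) stop(sprintf("config block '%s' must be a mapping", block))
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in config block '%s': %s", block,
                 paste(unknown, collapse = ", ")))
  }
  for (nm in names(given)) defaults[[nm]] <- given[[nm]]
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with blocks `forest`, `tech`, `noise`,
#' `experiment` plus top-level `master_seed` and `output_dir`. Missing
#' keys are filled with the world-scale baseline (r = 0.01, r' = 0.001,
#' a0 = 1e-12, R_c = 6e7, levels 1e13 to 4e26 W, Moore rate, growth /
#' stagnation sojourn means 1 and 4 years); unknown keys are rejected with
#' the offending name. The parameter blocks are validated by constructing
#' the corresponding parameter objects.
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return an object of class `run_config`: the validated list with parsed
#'   `forest`, `tech` and `noise` parameter objects alongside the raw
#'   blocks.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$tech
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    raw <- yaml::read_yaml(path)
    if (is.null(raw) || (is.list(raw) && length(raw) == 0L)) {
      stop("config file is empty; provide at least one of the keys: ",
           paste(names(config_defaults()), collapse = ", "))
    }
    if (!is.list(raw)) stop("config must parse to a mapping of blocks")
  }
  defaults <- config_defaults()
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown top-level config key(s): %s (expected: %s)",
                 paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  }
  cfg <- list()
  for (block in c("forest", "tech", "noise", "experiment")) {
    cfg[[block]] <- merge_block(defaults[[block]], raw[[block]], block)
  }
  cfg$master_seed <- if (!is.null(raw$master_seed)) raw$master_seed else defaults$master_seed
  cfg$output_dir <- if (!is.null(raw$output_dir)) raw$output_dir else defaults$output_dir
  if (!(is.numeric(cfg$master_seed) && length(cfg$master_seed) == 1L)) {
    stop("'master_seed' must be a single integer")
  }
  # validate by construction
  cfg$forest_params <- do.call(forest_params, cfg$forest)
  cfg$tech_params <- do.call(tech_params, cfg$tech)
  cfg$noise_spec <- do.call(dichotomous_spec, cfg$noise)
  with(cfg$experiment, {
    stopifnot(n_trials >= 1, horizon > 0, step > 0,
              length(alpha_grid) >= 1, length(a_grid) >= 1,
              length(beta_values) >= 1)
  })
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration back to YAML
#'
#' Serialises the raw blocks of a [load_config()] result; loading the
#' dumped file reproduces the configuration (round-trip idempotence).
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  blocks <- cfg[c("forest", "tech", "noise", "experiment")]
  blocks$noise <- blocks$noise[!vapply(blocks$noise, is.null, logical(1))]
  blocks$master_seed <- cfg$master_seed
  blocks$output_dir <- cfg$output_dir
  yaml::write_yaml(blocks, path)
  invisible(path)
}

config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  txt <- yaml::as.yaml(cfg[c("forest", "tech", "noise", "experiment",
                             "master_seed")])
  # small stable FNV-1a style hash over the serialised text
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
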