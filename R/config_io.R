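#' Default master configuration
#'
#' Every tunable default of the simulator in one named list, mirroring the
#' YAML schema accepted by [load_config()]: sections `arm`, `muscles`
#' (overrides by muscle name), `afferents`, `neuron`, `synthetic_data`,
#' `commands`, `weights`, `scenario`.
#'
#' @return Nested named list.
#' @export
default_master_config <- function() {
  list(
    arm = default_arm_parameters(),
    afferents = default_afferent_parameters()[
      c("ia_velocity_gain", "ia_velocity_exponent", "ia_length_gain",
        "ii_length_gain", "baseline_rate_hz", "velocity_floor_mm_s",
        "delay_s", "envelope_velocity_mm_s", "envelope_length_mm")],
    neuron = default_neuron_parameters(),
    synthetic_data = list(kind = "flexion_extension", duration_s = 2.8,
                          elbow_rom_deg = 78, elbow_start_deg = 20,
                          shoulder_amplitude_deg = 10,
                          shoulder_start_deg = 0, sample_rate_hz = 100),
    commands = list(flexor = list(a = 0, f = 1, phi = 0, d = 0),
                    extensor = list(a = 0, f = 1, phi = 0, d = 0)),
    weights = list(),
    scenario = list(dt_s = 0.001, gravity_scale = 1,
                    gravity_rotation_deg = 0, seed = 1L)
  )
}

merge_checked <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        length(names(defaults[[key]]))) {
      defaults[[key]] <- merge_checked(defaults[[key]], user[[key]],
                                       paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a master configuration from YAML
#'
#' Reads a (possibly empty) YAML file, validates every key against the
#' default schema -- unknown keys are rejected with their full path --
#' and returns the defaults overridden by the file. The `weights` section
#' is a flat map `pathway: weight` or `pathway: {muscle: weight}`.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_master_config()
  # weights have no fixed default keys; validate separately
  w_user <- user$weights
  user$weights <- NULL
  cfg <- merge_checked(defaults, user)
  if (!is.null(w_user)) {
    bad <- setdiff(names(w_user), pathway_kinds())
    if (length(bad))
      stop("unknown pathway in weights: ", paste(bad, collapse = ", "))
    cfg$weights <- w_user
  }
  cfg
}

#' Build a `simulation_config` from a master configuration
#'
#' @param cfg list from [load_config()] or [default_master_config()].
#' @return A `simulation_config`.
#' @export
simulation_config_from_master <- function(cfg) {
  sd <- cfg$synthetic_data
  target <- make_target(trajectory_spec(
    kind = sd$kind, duration_s = sd$duration_s,
    elbow_rom_deg = sd$elbow_rom_deg, elbow_start_deg = sd$elbow_start_deg,
    shoulder_amplitude_deg = sd$shoulder_amplitude_deg,
    shoulder_start_deg = sd$shoulder_start_deg,
    sample_rate_hz = sd$sample_rate_hz))
  cf <- cfg$commands$flexor; ce <- cfg$commands$extensor
  cmds <- command_set(
    sinusoid_command(cf$a, cf$f, cf$phi, cf$d, group = "elbow_flexor"),
    sinusoid_command(ce$a, ce$f, ce$phi, ce$d, group = "elbow_extensor"))
  w_args <- cfg$weights
  weights <- if (length(w_args)) do.call(synaptic_weights, w_args) else
    synaptic_weights()
  aff <- default_afferent_parameters()
  for (k in names(cfg$afferents)) aff[[k]] <- cfg$afferents[[k]]
  simulation_config(
    target = target, weights = weights, commands = cmds,
    gravity = gravity_environment(cfg$scenario$gravity_scale,
                                  cfg$scenario$gravity_rotation_deg),
    dt_s = cfg$scenario$dt_s, arm = cfg$arm, afferents = aff,
    neuron = cfg$neuron)
}

trace_header <- function() {
  mn <- muscle_names()
  c("time_s", "shoulder_deg", "elbow_deg", "elbow_speed_deg_s",
    paste0("u_", mn), paste0("a_", mn), paste0("force_n_", mn))
}

#' Write a simulation trace to CSV
#'
#' Fixed documented header: `time_s,shoulder_deg,elbow_deg,
#' elbow_speed_deg_s`, then per-muscle excitation (`u_*`), activation
#' (`a_*`) and force (`force_n_*`) columns.
#'
#' @param trace a `simulation_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(trace$time_s, trace$shoulder_deg, trace$elbow_deg,
                   trace$elbow_speed_deg_s, trace$u, trace$a,
                   trace$force_n, check.names = FALSE)
  names(df) <- trace_header()
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a simulation trace CSV
#'
#' @param path CSV written by [write_trace()].
#' @return List with `time_s`, `shoulder_deg`, `elbow_deg`,
#'   `elbow_speed_deg_s` and matrices `u`, `a`, `force_n`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- trace_header()
  if (!identical(names(df), expected)) {
    missing <- setdiff(expected, names(df))
    stop("malformed trace header; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  mn <- muscle_names()
  pick <- function(prefix) {
    m <- as.matrix(df[paste0(prefix, mn)])
    colnames(m) <- mn
    m
  }
  list(time_s = df$time_s, shoulder_deg = df$shoulder_deg,
       elbow_deg = df$elbow_deg, elbow_speed_deg_s = df$elbow_speed_deg_s,
       u = pick("u_"), a = pick("a_"), force_n = pick("force_n_"))
}

#' Write / read a target trajectory CSV
#'
#' Header `time_s,shoulder_deg,elbow_deg`.
#'
#' @param target a `target_trajectory`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `target_trajectory` (read).
#' @export
write_target <- function(target, path) {
  utils::write.csv(target[c("time_s", "shoulder_deg", "elbow_deg")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target
#' @export
read_target <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df)[1:3], c("time_s", "shoulder_deg", "elbow_deg")))
    stop("malformed target header")
  class(df) <- c("target_trajectory", "data.frame")
  df
}

#' Write a metrics report (or any flat list) as JSON
#'
#' @param x named list of scalars.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write the baseline targets as CSV), `simulate`
#' (run one simulation from a YAML config and write the trace),
#' `environments` (list the seven gravity environments), `sweep` /
#' `perturb` (pathway sweeps), `sensitivity` (reduced Sobol experiment).
#' Invoke as `Rscript -e 'reflexarm::reflexarm_main()' <subcommand> ...`.
#'
#' @param args character vector (default: command-line arguments).
#' @return Invisibly, the subcommand's result.
#' @export
reflexarm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: reflexarm {synth|simulate|environments|sweep|perturb|sensitivity}\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- args[-1]
  get_opt <- function(flag, default = NULL) {
    i <- which(opts == flag)
    if (length(i) && i < length(opts)) opts[i + 1] else default
  }
  out_dir <- get_opt("--out", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  master <- if (!is.null(get_opt("--config")))
    load_config(get_opt("--config")) else default_master_config()
  res <- switch(
    cmd,
    synth = {
      fe <- make_target(baseline_flexion_extension_spec())
      ci <- make_target(baseline_circular_spec())
      write_target(fe, file.path(out_dir, "target_flexion_extension.csv"))
      write_target(ci, file.path(out_dir, "target_circular.csv"))
      list(fe = fe, ci = ci)
    },
    simulate = {
      cfg <- simulation_config_from_master(master)
      tr <- run_simulation(cfg)
      write_trace(tr, file.path(out_dir, "trace.csv"))
      write_metrics_json(metrics_report(tr, cfg$target),
                         file.path(out_dir, "metrics.json"))
      tr
    },
    environments = {
      envs <- gravity_environments()
      for (nm in names(envs))
        cat(sprintf("%-8s scale %.1f  rotation %+.0f deg\n", nm,
                    envs[[nm]]$magnitude_scale,
                    envs[[nm]]$direction_rotation_deg))
      envs
    },
    sweep = {
      cfg <- simulation_config_from_master(master)
      pathway <- get_opt("--pathway", "IaMN")
      tab <- scenario_pathway_sweep(pathway, c(0, 0.5, 1), cfg)
      utils::write.csv(tab, file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
      tab
    },
    perturb = {
      cfg <- simulation_config_from_master(master)
      pathway <- get_opt("--pathway", "IaMN")
      tab <- scenario_perturbation(pathway, c(0, 0.5, 1), cfg)
      utils::write.csv(tab, file.path(out_dir, "perturb.csv"),
                       row.names = FALSE)
      tab
    },
    sensitivity = {
      cfg <- simulation_config_from_master(master)
      metric <- get_opt("--metric", "rmse")
      n <- as.integer(get_opt("--n", "16"))
      res <- sensitivity_experiment(metric, cfg, n = n,
                                    seed = master$scenario$seed)
      write_metrics_json(list(S1 = as.list(res$S1), ST = as.list(res$ST)),
                         file.path(out_dir, "sensitivity.json"))
      res
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}
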