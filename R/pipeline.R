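#' Load and validate a run configuration
#'
#' Reads the YAML configuration driving the command-line pipeline. All
#' fields are optional; synthetic-scene defaults are filled in. Referenced
#' paths must exist; per-trial events must be strictly increasing.
#'
#' @param path YAML file path, or `NULL` for an all-defaults synthetic run.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    seed = 20220121, output = "kinekick_out",
    simulate = list(n_trials = 5, noise_px = 0.5, trial_jitter = 0.05),
    rig = list(), kick = list(),
    filter = list(butter_order = 4, cutoff_hz = 25, rloess_span = 0.1),
    association = list(method = "greedy", min_confidence = 0.1, max_gap = 5),
    stats = list(flag_min_trials = 5),
    keypoint_map = as.list(default_keypoint_map()),
    paths = list(), events = list())
  cfg <- modifyList(defaults, cfg)
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) abort(sprintf("config error in 'paths': '%s' does not exist", p))
  }
  for (trial in names(cfg$events)) {
    ev <- unlist(cfg$events[[trial]])
    if (any(diff(ev[c("cycle_start", "support_touchdown", "ball_contact")]) <= 0)) {
      abort(sprintf("config error in 'events': trial '%s' events must be strictly increasing", trial))
    }
  }
  structure(cfg, class = "run_config")
}

#' Generate a complete synthetic scene on disk
#'
#' Simulates one or more kick trials, renders them through the synthetic
#' rig, and writes every pipeline input: per-camera consolidated keypoint
#' JSON, the control-point CSV, the fitted camera YAML, ground-truth
#' trajectory CSVs, and a manifest YAML tying the scene together.
#'
#' @param config A [read_run_config()] result (or `NULL` for defaults).
#' @param dir Output directory.
#' @param seed Overrides the config seed when given.
#' @return Invisibly, the manifest list.
#' @export
simulate_scene <- function(config = NULL, dir, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  seed <- seed %||% cfg$seed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rig <- make_rig(do.call(rig_spec, cfg$rig), seed = seed)
  write_control_points(rig$control, file.path(dir, "control_points.csv"))
  write_camera_yaml(rig$cameras_fit, file.path(dir, "cameras.yaml"))
  n_trials <- cfg$simulate$n_trials
  trials <- sprintf("trial%02d", seq_len(n_trials))
  events <- list()
  jitter <- cfg$simulate$trial_jitter %||% 0.05
  for (i in seq_len(n_trials)) {
    # trial-to-trial variability: each kick draws its ROMs and terminal
    # speed within +/- jitter of the spec values (real kicks differ)
    set.seed(child_seed(seed + i, "trial"))
    base <- do.call(kick_sim_spec, modifyList(cfg$kick, list(seed = seed + i)))
    for (fld in c("knee_rom", "ankle_rom", "hip_rom", "terminal_foot_speed")) {
      base[[fld]] <- base[[fld]] * runif(1, 1 - jitter, 1 + jitter)
    }
    sim <- simulate_kick(base)
    tdir <- file.path(dir, trials[i])
    dir.create(tdir, showWarnings = FALSE)
    render_views(sim$trajectories, rig, noise_px = cfg$simulate$noise_px,
                 seed = seed + i, dir = tdir)
    write.csv(sim$trajectories, file.path(tdir, "ground_truth.csv"),
              row.names = FALSE)
    events[[trials[i]]] <- sim$events
  }
  manifest <- list(seed = seed, trials = trials, events = events,
                   cameras = names(rig$cameras_fit),
                   control_points = "control_points.csv",
                   camera_file = "cameras.yaml",
                   noise_px = cfg$simulate$noise_px)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

# one trial: keypoint tibbles per camera -> automatic kick cycle
process_trial <- function(views, models, events, cfg, rate, trial_id) {
  series <- purrr::map(views, function(df) {
    build_tracks(df, min_confidence = cfg$association$min_confidence,
                 method = cfg$association$method) %>%
      select_subject_track() %>%
      extract_marker_series(
        keypoint_map = unlist(cfg$keypoint_map),
        min_confidence = cfg$association$min_confidence) %>%
      interpolate_gaps(max_gap = cfg$association$max_gap)
  })
  traj <- reconstruct_trajectories(series, models, rate = rate)
  traj <- foot_com(traj)
  fs <- filter_spec(cfg$filter$butter_order, cfg$filter$cutoff_hz,
                    cfg$filter$rloess_span)
  smoothed <- smooth_dual(traj, fs, rate = rate)
  kick_cycle(smoothed, events, rate = rate, trial_id = trial_id)
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes simulate -> track -> calibrate -> reconstruct -> kinematics ->
#' compare end to end: the rendered keypoints are tracked, reconstructed
#' through the fitted DLT cameras and smoothed; the ground-truth
#' trajectories (smoothed identically) stand in for the manual reference;
#' and the full agreement battery is written to `<output>/report/` along
#' with smoothed trajectories (CSV + TRC), cycle CSVs and a run log.
#'
#' @param config Path to a YAML config, a [read_run_config()] result, or
#'   `NULL` for defaults.
#' @param output Output directory (overrides the config).
#' @param seed Seed (overrides the config).
#' @return The [compare_methods()] report, invisibly.
#' @export
run_pipeline <- function(config = NULL, output = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  seed <- seed %||% cfg$seed
  output <- output %||% cfg$output
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  scene_dir <- file.path(output, "scene")
  manifest <- simulate_scene(cfg, scene_dir, seed = seed)
  models <- read_camera_yaml(file.path(scene_dir, "cameras.yaml"))
  rate <- models[[1]]$rate
  fs <- filter_spec(cfg$filter$butter_order, cfg$filter$cutoff_hz,
                    cfg$filter$rloess_span)
  auto <- list(); manual <- list()
  for (trial in manifest$trials) {
    tdir <- file.path(scene_dir, trial)
    views <- purrr::map(manifest$cameras, function(cam) {
      read_openpose_json(file.path(tdir, paste0(cam, "_keypoints.json")),
                         camera_id = cam)
    })
    names(views) <- manifest$cameras
    ev <- manifest$events[[trial]]
    cyc <- process_trial(views, models, ev, cfg, rate, trial)
    truth <- as_tibble(read.csv(file.path(tdir, "ground_truth.csv"))) %>%
      foot_com() %>%
      smooth_dual(fs, rate = rate)
    ref <- kick_cycle(truth, ev, rate = rate, trial_id = trial)
    smoothed_out <- file.path(output, paste0(trial, "_smoothed"))
    write_trc(truth, paste0(smoothed_out, "_reference.trc"), rate = rate)
    write_cycle_csv(cyc, file.path(output, paste0(trial, "_cycle.csv")))
    auto[[trial]] <- cyc
    manual[[trial]] <- ref
  }
  report <- compare_methods(bind_cycles(manual), bind_cycles(auto),
                            flag_min_trials = cfg$stats$flag_min_trials)
  write_agreement_report(report, file.path(output, "report"))
  log <- list(package_version = as.character(utils::packageVersion("kinekick")),
              r_version = R.version.string, seed = seed,
              config = unclass(cfg), finished = TRUE)
  yaml::write_yaml(log, file.path(output, "run_log.yaml"))
  invisible(report)
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper over the pipeline functions, intended to
#' be called from the installed `cli/kinekick.R` Rscript launcher.
#' Subcommands: `simulate`, `track`, `calibrate`, `reconstruct`,
#' `kinematics`, `compare`, `run-all`. Global flags: `--config PATH`,
#' `--seed INT`, `--output DIR`, `--verbose`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
kick_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: kinekick.R <simulate|track|calibrate|reconstruct|kinematics|compare|run-all>",
    "  [--config PATH] [--seed INT] [--output DIR] [--verbose]", sep = "\n")
  get_flag <- function(name, default = NULL) {
    hit <- which(args == paste0("--", name))
    if (length(hit) == 0) return(default)
    if (hit[1] == length(args)) abort(sprintf("usage error: --%s needs a value", name))
    args[hit[1] + 1]
  }
  run <- function() {
    if (length(args) == 0) {
      message(usage)
      return(2L)
    }
    cmd <- args[1]
    cfg_path <- get_flag("config")
    seed <- as.integer(get_flag("seed", NA))
    if (is.na(seed)) seed <- NULL
    output <- get_flag("output")
    cfg <- read_run_config(cfg_path)
    switch(
      cmd,
      "simulate" = {
        simulate_scene(cfg, output %||% file.path(cfg$output, "scene"),
                       seed = seed)
        0L
      },
      "run-all" = {
        run_pipeline(cfg, output = output, seed = seed)
        0L
      },
      "calibrate" = {
        cp_path <- cfg$paths$control_points
        if (is.null(cp_path)) abort("config error: 'paths$control_points' is required for calibrate")
        control <- read_control_points(cp_path)
        cams <- unique(control$camera_id)
        models <- purrr::map(cams, ~ calibrate_dlt(control, .x))
        names(models) <- cams
        out <- output %||% cfg$output
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_camera_yaml(models, file.path(out, "cameras.yaml"))
        err <- calibration_error(models, control)
        message(sprintf("global calibration error (cm): x %.2f y %.2f z %.2f",
                        err$mae_x * 100, err$mae_y * 100, err$mae_z * 100))
        0L
      },
      "track" = {
        kp <- cfg$paths$keypoints
        if (is.null(kp)) abort("config error: 'paths$keypoints' is required for track")
        out <- output %||% cfg$output
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        for (cam in names(kp)) {
          frames <- if (dir.exists(kp[[cam]])) {
            read_openpose_dir(kp[[cam]], camera_id = cam)
          } else read_openpose_json(kp[[cam]], camera_id = cam)
          tracks <- build_tracks(frames,
                                 min_confidence = cfg$association$min_confidence,
                                 method = cfg$association$method)
          write_tracks_csv(tracks, file.path(out, paste0(cam, "_tracks.csv")))
        }
        0L
      },
      "reconstruct" = {
        tk <- cfg$paths$tracks
        cam_file <- cfg$paths$cameras
        if (is.null(tk) || is.null(cam_file)) {
          abort("config error: 'paths$tracks' and 'paths$cameras' are required for reconstruct")
        }
        models <- read_camera_yaml(cam_file)
        series <- purrr::imap(tk, function(f, cam) {
          read_tracks_csv(f) %>%
            mutate(person = .data$person_id) %>%
            select_subject_track(min_confidence = cfg$association$min_confidence) %>%
            extract_marker_series(keypoint_map = unlist(cfg$keypoint_map),
                                  min_confidence = cfg$association$min_confidence) %>%
            interpolate_gaps(max_gap = cfg$association$max_gap)
        })
        traj <- reconstruct_trajectories(series, models)
        out <- output %||% cfg$output
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write.csv(traj, file.path(out, "trajectories.csv"), row.names = FALSE)
        0L
      },
      "kinematics" = {
        tp <- cfg$paths$trajectories
        if (is.null(tp) || length(cfg$events) == 0) {
          abort("config error: 'paths$trajectories' and 'events' are required for kinematics")
        }
        fs <- filter_spec(cfg$filter$butter_order, cfg$filter$cutoff_hz,
                          cfg$filter$rloess_span)
        out <- output %||% cfg$output
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        trial <- names(cfg$events)[1]
        traj <- as_tibble(read.csv(tp)) %>% foot_com() %>% smooth_dual(fs)
        cyc <- kick_cycle(traj, cfg$events[[trial]], trial_id = trial)
        write_cycle_csv(cyc, file.path(out, paste0(trial, "_cycle.csv")))
        write_trc(traj, file.path(out, paste0(trial, "_smoothed.trc")))
        0L
      },
      "compare" = {
        ref_dir <- cfg$paths$reference
        test_dir <- cfg$paths$test
        if (is.null(ref_dir) || is.null(test_dir) || length(cfg$events) == 0) {
          abort("config error: 'paths$reference', 'paths$test' and 'events' are required for compare")
        }
        fs <- filter_spec(cfg$filter$butter_order, cfg$filter$cutoff_hz,
                          cfg$filter$rloess_span)
        load_side <- function(d) {
          purrr::map(names(cfg$events), function(trial) {
            traj <- as_tibble(read.csv(file.path(d, paste0(trial, ".csv")))) %>%
              foot_com() %>% smooth_dual(fs)
            kick_cycle(traj, cfg$events[[trial]], trial_id = trial)
          })
        }
        report <- compare_methods(bind_cycles(load_side(ref_dir)),
                                  bind_cycles(load_side(test_dir)),
                                  flag_min_trials = cfg$stats$flag_min_trials)
        out <- output %||% cfg$output
        write_agreement_report(report, file.path(out, "report"))
        0L
      },
      {
        message(usage)
        2L
      })
  }
  code <- tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
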