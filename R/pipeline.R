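#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML (or list) with a `channel_map` naming
#' the `gfp`, `surface` and `cilium` channels, a `seed`, an output
#' directory, the list of `stages` to execute (`simulate`, `quantify`,
#' `timecourse`, `slopes`, `trace`) and per-stage parameter blocks.
#' Validation happens before any computation; defaults are filled in
#' explicitly so the manifest never contains an ambiguous "default".
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated `run_config` list with all defaults resolved.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  defaults <- list(
    seed = 1L,
    out_dir = "ciliarrival_out",
    stages = c("simulate", "quantify", "timecourse", "slopes"),
    channel_map = list(gfp = "gfp", surface = "surface", cilium = "cilium"),
    simulate = list(n_cells = 6L, times = c(0.5, 1), replicates = 2L,
                    stained_side = c("apical", "basolateral"),
                    profile = "population", write_stacks = FALSE,
                    kinetics = list(), variability = list()),
    quantify = list(threshold = "otsu", tilt_max = 60, min_protrusion = 1,
                    min_gfp = 0),
    slopes = list(release_time = NULL),
    trace = list(times_min = seq(0, 120, by = 10), plane_mode = TRUE))
  cfg <- modifyList(defaults, config)
  if (is.null(config$channel_map)) {
    stop("config must provide a channel_map (gfp, surface, cilium)", call. = FALSE)
  }
  cfg$channel_map <- config$channel_map  # never fill roles in silently
  missing_roles <- setdiff(c("gfp", "surface", "cilium"),
                           names(cfg$channel_map))
  if (length(missing_roles)) {
    stop("channel_map is missing roles: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(cfg$stages, c("simulate", "quantify", "timecourse",
                               "slopes", "trace"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("seed must be a single integer", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Executes the configured stages in order: `simulate` renders replicate
#' populations with the calibrated kinetics, `quantify` produces the
#' per-cell table, `timecourse` the replicate-normalized arrival curves,
#' `slopes` the per-replicate slope fits and their paired comparison,
#' and `trace` a live-imaging time lapse with its masked ciliary trace.
#' Every output file is listed in a manifest JSON together with its MD5
#' hash and the fully resolved configuration, so a run is reproducible
#' from its manifest alone.  Any stage error aborts the run with a
#' stage-named message.
#'
#' @param config Path to a YAML config or a list (see
#'   [read_run_config()]).
#' @param seed Optional seed overriding the config.
#' @param out_dir Optional output directory overriding the config.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  settings <- quant_settings(
    channel_map = unlist(cfg$channel_map),
    threshold = cfg$quantify$threshold,
    tilt_max = cfg$quantify$tilt_max,
    min_protrusion = cfg$quantify$min_protrusion,
    min_gfp = cfg$quantify$min_gfp)

  populations <- list()
  if ("simulate" %in% cfg$stages) {
    stage("simulate", {
      kin <- do.call(kinetic_params, cfg$simulate$kinetics)
      vs <- do.call(variability_spec, cfg$simulate$variability)
      prof <- population_profile(seed = cfg$seed)
      if (identical(cfg$simulate$profile, "fine")) {
        prof$geometry <- cell_geometry()
        prof$imaging <- imaging_params(seed = cfg$seed)
        prof$settings <- quant_settings()
      }
      settings <- modifyList(prof$settings, settings[c("channel_map", "threshold",
                                                        "tilt_max", "min_protrusion",
                                                        "min_gfp")])
      class(settings) <- "quant_settings"
      for (rep_i in seq_len(cfg$simulate$replicates)) {
        for (t_i in seq_along(cfg$simulate$times)) {
          t_h <- cfg$simulate$times[t_i]
          pop_seed <- (cfg$seed + 1009L * rep_i + 9173L * t_i) %% .Machine$integer.max
          pop <- generate_population(
            n_cells = cfg$simulate$n_cells, params = kin, variability = vs,
            time = t_h, seed = pop_seed,
            geometry = prof$geometry, imaging = prof$imaging,
            stained_side = unlist(cfg$simulate$stained_side),
            replicate_id = sprintf("rep%d", rep_i))
          populations[[length(populations) + 1L]] <- pop
          if (isTRUE(cfg$simulate$write_stacks)) {
            for (ci in pop) {
              p <- file.path(cfg$out_dir,
                             sprintf("%s_t%g.tif", ci$cell_id, t_h))
              write_stack(ci$stack, p)
              outputs <- c(outputs, p, sidecar_path(p))
            }
          }
        }
      }
      log$simulate <- list(kinetics = unclass(kin), variability = unclass(vs),
                            n_populations = length(populations))
    })
  }

  quant <- NULL
  if ("quantify" %in% cfg$stages) {
    stage("quantify", {
      if (!length(populations)) stop("no populations simulated")
      quant <- do.call(rbind, lapply(populations, quantify_population,
                                     settings = settings))
      qpath <- file.path(cfg$out_dir, "quantification.csv")
      write_quant_table(quant, qpath)
      outputs <- c(outputs, qpath)
      log$quantify <- list(n_cells = nrow(quant),
                            n_qc_pass = sum(quant$qc_pass),
                            threshold = settings$threshold)
    })
  }

  if ("timecourse" %in% cfg$stages) {
    stage("timecourse", {
      if (is.null(quant)) stop("no quantification table available")
      for (side in intersect(c("apical", "basolateral"), unique(quant$side))) {
        tc <- build_timecourse(quant, "surface_ratio", side = side)
        p <- file.path(cfg$out_dir, sprintf("timecourse_%s.csv", side))
        write.csv(as.data.frame(tc), p, row.names = FALSE)
        outputs <- c(outputs, p)
      }
      if (any(quant$qc_pass)) {
        tc <- build_timecourse(quant, "mcc")
        p <- file.path(cfg$out_dir, "timecourse_mcc.csv")
        write.csv(as.data.frame(tc), p, row.names = FALSE)
        outputs <- c(outputs, p)
      }
    })
  }

  if ("slopes" %in% cfg$stages) {
    stage("slopes", {
      if (is.null(quant)) stop("no quantification table available")
      # single-cell slopes are defined at one release time (default: latest)
      t_slope <- if (!is.null(cfg$slopes$release_time)) {
        cfg$slopes$release_time
      } else max(quant$release_time)
      quant <- quant[quant$release_time == t_slope, ]
      reps <- sort(unique(quant$replicate_id))
      ap <- lapply(reps, function(r)
        fit_mcc_vs_surface(quant[quant$replicate_id == r, ], "apical"))
      bl <- lapply(reps, function(r)
        fit_mcc_vs_surface(quant[quant$replicate_id == r, ], "basolateral"))
      cmp <- compare_slopes(ap, bl)
      p <- file.path(cfg$out_dir, "slope_comparison.json")
      jsonlite::write_json(
        list(apical_slopes = cmp$apical, basolateral_slopes = cmp$basolateral,
             t = cmp$t, df = cmp$df, p_value = cmp$p_value),
        p, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, p)
      log$slopes <- list(p_value = cmp$p_value)
    })
  }

  if ("trace" %in% cfg$stages) {
    stage("trace", {
      kin <- do.call(kinetic_params, cfg$simulate$kinetics)
      prof <- population_profile(seed = cfg$seed)
      tl <- simulate_timelapse(times_min = cfg$trace$times_min, params = kin,
                               geometry = prof$geometry,
                               imaging = prof$imaging, seed = cfg$seed,
                               plane_mode = isTRUE(cfg$trace$plane_mode))
      tr <- trace_ciliary_intensity(tl$frames, tl$background_mask,
                                    times = tl$times_min, settings = settings)
      p <- file.path(cfg$out_dir, "ciliary_trace.csv")
      write.csv(as.data.frame(tr), p, row.names = FALSE)
      outputs <- c(outputs, p)
    })
  }

  manifest <- list(
    config = unclass(cfg),
    log = log,
    outputs = lapply(unique(outputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
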