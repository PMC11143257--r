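# Config-driven orchestration of the analysis battery over one or more
# trajectory sets, producing a deterministic report directory.

#' Default analysis parameters
#'
#' Every study parameter surfaces here as a named, defaulted key: contact
#' cutoff 5 A, difference threshold 0.25, correlation cutoff 0.8, basin depth
#' 4 kJ/mol (one contour step), ABMD k = 5000 kJ/mol/nm^2 with target 0.5 nm,
#' hills h0 = 1.2 kJ/mol / sigma = 0.25 rad / bias factor 8, SF centre at
#' +7 A, crossing planes at 1/13 A, cylinder radius 8 A.
#' @export
default_parameters <- function() {
  list(
    sf_offset = 7, lower = 1, upper = 13, radius = 8,
    z_min = -4, z_max = 18, z_bin = 1,
    contact_cutoff = 5, min_seq_sep = 2, diff_threshold = 0.25,
    correlation_cutoff = 0.8, metapath_frac = 0.2,
    basin_min_depth = 4, abmd_k = 5000, abmd_target = 0.5,
    hill_height = 1.2, hill_sigma = 0.25 * 180 / pi, bias_factor = 8
  )
}

#' Validate an analysis configuration
#'
#' @param config list (or YAML file path) with elements `states` (named list
#'   of `topology`, `trajectory`, `voltage_mV`), optional `selections`
#'   (`sf`, `ions` expressions), optional `parameters` overriding
#'   [default_parameters()], optional `hills` (path), and `output_dir`.
#' @return normalized config list; errors before any computation when a
#'   referenced file is missing or a parameter is unknown.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$states) || !length(config$states)) {
    stop("config must define at least one state")
  }
  if (is.null(config$output_dir)) stop("config must define output_dir")
  for (nm in names(config$states)) {
    st <- config$states[[nm]]
    for (field in c("topology", "trajectory")) {
      if (is.null(st[[field]])) {
        stop("state '", nm, "' lacks required field '", field, "'")
      }
      if (!file.exists(st[[field]])) {
        stop("state '", nm, "': file not found: ", st[[field]])
      }
    }
    if (is.null(st$voltage_mV)) {
      stop("state '", nm, "' lacks required field 'voltage_mV'")
    }
  }
  if (!is.null(config$hills) && !file.exists(config$hills)) {
    stop("hills file not found: ", config$hills)
  }
  pars <- default_parameters()
  extra <- setdiff(names(config$parameters), names(pars))
  if (length(extra)) stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  pars[names(config$parameters)] <- config$parameters
  config$parameters <- pars
  if (is.null(config$selections$sf)) config$selections$sf <- "backbone"
  if (is.null(config$selections$ions)) config$selections$ions <- "resname K"
  config
}

#' Run the full analysis battery
#'
#' Per state: permeation events and conductance, 1D occupancy and site
#' table, residue contact probabilities. Across the first two states: the
#' contact difference map. When a hills log is configured, the FES and its
#' basins. All module outputs are written as CSV/JSON under `output_dir`;
#' the cross-state summary lands in `summary.json` and a file index in
#' `index.json`. The report is a pure function of (config, input files):
#' no timestamps or hostnames are written.
#'
#' @param config see [validate_config()].
#' @return (invisibly) list with `summary`, `files`, `failures`; a module
#'   failure yields a partial report, a `failures` manifest and a "partial"
#'   status recorded in `index.json`.
#' @export
run_analysis <- function(config) {
  config <- validate_config(config)
  pars <- config$parameters
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(...) file.path(config$output_dir, ...)
  files <- character(0)
  failures <- list()
  summary <- list(states = list())

  # expr is forced inside tryCatch but evaluates in this function's frame,
  # so plain `<-` assignments in the step bodies land here.
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      failures[[label]] <<- conditionMessage(e)
      NULL
    })
  }

  z_edges <- seq(pars$z_min, pars$z_max, by = pars$z_bin)
  for (nm in names(config$states)) {
    st <- config$states[[nm]]
    st_summary <- list(voltage_mV = st$voltage_mV)
    traj <- step(paste0(nm, ":load"), {
      top <- load_system(st$topology)
      read_trajectory(st$trajectory, system = top$system)
    })
    if (is.null(traj)) {
      summary$states[[nm]] <- st_summary
      next
    }
    sf_sel <- select_atoms(traj$system, config$selections$sf)
    ion_sel <- suppressWarnings(select_atoms(traj$system,
                                             config$selections$ions))
    axis <- compute_pore_axis(traj, sf_sel, offset = pars$sf_offset)

    step(paste0(nm, ":permeation"), {
      events <- detect_permeation_events(traj, ion_sel, axis,
                                         lower = pars$lower,
                                         upper = pars$upper,
                                         radius = pars$radius)
      utils::write.csv(events, out_file(paste0("events_", nm, ".csv")),
                       row.names = FALSE)
      files <- c(files, paste0("events_", nm, ".csv"))
      dt <- if (n_frames(traj) > 1) stats::median(diff(traj$times)) else 1
      sm <- permeation_summary(events, n_frames(traj) * dt, st$voltage_mV)
      st_summary$N <- sm$N
      st_summary$t_ns <- sm$t
      st_summary$conductance_pS <- sm$gamma
    })

    step(paste0(nm, ":occupancy"), {
      grid <- occupancy_profile(traj, ion_sel, axis, z_edges,
                                radius = pars$radius)
      utils::write.csv(grid, out_file(paste0("occupancy_1d_", nm, ".csv")),
                       row.names = FALSE)
      sites <- assign_sites(grid, default_sites(pars$sf_offset))
      utils::write.csv(sites, out_file(paste0("sites_", nm, ".csv")),
                       row.names = FALSE)
      files <- c(files, paste0("occupancy_1d_", nm, ".csv"),
                 paste0("sites_", nm, ".csv"))
      st_summary$site_fraction <- as.list(stats::setNames(sites$fraction,
                                                          sites$site))
    })

    step(paste0(nm, ":contacts"), {
      cp <- contact_probability(traj, cutoff = pars$contact_cutoff,
                                min_seq_sep = pars$min_seq_sep)
      utils::write.csv(cp, out_file(paste0("contacts_", nm, ".csv")),
                       row.names = FALSE)
      files <- c(files, paste0("contacts_", nm, ".csv"))
    })
    summary$states[[nm]] <- st_summary
  }

  state_names <- names(config$states)
  if (length(state_names) >= 2) {
    step("difference_map", {
      up_file <- out_file(paste0("contacts_", state_names[1], ".csv"))
      down_file <- out_file(paste0("contacts_", state_names[2], ".csv"))
      if (file.exists(up_file) && file.exists(down_file)) {
        up <- utils::read.csv(up_file, stringsAsFactors = FALSE)
        down <- utils::read.csv(down_file, stringsAsFactors = FALSE)
        dm <- difference_map(up, down, threshold = pars$diff_threshold)
        utils::write.csv(dm, out_file("diffmap.csv"), row.names = FALSE)
        files <- c(files, "diffmap.csv")
        summary$difference_map <- list(
          threshold = pars$diff_threshold,
          n_total = attr(dm, "n_total"),
          n_inter = attr(dm, "n_inter"),
          n_intra = attr(dm, "n_intra")
        )
      }
    })
  }

  if (!is.null(config$hills)) {
    step("fes", {
      hills <- read_hills(config$hills)
      fes <- reconstruct_fes(hills)
      fes_df <- data.frame(cv1 = rep(fes$cv1, length(fes$cv2)),
                           cv2 = rep(fes$cv2, each = length(fes$cv1)),
                           F = as.vector(fes$F))
      utils::write.csv(fes_df, out_file("fes.csv"), row.names = FALSE)
      basins <- find_basins(fes, min_depth = pars$basin_min_depth)
      jsonlite::write_json(basins, out_file("basins.json"), digits = NA)
      files <- c(files, "fes.csv", "basins.json")
      summary$fes <- list(n_basins = nrow(basins))
    })
  }

  jsonlite::write_json(summary, out_file("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  index <- list(files = sort(unique(c(files, "summary.json"))),
                failures = failures,
                status = if (length(failures)) "partial" else "ok")
  jsonlite::write_json(index, out_file("index.json"), auto_unbox = TRUE)
  invisible(list(summary = summary, files = index$files, failures = failures))
}
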