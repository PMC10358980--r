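# Blinded administrator/user evaluation workflow: simulation library
# management, surface-point export, electrode and noise ingestion, blinded
# electrogram generation, prediction ingestion and report generation.
#
# The administrator holds the silver standard (Vm, node AcTs, event
# locations); the user only ever receives surface points and noisy
# electrograms, and returns predicted activation times and patterns.

#' Build a library of precomputed simulations
#'
#' Each config runs the simulator and activation analysis and persists one
#' library entry: the mesh (VTK), the Vm movie, per-node activation times,
#' and the ground-truth event list (paced/focal stimulation sites and times;
#' reentry source locations and chirality from phase-singularity density
#' clustering when `analyze_reentry` is set).
#'
#' @param configs list of configs; each a list with `id`, `geom`
#'   (a [tissue_geometry()]), `params` ([tissue_params()]), `protocol`
#'   (a `stimulus_protocol`), `cell_model`, `seed`, and optionally
#'   `analyze_reentry` (logical) and `reentry_window` (ms, default
#'   `c(1000, 2000)` clipped to the record).
#' @param dir library directory (created if needed).
#' @return data.frame index of entries with their validity status.
#' @export
build_library <- function(configs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- data.frame(id = character(0), valid = logical(0),
                      n_events = integer(0), stringsAsFactors = FALSE)
  for (cfg in configs) {
    status <- tryCatch({
      entry <- build_library_entry(cfg)
      save_library_entry(entry, file.path(dir, cfg$id))
      c(TRUE, length(entry$truth$type))
    }, error = function(e) {
      warning("library entry '", cfg$id, "' failed: ", conditionMessage(e))
      c(FALSE, 0L)
    })
    index <- rbind(index, data.frame(id = cfg$id, valid = as.logical(status[1]),
                                     n_events = as.integer(status[2]),
                                     stringsAsFactors = FALSE))
  }
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  index
}

build_library_entry <- function(cfg) {
  record <- run_monodomain(cfg$geom, cfg$params, cfg$protocol,
                           cell_model = cfg$cell_model, seed = cfg$seed)
  acts <- vm_activation_map(record)
  truth <- truth_from_protocol(record$protocol)
  if (isTRUE(cfg$analyze_reentry)) {
    win <- cfg$reentry_window
    if (is.null(win)) win <- c(1000, 2000)
    win[2] <- min(win[2], max(record$times))
    truth <- rbind(truth, reentry_truth(record, acts, win, seed = cfg$seed))
  }
  list(id = cfg$id, record = record, acts = acts, truth = truth,
       meta = list(cell_model = cfg$cell_model, seed = cfg$seed))
}

# P/F events straight from the stimulus protocol metadata
truth_from_protocol <- function(protocol) {
  rows <- lapply(seq_along(protocol$events), function(k) {
    ev <- protocol$events[[k]]
    lab <- ev$label
    type <- if (identical(lab, "S1")) "P"
            else if (grepl("^F", lab)) lab
            else if (grepl("^focal", lab)) "F"
            else NA_character_
    if (is.na(type)) return(NULL)  # S2 induces reentry; not itself a pattern
    data.frame(type = type, beat = if (!is.null(ev$beat)) ev$beat else 1L,
               x = ev$center[1], y = ev$center[2], z = ev$center[3],
               ref_time = ev$onset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(type = character(0), beat = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), ref_time = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

# R+/R- events: PS density clustering for locations, beat times from the
# Vm AcTs of the node nearest each source within the analysis window.
reentry_truth <- function(record, acts, window, seed = 1L) {
  phase <- compute_phase(record)
  series <- ps_series(phase, record$geometry, window)
  occ <- ps_occurrences(series, record$geometry)
  sources <- cluster_reentry_sources(occ, k = 2, seed = seed)
  rows <- lapply(names(sources), function(nm) {
    src <- sources[[nm]]
    node <- nearest_surface_node(record$geometry, matrix(src$location, 1))
    beats <- acts[[as.character(node)]]
    beats <- beats[beats >= window[1] & beats <= window[2]]
    if (length(beats) == 0) return(NULL)
    data.frame(type = src$chirality, beat = seq_along(beats),
               x = src$location[1], y = src$location[2],
               z = src$location[3], ref_time = beats,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

save_library_entry <- function(entry, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_mesh_vtk(entry$record$geometry, file.path(path, "mesh.vtk"))
  saveRDS(entry$record, file.path(path, "vm.rds"))
  act_df <- do.call(rbind, lapply(names(entry$acts), function(nd) {
    a <- entry$acts[[nd]]
    if (length(a) == 0) return(NULL)
    data.frame(site_id = as.integer(nd), act_ms = a)
  }))
  if (is.null(act_df)) act_df <- data.frame(site_id = integer(0),
                                            act_ms = numeric(0))
  utils::write.csv(act_df, file.path(path, "acts.csv"), row.names = FALSE)
  jsonlite::write_json(entry$truth, file.path(path, "truth.json"),
                       digits = NA)
  jsonlite::write_json(entry$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load a library entry
#' @param dir library directory.
#' @param id entry identifier.
#' @return The entry list (`record`, `acts`, `truth`, `meta`).
#' @export
load_library_entry <- function(dir, id) {
  path <- file.path(dir, id)
  record <- readRDS(file.path(path, "vm.rds"))
  act_df <- utils::read.csv(file.path(path, "acts.csv"))
  acts <- split(act_df$act_ms, act_df$site_id)
  # nodes with no activation still need (empty) entries
  all_nodes <- as.character(seq_len(nrow(record$geometry$nodes)))
  acts <- c(acts, setNames(rep(list(numeric(0)),
                               sum(!all_nodes %in% names(acts))),
                           all_nodes[!all_nodes %in% names(acts)]))
  truth <- as.data.frame(jsonlite::read_json(file.path(path, "truth.json"),
                                             simplifyVector = TRUE))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  list(id = id, record = record, acts = acts, truth = truth, meta = meta)
}

#' Export the surface points of a library entry (blinded)
#'
#' Writes only labeled surface-node coordinates (`id,x,y,z` in cm): no Vm,
#' activation or event data leaves the administrator side.
#'
#' @param entry a library entry.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_surface_points <- function(entry, path) {
  geom <- entry$record$geometry
  sn <- geom$surface_nodes
  df <- data.frame(id = sn, x = geom$nodes[sn, 1], y = geom$nodes[sn, 2],
                   z = geom$nodes[sn, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --------------------------------------------------------------------------
# Evaluation session
# --------------------------------------------------------------------------

#' Start a blinded evaluation session
#'
#' All randomness in the session (electrogram noise) flows from the recorded
#' master seed, making every issued export reproducible.
#'
#' @param entry a library entry (from [load_library_entry()] or an in-memory
#'   build).
#' @param master_seed integer master seed.
#' @return An `evaluation_session`.
#' @export
new_session <- function(entry, master_seed = 1L) {
  structure(list(entry = entry, master_seed = as.integer(master_seed),
                 array = NULL, noise_levels = NULL, issued = NULL,
                 predictions = NULL),
            class = "evaluation_session")
}

#' Register the user's electrode locations
#' @param session an `evaluation_session`.
#' @param array an [electrode_array()] (e.g. read from the exchange table
#'   with [read_electrode_table()]).
#' @return The updated session.
#' @export
register_electrodes <- function(session, array) {
  if (is.null(array$nearest_node)) {
    geom <- session$entry$record$geometry
    nn <- nearest_surface_node(geom, array$positions)
    array$nearest_node <- nn
    array$contact_distance <-
      sqrt(rowSums((array$positions - geom$nodes[nn, , drop = FALSE])^2))
  }
  session$array <- array
  session
}

#' Register the user's declared per-electrode noise levels
#' @param session an `evaluation_session`.
#' @param levels noise levels in mV/ms, scalar or one per electrode.
#' @return The updated session.
#' @export
declare_noise <- function(session, levels) {
  if (is.null(session$array))
    stop("protocol order: register electrodes before declaring noise")
  ne <- length(session$array$labels)
  if (length(levels) == 1) levels <- rep(levels, ne)
  if (length(levels) != ne) stop("one noise level per electrode required")
  if (any(levels < 0)) stop("noise levels must be >= 0")
  session$noise_levels <- levels
  session
}

#' Issue blinded electrograms to the user
#'
#' Requires electrode locations and noise declarations (blinding order);
#' computes the virtual electrograms, adds the declared noise with a seed
#' derived from the master seed (stored session-side only), and optionally
#' writes the blinded exchange table (time + signals, nothing else).
#'
#' @param session an `evaluation_session`.
#' @param path optional path for the delimited-text export.
#' @param params an [electrogram_params()].
#' @return The updated session; the issued set is in `session$issued`.
#' @export
issue_blinded_electrograms <- function(session, path = NULL,
                                       params = electrogram_params()) {
  if (is.null(session$array) || is.null(session$noise_levels))
    stop("protocol order: electrode table and noise declarations must be registered before electrograms are issued")
  egms <- compute_electrograms(session$entry$record, session$array, params)
  noise_seed <- (session$master_seed * 7919L + 17L) %% .Machine$integer.max
  egms <- add_noise(egms, session$noise_levels, seed = noise_seed)
  session$issued <- list(egms = egms, seed = noise_seed)
  if (!is.null(path)) write_electrogram_table(egms, path)
  session
}

#' Ingest the user's predictions
#'
#' @param session an `evaluation_session`.
#' @param act_predictions data.frame `site_id`, `act_ms`: predicted
#'   activation times at surface sites (repeated rows per site).  Sites must
#'   belong to the issued surface-point set.
#' @param pattern_predictions data.frame `type`, `beat`, `site_id`,
#'   `time_ms`: predicted activation patterns at surface sites.
#' @return The updated session.
#' @export
ingest_predictions <- function(session, act_predictions = NULL,
                               pattern_predictions = NULL) {
  surf <- session$entry$record$geometry$surface_nodes
  if (!is.null(act_predictions)) {
    bad <- setdiff(unique(act_predictions$site_id), surf)
    if (length(bad) > 0)
      stop("prediction sites not in the issued surface-point set: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.null(pattern_predictions)) {
    bad <- setdiff(unique(pattern_predictions$site_id), surf)
    if (length(bad) > 0)
      stop("pattern sites not in the issued surface-point set: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  session$predictions <- list(acts = act_predictions,
                              patterns = pattern_predictions)
  session
}

#' Score the session: compare predictions against the silver standard
#'
#' @param session an `evaluation_session` with ingested predictions.
#' @param tol activation-time matching tolerance, ms.
#' @param tol_values tolerances for the AcTPM sweep.
#' @param time_window,dist_window pattern matching windows (ms, cm).
#' @param path optional path; when given the report is written as JSON.
#' @return An `evaluation_report` list: `act` ([compare_act()] output),
#'   `sweep` ([tolerance_sweep()]), `patterns` ([compare_patterns()] output
#'   or NULL), and `provenance` (seeds and parameters).
#' @export
evaluate_session <- function(session, tol = 2, tol_values = c(0, 1, 2, 5, 10),
                             time_window = 100, dist_window = 1,
                             path = NULL) {
  if (is.null(session$predictions)) stop("no predictions ingested")
  geom <- session$entry$record$geometry
  act_rep <- NULL; sweep <- NULL; acp_rep <- NULL
  pred <- session$predictions
  if (!is.null(pred$acts)) {
    sites <- sort(unique(pred$acts$site_id))
    egm_acts <- lapply(sites, function(s)
      sort(pred$acts$act_ms[pred$acts$site_id == s]))
    names(egm_acts) <- as.character(sites)
    act_rep <- compare_act(egm_acts, session$entry$acts, sites, tol)
    sweep <- tolerance_sweep(egm_acts, session$entry$acts, sites, tol_values)
  }
  if (!is.null(pred$patterns)) {
    pp <- pred$patterns
    det <- data.frame(electrode = as.character(pp$site_id),
                      time = pp$time_ms, type = pp$type,
                      stringsAsFactors = FALSE)
    acp_rep <- compare_patterns(det, session$entry$truth,
                                time_window = time_window,
                                dist_window = dist_window,
                                positions = geom$nodes[pp$site_id, ,
                                                       drop = FALSE])
  }
  report <- list(
    act = act_rep, sweep = sweep, patterns = acp_rep,
    provenance = list(entry_id = session$entry$id,
                      master_seed = session$master_seed,
                      noise_seed = if (!is.null(session$issued))
                        session$issued$seed else NULL,
                      noise_levels = session$noise_levels,
                      tol = tol, time_window = time_window,
                      dist_window = dist_window))
  class(report) <- "evaluation_report"
  if (!is.null(path)) write_report_json(report, path)
  report
}

write_report_json <- function(report, path) {
  out <- list(
    act = if (!is.null(report$act)) list(
      fC = report$act$fC, fS = report$act$fS, actpm = report$act$actpm,
      rms = report$act$rms, rms_sd = report$act$rms_sd, tol = report$act$tol,
      per_electrode = report$act$per_electrode) else NULL,
    sweep = report$sweep,
    patterns = if (!is.null(report$patterns))
      list(per_type = report$patterns$per_type) else NULL,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
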