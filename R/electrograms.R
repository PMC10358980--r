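# Virtual unipolar electrograms by the volume-conductor forward model.
#
# phi_e(x') = integral over the myocardium of -sigma_e grad(Vm).grad(1/r) dV
#
# With linear elements grad(Vm) is constant per element, so the map from the
# nodal Vm vector to the electrode potentials is a fixed matrix assembled
# once per (geometry, array) pair; every saved frame is then a single
# matrix-vector product.

#' Electrogram forward-model parameters
#'
#' @param sigma_e extracellular conductivity, mS/cm (default 7).
#' @param quadrature_order Gauss order per element: 1 (centroid), 2 (3-point,
#'   default) or 6 (12-point refined rule, used as the convergence oracle).
#' @return An `electrogram_params` list.
#' @export
electrogram_params <- function(sigma_e = 7, quadrature_order = 2) {
  stopifnot(sigma_e > 0, quadrature_order >= 1)
  structure(list(sigma_e = sigma_e,
                 quadrature_order = as.integer(quadrature_order)),
            class = "electrogram_params")
}

#' Assemble the electrogram transfer matrix
#'
#' @param geom a [tissue_geometry()] (its `thickness` supplies the volume
#'   element for thin-surface fixtures).
#' @param array an [electrode_array()]; electrodes must not coincide with any
#'   quadrature point.
#' @param params an [electrogram_params()].
#' @return A dense matrix (electrodes x nodes) mapping a Vm frame (mV) to
#'   extracellular potentials (mV).
#' @export
egm_transfer_matrix <- function(geom, array, params = electrogram_params()) {
  egm_transfer_cpp(geom$nodes, geom$elements, array$positions,
                   params$sigma_e, geom$thickness, params$quadrature_order,
                   array$labels)
}

#' Compute virtual unipolar electrograms
#'
#' @param record a `vm_record` from [run_monodomain()].
#' @param array an [electrode_array()].
#' @param params an [electrogram_params()].
#' @return An `electrogram_set`: `labels`, `times` (ms), `phi_e` (electrodes
#'   x times, mV), and noise metadata (empty until [add_noise()]).
#' @export
compute_electrograms <- function(record, array,
                                 params = electrogram_params()) {
  T <- egm_transfer_matrix(record$geometry, array, params)
  phi <- T %*% record$vm
  structure(list(labels = array$labels, times = record$times,
                 phi_e = unname(as.matrix(phi)), params = params,
                 noise_level = NULL, noise_seed = NULL),
            class = "electrogram_set")
}

#' @exportS3Method base::print
print.electrogram_set <- function(x, ...) {
  cat(sprintf("<electrogram_set> %d electrodes x %d frames (%g..%g ms)%s\n",
              nrow(x$phi_e), ncol(x$phi_e), x$times[1],
              x$times[length(x$times)],
              if (is.null(x$noise_level)) "" else ", noise added"))
  invisible(x)
}

#' Add uniform measurement noise to electrograms
#'
#' Independent uniform samples on `[-level * dt, +level * dt]` mV are added
#' to every sample, where `level` is the declared per-electrode noise level
#' in mV/ms and `dt` the sampling interval (1 ms at 1 kHz, so the bound
#' equals the level numerically).  Deterministic given `seed`.
#'
#' @param egms an `electrogram_set`.
#' @param level noise level(s) in mV/ms: scalar or one value per electrode.
#' @param seed integer seed; recorded in the returned object.
#' @return The `electrogram_set` with noise added and provenance recorded.
#' @export
add_noise <- function(egms, level, seed) {
  ne <- nrow(egms$phi_e)
  if (length(level) == 1) level <- rep(level, ne)
  if (length(level) != ne) stop("one noise level per electrode required")
  if (any(level < 0)) stop("noise levels must be >= 0")
  dt <- if (length(egms$times) > 1) egms$times[2] - egms$times[1] else 1
  nt <- ncol(egms$phi_e)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  noise <- matrix(runif(ne * nt, -1, 1), ne, nt) * (level * dt)
  egms$phi_e <- egms$phi_e + noise
  egms$noise_level <- level
  egms$noise_seed <- as.integer(seed)
  egms
}

#' Write electrograms as a delimited-text table
#'
#' One `time_ms` column followed by one column per electrode label; the
#' blinded exchange format handed to the mapping-system user.
#'
#' @param egms an `electrogram_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_electrogram_table <- function(egms, path) {
  df <- data.frame(time_ms = egms$times, t(egms$phi_e))
  names(df) <- c("time_ms", egms$labels)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read electrograms written by [write_electrogram_table()]
#' @param path CSV file with `time_ms` then one column per electrode.
#' @return An `electrogram_set`.
#' @export
read_electrogram_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "time_ms")
  structure(list(labels = names(df)[-1], times = df$time_ms,
                 phi_e = t(as.matrix(df[, -1, drop = FALSE])),
                 params = NULL, noise_level = NULL, noise_seed = NULL),
            class = "electrogram_set")
}
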