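# Monodomain reaction-diffusion solver on triangulated tissue.
#
#   chi*Cm dVm/dt + Iion + Istim - div(sigma grad Vm) = 0
#
# Linear finite elements with mass lumping; diffusion advanced implicitly
# (backward Euler, sparse Cholesky factorization reused across steps);
# ionic model advanced per node at the same dt (Rush-Larsen gates).
# No-flux boundaries everywhere.

# --------------------------------------------------------------------------
# Cell-model registry
# --------------------------------------------------------------------------

.cell_models <- new.env(parent = emptyenv())

#' Register a cell model
#'
#' Cell models are pluggable.  A model provides an initializer returning a
#' state matrix (state variables x nodes), a step function advancing `vm` and
#' the state in place over one PDE step, and its resting potential.
#'
#' @param name model identifier.
#' @param init `function(n)` returning the state matrix for n nodes.
#' @param step `function(vm, state, istim, dt_ms, nsub)` advancing in place.
#' @param vrest resting membrane potential (mV).
#' @param nsub reaction substeps per PDE step.
#' @return `name`, invisibly.
#' @export
register_cell_model <- function(name, init, step, vrest, nsub = 1L) {
  assign(name, list(init = init, step = step, vrest = vrest,
                    nsub = as.integer(nsub)), envir = .cell_models)
  invisible(name)
}

#' Look up a registered cell model
#' @param name model identifier (`"nygren"` or `"alievpanfilov"` built in).
#' @return The model definition list.
#' @export
get_cell_model <- function(name) {
  if (!exists(name, envir = .cell_models))
    stop("unknown cell model: ", name, " (registered: ",
         paste(ls(.cell_models), collapse = ", "), ")")
  get(name, envir = .cell_models)
}

register_builtin_models <- function() {
  register_cell_model("nygren",
    init = nygren_init_cpp, step = nygren_step_cpp,
    vrest = nygren_vrest_cpp(), nsub = 1L)
  register_cell_model("alievpanfilov",
    init = ap_init_cpp,
    step = function(vm, state, istim, dt_ms, nsub)
      ap_step_cpp(vm, state, istim, dt_ms, nsub, ap_default_pars()),
    vrest = ap_vrest_cpp(), nsub = 1L)
}

#' Default Aliev-Panfilov parameters
#'
#' `(k, a, eps0, mu1, mu2, tscale)`: the classic excitability constants with
#' a time scale in ms per dimensionless unit.  The default recovery settings
#' are chosen to give a compact activation wavelength (a few cm) so that
#' reentry fits on desk-scale sheets.
#' @return Named numeric vector of the six parameters.
#' @export
ap_default_pars <- function() {
  c(k = 8, a = 0.15, eps0 = 0.01, mu1 = 0.2, mu2 = 0.3, tscale = 12.9)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_models()
}

# --------------------------------------------------------------------------
# Parameters and protocols
# --------------------------------------------------------------------------

#' Tissue and solver parameters
#'
#' @param chi surface-to-volume ratio, 1/cm.
#' @param Cm membrane capacitance, uF/cm^2.
#' @param sigma isotropic conductivity, mS/cm.  The default 4.66 mS/cm
#'   (0.466 S/m) calibrates the plane-wave conduction velocity of the Nygren
#'   model to the human atrial value of 55 cm/s; see the methods vignette
#'   for the unit normalization.
#' @param dt solver time step, ms.
#' @param save_interval sampling interval of the saved Vm movie, ms (1 ms =
#'   1 kHz sampling); must be an integer multiple of `dt`.
#' @param duration total simulated time, ms.
#' @return A `tissue_params` list.
#' @export
tissue_params <- function(chi = 1400, Cm = 1.0, sigma = 4.66, dt = 0.1,
                          save_interval = 1, duration = 2000) {
  stopifnot(chi > 0, Cm > 0, sigma > 0, dt > 0, save_interval >= dt,
            duration > 0)
  ratio <- save_interval / dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("save_interval must be an integer multiple of dt")
  structure(list(chi = chi, Cm = Cm, sigma = sigma, dt = dt,
                 save_interval = save_interval, duration = duration),
            class = "tissue_params")
}

#' Construct a stimulus protocol from explicit events
#'
#' Each event is a list with `label`, `onset` (ms), `duration` (ms),
#' `amplitude` (mV/ms added to dVm/dt over the stimulated nodes), and either
#' `center` + `radius` (cm, nodes selected geometrically at run time) or an
#' explicit integer `nodes` vector.
#'
#' @param events list of event lists.
#' @return A `stimulus_protocol`.
#' @export
stimulus_protocol <- function(events) {
  for (ev in events) {
    stopifnot(!is.null(ev$label), ev$onset >= 0, ev$duration > 0)
    if (is.null(ev$nodes) && (is.null(ev$center) || is.null(ev$radius)))
      stop("event needs either nodes or center+radius")
  }
  structure(list(events = events), class = "stimulus_protocol")
}

#' S1-S2 cross-gradient pacing protocol
#'
#' A small S1 pacing site followed, after `s2_delay` ms, by a large S2 site;
#' applied across the repolarization gradient of the S1 beat this initiates a
#' pair of counter-rotating reentrant waves (figure-of-eight).
#'
#' @param geom a [tissue_geometry()] (node selection is validated eagerly).
#' @param s1_center,s2_center stimulus centers, length-3 numeric, cm.
#' @param s1_radius,s2_radius stimulus radii, cm (defaults 0.5 and 1.0 cm).
#' @param s2_delay S2 onset relative to S1 onset, ms (default 390 ms).
#' @param amplitude stimulus strength, mV/ms (suprathreshold).
#' @param duration stimulus duration, ms.
#' @return A `stimulus_protocol` with two events labeled S1 and S2.
#' @export
protocol_s1s2 <- function(geom, s1_center, s1_radius = 0.5,
                          s2_center, s2_radius = 1.0, s2_delay = 390,
                          amplitude = 40, duration = 2) {
  sel1 <- select_nodes(geom, s1_center, s1_radius)
  sel2 <- select_nodes(geom, s2_center, s2_radius)
  if (length(sel1) == 0) stop("S1 selects no nodes")
  if (length(sel2) == 0) stop("S2 selects no nodes")
  stimulus_protocol(list(
    list(label = "S1", onset = 0, duration = duration,
         amplitude = amplitude, center = s1_center, radius = s1_radius,
         nodes = sel1),
    list(label = "S2", onset = s2_delay, duration = duration,
         amplitude = amplitude, center = s2_center, radius = s2_radius,
         nodes = sel2)))
}

#' Focal-source pacing protocol
#'
#' One event per onset per source; used to replicate reentrant activity as
#' focal beats paced at the reentry source locations with the measured cycle
#' lengths.
#'
#' @param sources list of lists with `center` (cm), `radius` (cm), `onsets`
#'   (ms, non-decreasing) and optionally `label` (default `focal-k`).
#' @param amplitude stimulus strength, mV/ms.
#' @param duration stimulus duration, ms.
#' @return A `stimulus_protocol`.
#' @export
protocol_focal <- function(sources, amplitude = 40, duration = 2) {
  events <- list()
  for (k in seq_along(sources)) {
    src <- sources[[k]]
    if (length(src$onsets) == 0) stop("source ", k, " has no onsets")
    if (is.unsorted(src$onsets)) stop("onsets must be non-decreasing")
    lab <- if (!is.null(src$label)) src$label else paste0("focal-", k)
    for (i in seq_along(src$onsets)) {
      events[[length(events) + 1L]] <-
        list(label = lab, onset = src$onsets[i], duration = duration,
             amplitude = amplitude, center = src$center, radius = src$radius,
             beat = i)
    }
  }
  stimulus_protocol(events)
}

select_nodes <- function(geom, center, radius) {
  d2 <- (geom$nodes[, 1] - center[1])^2 + (geom$nodes[, 2] - center[2])^2 +
    (geom$nodes[, 3] - center[3])^2
  which(d2 <= radius^2)
}

# --------------------------------------------------------------------------
# FEM assembly
# --------------------------------------------------------------------------

# Stiffness (sigma-scaled) and lumped mass for linear triangles.
assemble_fem <- function(geom, sigma) {
  el <- geom$elements
  p1 <- geom$nodes[el[, 1], , drop = FALSE]
  p2 <- geom$nodes[el[, 2], , drop = FALSE]
  p3 <- geom$nodes[el[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  two_area <- sqrt(nx^2 + ny^2 + nz^2)
  area <- two_area / 2
  nrm <- cbind(nx, ny, nz) / two_area
  # shape-function gradients g_k = n x e_k / (2A), e_k the opposite edge
  grads <- vector("list", 3)
  edges <- list(p3 - p2, p1 - p3, p2 - p1)
  for (k in 1:3) {
    e <- edges[[k]]
    gx <- nrm[, 2] * e[, 3] - nrm[, 3] * e[, 2]
    gy <- nrm[, 3] * e[, 1] - nrm[, 1] * e[, 3]
    gz <- nrm[, 1] * e[, 2] - nrm[, 2] * e[, 1]
    grads[[k]] <- cbind(gx, gy, gz) / two_area
  }
  n <- nrow(geom$nodes)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (a in 1:3) {
    for (b in 1:3) {
      ii <- c(ii, el[, a]); jj <- c(jj, el[, b])
      vv <- c(vv, sigma * area * rowSums(grads[[a]] * grads[[b]]))
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  mass <- numeric(n)
  for (a in 1:3) {
    add <- tapply(area / 3, el[, a], sum)
    idx <- as.integer(names(add))
    mass[idx] <- mass[idx] + as.numeric(add)
  }
  list(K = K, mass = mass)
}

# --------------------------------------------------------------------------
# Solver
# --------------------------------------------------------------------------

#' Solve the monodomain equation
#'
#' Operator splitting per time step: the ionic model is advanced at `dt`
#' (reaction step, Rush-Larsen gates), then the diffusion operator is applied
#' implicitly (backward Euler) via a pre-factorized sparse SPD system.  Vm is
#' stored every `save_interval` ms.
#'
#' @param geom a [tissue_geometry()].
#' @param params a [tissue_params()].
#' @param protocol a `stimulus_protocol`.
#' @param cell_model registered model name (default `"nygren"`).
#' @param seed integer recorded for provenance (the solver itself is
#'   deterministic).
#' @param progress print progress every 200 ms of simulated time.
#' @return A `vm_record`: `times` (ms), `vm` (nodes x times, mV), plus
#'   geometry/protocol/parameter references.
#' @export
run_monodomain <- function(geom, params = tissue_params(), protocol,
                           cell_model = "nygren", seed = 1L,
                           progress = FALSE) {
  model <- get_cell_model(cell_model)
  n <- nrow(geom$nodes)
  # resolve stimulus node sets
  events <- lapply(protocol$events, function(ev) {
    if (is.null(ev$nodes)) ev$nodes <- select_nodes(geom, ev$center, ev$radius)
    if (length(ev$nodes) == 0)
      stop("stimulus event '", ev$label, "' selects no nodes")
    ev
  })
  fem <- assemble_fem(geom, params$sigma)
  scale <- params$chi * params$Cm / params$dt
  A <- Matrix::Diagonal(n, x = scale * fem$mass) + fem$K
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  rhs_scale <- scale * fem$mass

  vm <- rep(model$vrest, n)
  state <- model$init(n)
  nsteps <- round(params$duration / params$dt)
  save_every <- round(params$save_interval / params$dt)
  nsave <- floor(nsteps / save_every) + 1L
  out <- matrix(NA_real_, n, nsave)
  times <- numeric(nsave)
  out[, 1] <- vm; times[1] <- 0
  isave <- 1L
  istim <- numeric(n)

  for (step in seq_len(nsteps)) {
    t0 <- (step - 1) * params$dt
    istim[] <- 0
    for (ev in events) {
      if (t0 >= ev$onset && t0 < ev$onset + ev$duration)
        istim[ev$nodes] <- istim[ev$nodes] + ev$amplitude
    }
    model$step(vm, state, istim, params$dt, model$nsub)  # reaction, in place
    vm <- as.numeric(Matrix::solve(fac, rhs_scale * vm)) # implicit diffusion
    if (!all(is.finite(vm)))
      stop("solver divergence: non-finite Vm at t = ", t0 + params$dt, " ms")
    if (step %% save_every == 0) {
      isave <- isave + 1L
      out[, isave] <- vm
      times[isave] <- step * params$dt
      if (progress && (times[isave] %% 200 == 0))
        message("t = ", times[isave], " ms")
    }
  }
  structure(list(times = times[seq_len(isave)],
                 vm = out[, seq_len(isave), drop = FALSE],
                 geometry = geom, protocol = structure(list(events = events),
                                                      class = "stimulus_protocol"),
                 params = params, cell_model = cell_model, seed = seed),
            class = "vm_record")
}

#' @exportS3Method base::print
print.vm_record <- function(x, ...) {
  cat(sprintf("<vm_record> %d nodes x %d frames (%g..%g ms), model %s\n",
              nrow(x$vm), ncol(x$vm), x$times[1], x$times[length(x$times)],
              x$cell_model))
  invisible(x)
}

#' Measure plane-wave conduction velocity between two nodes
#'
#' Activation times are detected from the Vm traces at the two sites (maximum
#' positive dV/dt above threshold) and the speed is the Euclidean distance
#' divided by the activation-time difference.
#'
#' @param record a `vm_record`.
#' @param site_a,site_b node indices (activation must reach `site_b` later).
#' @param params a [detector_params()]; defaults to the Vm detector.
#' @return Speed in cm/s.
#' @export
measure_cv <- function(record, site_a, site_b, params = detector_params()) {
  if (site_a == site_b) stop("sites must be distinct")
  dt_samp <- record$times[2] - record$times[1]
  acts_a <- detect_activations(record$vm[site_a, ], params, dt = dt_samp)
  acts_b <- detect_activations(record$vm[site_b, ], params, dt = dt_samp)
  if (length(acts_a) != 1 || length(acts_b) != 1)
    stop("each site must activate exactly once in the record window")
  t_a <- record$times[1] + acts_a
  t_b <- record$times[1] + acts_b
  if (t_b <= t_a) stop("site_b does not activate after site_a")
  dist <- sqrt(sum((record$geometry$nodes[site_a, ] -
                    record$geometry$nodes[site_b, ])^2))
  dist / ((t_b - t_a) / 1000)
}
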