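# Activation-time detection, state-space phase, surface phase singularities
# and reentry-source localization.

#' Activation-time detector parameters
#'
#' Activation is the time of extremal signal derivative, provided its
#' magnitude exceeds `alpha`, with no two activations closer than the
#' refractory window `beta`.  For transmembrane potential the upstroke is
#' detected (positive polarity, default threshold 0.2 mV/ms); for unipolar
#' electrograms the steepest negative deflection is detected (negative
#' polarity; 1 mV/ms for good-contact baskets, 0.5 mV/ms otherwise).
#'
#' @param alpha derivative threshold magnitude, mV/ms (> 0).
#' @param beta refractory window, ms (> 0).
#' @param polarity `"positive"` (Vm) or `"negative"` (electrograms).
#' @return A `detector_params` list.
#' @export
detector_params <- function(alpha = 0.2, beta = 100,
                            polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta, polarity = polarity),
            class = "detector_params")
}

#' Electrogram detector presets
#' @param contact `"good"` (threshold 1 mV/ms) or `"poor"` (0.5 mV/ms, also
#'   used for uniform grid arrays).
#' @return A [detector_params()] with negative polarity.
#' @export
egm_detector_params <- function(contact = c("good", "poor")) {
  contact <- match.arg(contact)
  detector_params(alpha = if (contact == "good") 1.0 else 0.5,
                  beta = 100, polarity = "negative")
}

#' Detect activation times in a sampled signal
#'
#' The forward finite-difference derivative is computed on the sample grid
#' (no interpolation: AcT resolution equals the sampling interval).  Within
#' each contiguous suprathreshold episode the sample of extremal derivative
#' (earliest on ties) is an activation candidate; candidates closer than
#' `beta` ms to an already accepted activation are discarded, scanning in
#' time order.
#'
#' @param signal numeric vector, mV, sampled every `dt` ms.
#' @param params a [detector_params()].
#' @param dt sampling interval, ms.
#' @param t0 time of the first sample, ms.
#' @return Numeric vector of activation times (ms); may be empty.
#' @export
detect_activations <- function(signal, params = detector_params(), dt = 1,
                               t0 = 0) {
  n <- length(signal)
  if (n < 3) stop("signal must have at least 3 samples")
  d <- diff(signal) / dt                     # derivative at samples 1..n-1
  if (params$polarity == "negative") d <- -d
  supra <- d >= params$alpha
  supra[is.na(supra)] <- FALSE
  if (!any(supra)) return(numeric(0))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(d[seg])])  # earliest max on ties
  }
  acts <- numeric(0)
  last <- -Inf
  for (i in cand) {
    t <- t0 + (i - 1) * dt
    if (t - last >= params$beta) {
      acts <- c(acts, t)
      last <- t
    }
  }
  acts
}

#' Activation map for every node of a Vm record
#'
#' @param record a `vm_record`.
#' @param params a [detector_params()] (Vm defaults).
#' @param nodes node indices (default all).
#' @return Named list (by node index) of activation-time vectors (ms).
#' @export
vm_activation_map <- function(record, params = detector_params(),
                              nodes = seq_len(nrow(record$vm))) {
  dt <- record$times[2] - record$times[1]
  out <- lapply(nodes, function(i)
    detect_activations(record$vm[i, ], params, dt = dt, t0 = record$times[1]))
  names(out) <- as.character(nodes)
  out
}

#' Activation map for an electrogram set
#' @param egms an `electrogram_set`.
#' @param params a [detector_params()] (use [egm_detector_params()]).
#' @return Named list (by electrode label) of activation-time vectors (ms).
#' @export
egm_activation_map <- function(egms, params = egm_detector_params("good")) {
  dt <- egms$times[2] - egms$times[1]
  out <- lapply(seq_len(nrow(egms$phi_e)), function(i)
    detect_activations(egms$phi_e[i, ], params, dt = dt, t0 = egms$times[1]))
  names(out) <- egms$labels
  out
}

# --------------------------------------------------------------------------
# Phase
# --------------------------------------------------------------------------

# wrap angles (or angle differences) to (-pi, pi]
wrap_angle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

#' State-space phase of a Vm record
#'
#' theta(t) = atan2(Vm(t + delay) + offset, Vm(t - delay) + offset), the
#' delay-embedded phase used to track reentrant waves.  The first and last
#' `delay` ms are undefined (NA), as are samples where both atan2 arguments
#' are below the degeneracy floor.
#'
#' @param record a `vm_record` (or a plain nodes x times matrix via `vm` +
#'   `times`).
#' @param offset voltage offset, mV (default 30: centers the phase orbit).
#' @param delay embedding delay, ms (default 2).
#' @param floor degeneracy floor, mV.
#' @return A `phase_record`: `theta` (nodes x times, radians in (-pi, pi]),
#'   `times`, `offset`, `delay`.
#' @export
compute_phase <- function(record, offset = 30, delay = 2, floor = 1e-6) {
  vm <- record$vm
  times <- record$times
  dt <- times[2] - times[1]
  lag <- round(delay / dt)
  nt <- ncol(vm)
  if (nt < 2 * lag + 1) stop("record must span at least twice the delay")
  theta <- matrix(NA_real_, nrow(vm), nt)
  idx <- (lag + 1):(nt - lag)
  a <- vm[, idx + lag, drop = FALSE] + offset
  b <- vm[, idx - lag, drop = FALSE] + offset
  th <- atan2(a, b)
  th[abs(a) < floor & abs(b) < floor] <- NA_real_
  theta[, idx] <- th
  structure(list(theta = theta, times = times, offset = offset,
                 delay = delay, geometry = record$geometry),
            class = "phase_record")
}

# --------------------------------------------------------------------------
# Surface phase singularities
# --------------------------------------------------------------------------

# Ordered one-ring (closed cycle) of surface neighbors for every node,
# oriented counterclockwise about the outward normal (from the consistent
# CCW-from-outside triangle orientation).  Boundary and non-manifold nodes
# get an empty ring.
surface_one_rings <- function(geom) {
  n <- nrow(geom$nodes)
  el <- geom$elements
  # directed opposite edges per vertex: triangle (i, a, b) contributes a->b
  from <- vector("list", n)
  to <- vector("list", n)
  for (k in 1:3) {
    i <- el[, k]
    a <- el[, (k %% 3) + 1L]
    b <- el[, ((k + 1) %% 3) + 1L]
    for (t in seq_along(i)) {
      from[[i[t]]] <- c(from[[i[t]]], a[t])
      to[[i[t]]] <- c(to[[i[t]]], b[t])
    }
  }
  rings <- vector("list", n)
  for (i in seq_len(n)) {
    f <- from[[i]]; s <- to[[i]]
    if (is.null(f) || length(f) < 3) { rings[[i]] <- integer(0); next }
    succ <- s[match(f, f)]           # placeholder to keep names simple
    succ_map <- s; names(succ_map) <- as.character(f)
    if (anyDuplicated(f)) { rings[[i]] <- integer(0); next }  # non-manifold
    start <- f[1]
    ring <- integer(0)
    cur <- start
    ok <- TRUE
    for (step in seq_len(length(f))) {
      ring <- c(ring, cur)
      nxt <- succ_map[as.character(cur)]
      if (is.na(nxt)) { ok <- FALSE; break }                  # boundary fan
      cur <- as.integer(nxt)
      if (cur == start) break
    }
    if (!ok || cur != start || length(ring) != length(f)) {
      rings[[i]] <- integer(0)
    } else {
      rings[[i]] <- ring
    }
  }
  rings
}

rings_to_csr <- function(rings) {
  lens <- vapply(rings, length, integer(1))
  list(offsets = c(0L, cumsum(lens)), nodes = unlist(rings, use.names = FALSE))
}

#' Detect surface phase singularities at one or more frames
#'
#' For each surface node with a closed one-ring, the wrapped phase
#' differences are summed around the ordered ring; a winding of +-2*pi
#' (|winding| > pi in practice) marks a phase singularity whose topological
#' charge is the winding sign with respect to the outward surface normal.
#' A singular point inside a triangle is enclosed by the one-rings of all
#' three of its vertices, so edge-connected flagged nodes of equal charge
#' are merged into a single singularity, reported at the member node nearest
#' the component centroid (lowest node index on ties).
#'
#' @param phase a `phase_record` from [compute_phase()].
#' @param geom the [tissue_geometry()] (defaults to the record's geometry).
#' @param t time(s) in ms at which to evaluate (must be within the defined
#'   phase window).
#' @return For a single `t`, a data.frame with columns `node` and `charge`;
#'   for several, a list of such data.frames (one per frame, named by time).
#' @export
detect_surface_ps <- function(phase, geom = phase$geometry, t) {
  rings <- attr(geom, "one_rings")
  if (is.null(rings)) rings <- surface_one_rings(geom)
  csr <- rings_to_csr(rings)
  frames <- match(t, phase$times)
  if (anyNA(frames)) stop("requested times not in the phase record")
  res <- ps_detect_cpp(phase$theta, csr$offsets, csr$nodes,
                       as.integer(frames))
  adj <- attr(geom, "edge_adjacency")
  if (is.null(adj)) adj <- surface_edge_adjacency(geom)
  res <- lapply(res, function(m) merge_ps_components(as.data.frame(m), geom,
                                                     adj))
  names(res) <- as.character(t)
  if (length(res) == 1) res[[1]] else res
}

# undirected node adjacency over surface triangle edges
surface_edge_adjacency <- function(geom) {
  el <- geom$elements
  e <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], e[, 1])
}

merge_ps_components <- function(fr, geom, adj) {
  if (nrow(fr) <= 1) return(fr)
  out_node <- integer(0); out_charge <- integer(0)
  for (ch in unique(fr$charge)) {
    nodes <- fr$node[fr$charge == ch]
    remaining <- nodes
    while (length(remaining) > 0) {
      comp <- remaining[1]
      frontier <- comp
      while (length(frontier) > 0) {
        nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
        nxt <- setdiff(intersect(nb, remaining), comp)
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      remaining <- setdiff(remaining, comp)
      comp <- sort(comp)  # deterministic tie-break: lowest node index first
      ctr <- colMeans(geom$nodes[comp, , drop = FALSE])
      d2 <- rowSums((geom$nodes[comp, , drop = FALSE] -
                     matrix(ctr, length(comp), 3, byrow = TRUE))^2)
      rep_node <- comp[which.min(d2)]
      out_node <- c(out_node, rep_node)
      out_charge <- c(out_charge, ch)
    }
  }
  ord <- order(out_node)
  data.frame(node = out_node[ord], charge = out_charge[ord])
}

#' Phase-singularity series over a time window
#'
#' Convenience wrapper evaluating [detect_surface_ps()] at every saved frame
#' in `window`; one-ring construction is shared across frames.
#'
#' @param phase a `phase_record`.
#' @param geom the [tissue_geometry()].
#' @param window `c(from, to)` in ms.
#' @return Named list (by time) of data.frames with `node`, `charge`.
#' @export
ps_series <- function(phase, geom = phase$geometry,
                      window = c(1000, 2000)) {
  sel <- phase$times >= window[1] & phase$times <= window[2]
  # restrict to frames where the phase is defined
  lag <- round(phase$delay / (phase$times[2] - phase$times[1]))
  nt <- length(phase$times)
  defined <- seq_len(nt) > lag & seq_len(nt) <= nt - lag
  ts <- phase$times[sel & defined]
  if (length(ts) == 0) stop("empty analysis window")
  out <- detect_surface_ps(phase, geom, ts)
  if (is.data.frame(out)) out <- setNames(list(out), as.character(ts))
  out
}

#' Phase-singularity density map
#'
#' Counts, per node, how many frames in the series carry a phase singularity
#' at that node.
#'
#' @param series output of [ps_series()] (list of per-frame PS tables).
#' @param n_nodes number of mesh nodes.
#' @return Integer vector of per-node PS occurrence counts.
#' @export
ps_density <- function(series, n_nodes) {
  if (length(series) == 0) stop("empty PS series")
  counts <- integer(n_nodes)
  for (fr in series) {
    if (nrow(fr) == 0) next
    counts[fr$node] <- counts[fr$node] + 1L
  }
  counts
}

#' Table of individual PS occurrences with coordinates
#' @param series output of [ps_series()].
#' @param geom the [tissue_geometry()].
#' @return data.frame with `t`, `node`, `charge`, `x`, `y`, `z`.
#' @export
ps_occurrences <- function(series, geom) {
  rows <- lapply(names(series), function(tt) {
    fr <- series[[tt]]
    if (nrow(fr) == 0) return(NULL)
    data.frame(t = as.numeric(tt), node = fr$node, charge = fr$charge,
               x = geom$nodes[fr$node, 1], y = geom$nodes[fr$node, 2],
               z = geom$nodes[fr$node, 3])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Localize reentry sources by clustering PS occurrences
#'
#' k-means (k = 2, seeded multi-restart) on the coordinates of individual
#' phase-singularity occurrences; each cluster's center of mass is a reentry
#' source location and its chirality is the majority topological charge of
#' its members (positive charge about the outward normal = clockwise viewed
#' from the endocardium = R+).
#'
#' @param occurrences data.frame from [ps_occurrences()].
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means restarts.
#' @return A list with elements `R+` and `R-` (when both chiralities are
#'   present), each a `reentry_source`: `location` (cm), `chirality`,
#'   `support` (occurrence count), `nodes` (member node indices).
#' @export
cluster_reentry_sources <- function(occurrences, k = 2, seed = 1L) {
  if (is.null(occurrences) || nrow(occurrences) < k)
    stop("need at least k PS occurrences")
  pts <- as.matrix(occurrences[, c("x", "y", "z")])
  if (nrow(unique(pts)) < k)
    stop("degenerate clustering: fewer than k distinct PS locations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  km <- kmeans(pts, centers = k, nstart = 10, iter.max = 100)
  sources <- lapply(seq_len(k), function(cl) {
    members <- which(km$cluster == cl)
    maj <- sign(sum(occurrences$charge[members]))
    chir <- if (maj >= 0) "R+" else "R-"
    structure(list(location = colMeans(pts[members, , drop = FALSE]),
                   chirality = chir, support = length(members),
                   nodes = unique(occurrences$node[members])),
              class = "reentry_source")
  })
  chirs <- vapply(sources, function(s) s$chirality, character(1))
  names(sources) <- make.unique(chirs)
  sources
}
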