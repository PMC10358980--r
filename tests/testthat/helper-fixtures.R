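# Shared simulation fixtures, computed lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Plane wave on a narrow strip, Nygren kinetics: the CV calibration fixture.
fixture_strip <- function() {
  fixture("strip", function() {
    geom <- build_sheet_geometry(101, 3, 0.025)
    prot <- stimulus_protocol(list(list(
      label = "S1", onset = 0, duration = 2, amplitude = 40,
      center = c(0, 0.025, 0), radius = 0.06)))
    run_monodomain(geom, tissue_params(duration = 100), prot, "nygren")
  })
}

# Single paced beat on a 2 cm x 2 cm sheet with a 6x6 contact array.
fixture_paced_sheet <- function() {
  fixture("paced_sheet", function() {
    geom <- build_sheet_geometry(81, 81, 0.025)
    prot <- stimulus_protocol(list(list(
      label = "S1", onset = 5, duration = 2, amplitude = 40,
      center = c(0, 1, 0), radius = 0.15)))
    record <- run_monodomain(geom, tissue_params(duration = 120), prot,
                             "nygren")
    array <- place_uniform_array(geom, center = c(1, 1, 0))
    list(record = record, array = array)
  })
}

# Figure-of-eight reentry on a 4 cm x 4 cm sheet (fast two-variable model):
# S1 at the left edge, S2 disc mid-sheet across the recovery line.
fixture_fo8 <- function(duration = 1500) {
  fixture("fo8", function() {
    geom <- build_sheet_geometry(81, 81, 0.05)
    prot <- protocol_s1s2(geom, s1_center = c(0, 2, 0), s1_radius = 0.5,
                          s2_center = c(2, 2, 0), s2_radius = 1.0,
                          s2_delay = 400)
    record <- run_monodomain(geom, tissue_params(sigma = 1.0,
                                                 duration = duration),
                             prot, "alievpanfilov")
    phase <- compute_phase(record)
    series <- ps_series(phase, geom, window = c(500, duration - 10))
    occ <- ps_occurrences(series, geom)
    sources <- cluster_reentry_sources(occ, seed = 1)
    list(record = record, phase = phase, series = series, occ = occ,
         sources = sources)
  })
}

# Exhaustive maximum matching size for AcT lists within tol (oracle for the
# greedy matcher on small instances).
optimal_match_count <- function(measured, truth, tol) {
  n <- length(measured)
  if (n == 0 || length(truth) == 0) return(0L)
  best <- 0L
  recurse <- function(mi, used) {
    if (mi > n) {
      best <<- max(best, sum(used))
      return(invisible(NULL))
    }
    recurse(mi + 1L, used)  # leave measured[mi] unmatched
    for (ti in seq_along(truth)) {
      if (!used[ti] && abs(measured[mi] - truth[ti]) <= tol) {
        used[ti] <- TRUE
        recurse(mi + 1L, used)
        used[ti] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(truth)))
  best
}

# Brute-force AcT detector oracle: scan every sample, apply threshold,
# episode-extremum and refractory rules literally.
detector_oracle <- function(signal, alpha, beta, polarity = "positive") {
  d <- diff(signal)
  if (polarity == "negative") d <- -d
  supra <- d >= alpha
  cand <- integer(0)
  i <- 1
  while (i <= length(d)) {
    if (supra[i]) {
      j <- i
      while (j < length(d) && supra[j + 1]) j <- j + 1
      seg <- i:j
      cand <- c(cand, seg[which.max(d[seg])])
      i <- j + 1
    } else i <- i + 1
  }
  acts <- numeric(0)
  for (k in cand) {
    t <- k - 1
    if (length(acts) == 0 || t - acts[length(acts)] >= beta)
      acts <- c(acts, t)
  }
  acts
}
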