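# Focal / reentrant activation-pattern classification from electrode-array
# activation times, using the 3 x 3 neighborhood of each interior electrode.

#' Pattern-classifier parameters
#'
#' @param delta difference tolerance, ms (>= 0): how far outside exact
#'   synchrony/progression a neighbor difference may fall.
#' @param gamma wavefront interval, ms (> 0): the window within which
#'   neighboring activations are considered part of one wavefront.
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(delta = 2, gamma = 100) {
  stopifnot(delta >= 0, gamma > 0)
  structure(list(delta = delta, gamma = gamma), class = "classifier_params")
}

# nearest AcT at or after time t (Inf if none)
.next_act <- function(acts, t) {
  a <- acts[acts >= t]
  if (length(a) == 0) Inf else a[1]
}

#' Classify one electrode site's beats as focal or reentrant
#'
#' For each central activation time T:
#' * Focal (F): for every one of the 8 neighbors, the difference between the
#'   neighbor's nearest activation at or after `T - delta` and T lies in
#'   `[-delta, gamma + delta]` -- all neighbors activate with (or just
#'   after) the center, as for a source radiating from the site.
#' * Reentrant (R+/R-): there is a progression of activation along the
#'   closed ring of the 8 neighbors (R+ along the stored clockwise ring
#'   order, R- along the reversed ring) in which every consecutive
#'   difference lies in `[-delta, gamma + delta]`, the loop closes through
#'   the starting neighbor's next activation (continuation of activation
#'   between beats), and the total progression around the loop is strictly
#'   positive.  All 8 rotations of the starting neighbor are tried.
#'
#' R verdicts take precedence over F (a slowly rotating ring can also
#' satisfy the F bound).
#'
#' @param center_acts numeric vector of the central electrode's AcTs (ms).
#' @param ring_acts list of 8 AcT vectors, ordered per the array's stored
#'   neighbor ring.
#' @param params a [classifier_params()].
#' @return data.frame with columns `time` (central AcT) and `type` (`"F"`,
#'   `"R+"`, `"R-"`); beats matching no rule are omitted.
#' @export
classify_site <- function(center_acts, ring_acts, params = classifier_params()) {
  stopifnot(length(ring_acts) == 8)
  lo <- -params$delta
  hi <- params$gamma + params$delta
  res_t <- numeric(0); res_type <- character(0)
  for (T in center_acts) {
    type <- NA_character_
    if (.ring_progression(T, ring_acts, lo, hi)) {
      type <- "R+"
    } else if (.ring_progression(T, rev(ring_acts), lo, hi)) {
      type <- "R-"
    } else {
      diffs <- vapply(ring_acts, function(a) .next_act(a, T - params$delta) - T,
                      numeric(1))
      if (all(is.finite(diffs)) && all(diffs >= lo & diffs <= hi))
        type <- "F"
    }
    if (!is.na(type)) {
      res_t <- c(res_t, T); res_type <- c(res_type, type)
    }
  }
  data.frame(time = res_t, type = res_type, stringsAsFactors = FALSE)
}

# Does any rotation of the ring admit a valid chained progression tied to
# central activation time T?  Exhaustive (depth-first) search over the
# candidate activations at each ring position; windows keep the branching
# factor small in practice, and exhaustiveness makes detections monotone in
# delta (an admissible chain stays admissible when the window widens).
.ring_progression <- function(T, ring_acts, lo, hi) {
  for (start in 1:8) {
    path <- c(start:8, seq_len(start - 1))[1:8]
    a1 <- ring_acts[[path[1]]]
    anchors <- a1[abs(a1 - T) <= hi]       # tie the chain to this beat
    for (t1 in anchors) {
      if (.chain_dfs(t1, t1, 2L, path, ring_acts, lo, hi)) return(TRUE)
    }
  }
  FALSE
}

.chain_dfs <- function(t1, prev, k, path, ring_acts, lo, hi) {
  if (k > 8L) {
    # close the loop through the starting neighbor; the wrap step may use
    # the next beat (continuation of activation between beats)
    wraps <- ring_acts[[path[1]]]
    wraps <- wraps[wraps - prev >= lo & wraps - prev <= hi]
    return(any(wraps - t1 > 0))            # strictly positive progression
  }
  cands <- ring_acts[[path[k]]]
  cands <- cands[cands - prev >= lo & cands - prev <= hi]
  for (cn in cands) {
    if (.chain_dfs(t1, cn, k + 1L, path, ring_acts, lo, hi)) return(TRUE)
  }
  FALSE
}

#' Extract activation-pattern detections over a whole electrode array
#'
#' Applies [classify_site()] at every electrode that has a full 8-neighbor
#' ring (border electrodes are never classification centers).
#'
#' @param acts activation map over the array: named list of AcT vectors in
#'   electrode order (e.g. from [egm_activation_map()]).
#' @param array the [electrode_array()] supplying adjacency.
#' @param params a [classifier_params()].
#' @return data.frame with columns `electrode`, `time`, `type`.
#' @export
extract_patterns <- function(acts, array, params = classifier_params()) {
  stopifnot(length(acts) == length(array$labels))
  out <- list()
  for (i in seq_along(array$labels)) {
    nb <- array$adjacency[[i]]
    if (is.null(nb)) next
    det <- classify_site(acts[[i]], acts[nb], params)
    if (nrow(det) > 0) {
      det$electrode <- array$labels[i]
      out[[length(out) + 1L]] <- det[, c("electrode", "time", "type")]
    }
  }
  if (length(out) == 0)
    return(data.frame(electrode = character(0), time = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
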