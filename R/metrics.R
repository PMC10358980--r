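# Performance metrics: activation-time agreement (fC, fS, RMS, AcTPM vs
# tolerance) and activation-pattern agreement (correct / spurious /
# misclassified, AcPPM, temporal and spatial localization errors).

#' Activation-time performance metric
#'
#' `AcTPM = fC * (1 - fS) * 100`; 100 indicates perfect performance.
#'
#' @param fC fraction of correct activation times, in \[0, 1\].
#' @param fS fraction of spurious activation times, in \[0, 1\].
#' @return Score in \[0, 100\].
#' @export
actpm <- function(fC, fS) {
  if (any(fC < 0 | fC > 1) || any(fS < 0 | fS > 1))
    stop("fC and fS must lie in [0, 1]")
  fC * (1 - fS) * 100
}

#' Activation-pattern performance metric
#'
#' `AcPPM = fC * (1 - fS) * (1 - fM) * 100`, combining correct, spurious and
#' misclassified pattern fractions.
#'
#' @param fC,fS,fM fractions of correct, spurious and misclassified
#'   patterns, each in \[0, 1\].
#' @return Score in \[0, 100\].
#' @export
acppm <- function(fC, fS, fM) {
  if (any(fC < 0 | fC > 1) || any(fS < 0 | fS > 1) || any(fM < 0 | fM > 1))
    stop("fC, fS and fM must lie in [0, 1]")
  fC * (1 - fS) * (1 - fM) * 100
}

# One-to-one matching of measured to truth times within tol.  Truth times
# are processed in increasing order and each takes the earliest unused
# measured time within its window -- the earliest-deadline rule, which is
# maximum-cardinality for equal-width intervals (guarded by the exhaustive
# oracle in the tests).  Ties therefore go to the earlier truth time.
match_act_times <- function(measured, truth, tol) {
  ms <- sort(measured)
  used <- logical(length(ms))
  out_m <- numeric(0); out_t <- numeric(0)
  for (t in sort(truth)) {
    cand <- which(!used & ms >= t - tol & ms <= t + tol)
    if (length(cand) == 0) next
    j <- cand[1]
    used[j] <- TRUE
    out_m <- c(out_m, ms[j]); out_t <- c(out_t, t)
  }
  data.frame(measured = out_m, truth = out_t, diff = out_m - out_t)
}

#' Compare electrode activation times to the silver standard
#'
#' Each electrode's AcT list is matched one-to-one against the Vm AcT list
#' of its nearest endocardial node within `tol` ms.  `fC` is the number of
#' matched AcTs over the total number of truth AcTs; `fS` the number of
#' unmatched electrode AcTs over the same denominator, capped at 1.
#'
#' @param egm_acts named list of AcT vectors per electrode (label order).
#' @param truth_acts list of Vm AcT vectors indexed by node (names are node
#'   indices, e.g. from [vm_activation_map()]).
#' @param mapping integer vector, nearest surface node per electrode.
#' @param tol matching tolerance, ms (>= 0).
#' @return An `act_report`: per-electrode table (`label`, counts, `fC`,
#'   `fS`, `rms`), pooled `fC`, `fS`, `rms` (over all matched pairs),
#'   `rms_sd` (SD across electrodes of per-electrode RMS), `actpm`, `tol`.
#' @export
compare_act <- function(egm_acts, truth_acts, mapping, tol) {
  if (tol < 0) stop("tol must be >= 0")
  ne <- length(egm_acts)
  stopifnot(length(mapping) == ne)
  labels <- names(egm_acts)
  if (is.null(labels)) labels <- as.character(seq_len(ne))
  n_corr <- n_spur <- n_truth <- integer(ne)
  rms_e <- rep(NA_real_, ne)
  all_diffs <- numeric(0)
  for (i in seq_len(ne)) {
    tr <- truth_acts[[as.character(mapping[i])]]
    if (is.null(tr)) stop("no truth AcT list for node ", mapping[i])
    m <- match_act_times(egm_acts[[i]], tr, tol)
    n_corr[i] <- nrow(m)
    n_spur[i] <- length(egm_acts[[i]]) - nrow(m)
    n_truth[i] <- length(tr)
    if (nrow(m) > 0) {
      rms_e[i] <- sqrt(mean(m$diff^2))
      all_diffs <- c(all_diffs, m$diff)
    }
  }
  fC_e <- ifelse(n_truth > 0, n_corr / n_truth, 0)
  fS_e <- ifelse(n_truth > 0, pmin(n_spur / n_truth, 1), 1)
  tot_truth <- sum(n_truth)
  fC <- if (tot_truth > 0) sum(n_corr) / tot_truth else 0
  fS <- if (tot_truth > 0) min(sum(n_spur) / tot_truth, 1) else 1
  structure(list(
    per_electrode = data.frame(label = labels, n_truth = n_truth,
                               n_correct = n_corr, n_spurious = n_spur,
                               fC = fC_e, fS = fS_e, rms = rms_e,
                               stringsAsFactors = FALSE),
    fC = fC, fS = fS,
    rms = if (length(all_diffs)) sqrt(mean(all_diffs^2)) else NA_real_,
    rms_sd = if (sum(!is.na(rms_e)) > 1) sd(rms_e, na.rm = TRUE) else NA_real_,
    actpm = actpm(fC, fS), tol = tol), class = "act_report")
}

#' @exportS3Method base::print
print.act_report <- function(x, ...) {
  cat(sprintf("<act_report> tol = %g ms: fC = %.3f, fS = %.3f, AcTPM = %.1f, RMS = %.3g ms\n",
              x$tol, x$fC, x$fS, x$actpm, x$rms))
  invisible(x)
}

#' AcTPM as a function of matching tolerance
#'
#' @param egm_acts,truth_acts,mapping as in [compare_act()].
#' @param tol_values non-empty vector of non-negative tolerances, ms.
#' @return data.frame with `tol`, `actpm`, `pS` (spurious percentage,
#'   `100 * fS`), `rms`, `rms_sd`.
#' @export
tolerance_sweep <- function(egm_acts, truth_acts, mapping, tol_values) {
  if (length(tol_values) == 0 || any(tol_values < 0))
    stop("tol_values must be non-empty and non-negative")
  rows <- lapply(tol_values, function(tol) {
    r <- compare_act(egm_acts, truth_acts, mapping, tol)
    data.frame(tol = tol, actpm = r$actpm, pS = 100 * r$fS, rms = r$rms,
               rms_sd = r$rms_sd)
  })
  do.call(rbind, rows)
}

#' Compare detected activation patterns to ground-truth events
#'
#' A detection is correct if a truth event of the same type lies within
#' `time_window` ms of its central AcT and within `dist_window` cm of its
#' electrode; the spatially nearest eligible detection is the match and each
#' truth event matches at most one detection.  An unmatched truth event
#' paired (within both windows) with a detection of a different type counts
#' as a misclassification of that truth type.  Same-type detections inside
#' the windows of an already matched truth event are duplicates (neither
#' correct nor spurious).  All remaining detections are spurious.
#'
#' @param detections data.frame `electrode`, `time`, `type` (from
#'   [extract_patterns()] or user predictions).
#' @param truth data.frame of ground-truth events: `type` (P, R+, R-, F+,
#'   F-), `beat`, `x`, `y`, `z` (cm), `ref_time` (ms: stimulation time for
#'   P/F, beat reference for R).
#' @param array the [electrode_array()] giving detection positions; may be
#'   NULL when `positions` is supplied directly.
#' @param time_window temporal matching window, ms (default 100).
#' @param dist_window spatial matching window, cm (default 1).
#' @param positions optional matrix (one row per detection, x/y/z in cm)
#'   overriding the array lookup, e.g. for predictions at surface sites.
#' @return An `acp_report`: per-type table with counts, `fC`, `fS`, `fM`,
#'   `acppm`, `E_T` (mean |AcT - stimulation time| over correct P/F, ms) and
#'   `E_X` (mean electrode-to-source distance over correct detections, cm),
#'   plus detail tables of correct / misclassified / spurious detections.
#' @export
compare_patterns <- function(detections, truth, array = NULL,
                             time_window = 100, dist_window = 1,
                             positions = NULL) {
  det <- detections
  if (is.null(positions)) {
    pos <- array$positions[match(det$electrode, array$labels), , drop = FALSE]
    if (nrow(det) > 0 && anyNA(pos[, 1]))
      stop("detections reference electrodes not in the array")
  } else {
    pos <- matrix(as.numeric(positions), ncol = 3)
    if (nrow(pos) != nrow(det))
      stop("one position row per detection required")
  }
  n_det <- nrow(det)
  det_used <- rep(FALSE, n_det)
  det_role <- rep("spurious", n_det)
  truth$matched <- FALSE
  truth$E_X <- NA_real_; truth$E_T <- NA_real_
  truth$det_row <- NA_integer_

  dist_to <- function(tr_row, d_idx) {
    sqrt((pos[d_idx, 1] - truth$x[tr_row])^2 +
         (pos[d_idx, 2] - truth$y[tr_row])^2 +
         (pos[d_idx, 3] - truth$z[tr_row])^2)
  }
  eligible <- function(tr_row, same_type) {
    if (n_det == 0) return(integer(0))
    cand <- which(!det_used &
                  (if (same_type) det$type == truth$type[tr_row]
                   else det$type != truth$type[tr_row]) &
                  abs(det$time - truth$ref_time[tr_row]) <= time_window)
    cand[vapply(cand, function(j) dist_to(tr_row, j) <= dist_window,
                logical(1))]
  }

  # pass 1: correct matches (spatially nearest eligible same-type detection)
  for (i in seq_len(nrow(truth))) {
    cand <- eligible(i, same_type = TRUE)
    if (length(cand) == 0) next
    dd <- vapply(cand, function(j) dist_to(i, j), numeric(1))
    j <- cand[which.min(dd)]
    det_used[j] <- TRUE; det_role[j] <- "correct"
    truth$matched[i] <- TRUE
    truth$det_row[i] <- j
    truth$E_X[i] <- min(dd)
    truth$E_T[i] <- abs(det$time[j] - truth$ref_time[i])
  }
  # pass 2: duplicates (same-type detections inside a matched truth's windows)
  for (i in which(truth$matched)) {
    for (j in eligible(i, same_type = TRUE)) {
      det_used[j] <- TRUE; det_role[j] <- "duplicate"
    }
  }
  # pass 3: misclassifications for unmatched truth events
  misclass <- setNames(integer(0), character(0))
  for (i in which(!truth$matched)) {
    cand <- eligible(i, same_type = FALSE)
    if (length(cand) == 0) next
    dd <- vapply(cand, function(j) dist_to(i, j), numeric(1))
    j <- cand[which.min(dd)]
    det_used[j] <- TRUE; det_role[j] <- "misclassified"
    ty <- truth$type[i]
    misclass[ty] <- (if (ty %in% names(misclass)) misclass[ty] else 0L) + 1L
  }

  types <- unique(c(truth$type, det$type))
  per_type <- do.call(rbind, lapply(types, function(ty) {
    nT <- sum(truth$type == ty)
    nC <- sum(truth$type == ty & truth$matched)
    nM <- if (ty %in% names(misclass)) misclass[[ty]] else 0L
    nS <- sum(det$type == ty & det_role == "spurious")
    if (nT > 0) {
      fC <- nC / nT; fS <- min(nS / nT, 1); fM <- min(nM / nT, 1)
      score <- acppm(fC, fS, fM)
    } else {
      fC <- NA_real_; fS <- NA_real_; fM <- NA_real_; score <- NA_real_
    }
    corr <- truth$type == ty & truth$matched
    data.frame(type = ty, n_truth = nT, n_correct = nC, n_spurious = nS,
               n_misclassified = nM, fC = fC, fS = fS, fM = fM,
               acppm = score,
               E_X = if (any(corr)) mean(truth$E_X[corr]) else NA_real_,
               E_T = if (any(corr) && ty %in% c("P", "F+", "F-", "F"))
                 mean(truth$E_T[corr]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  details <- if (n_det > 0) cbind(det, role = det_role) else det
  structure(list(per_type = per_type, truth = truth, detections = details,
                 time_window = time_window, dist_window = dist_window),
            class = "acp_report")
}

#' @exportS3Method base::print
print.acp_report <- function(x, ...) {
  cat("<acp_report>\n")
  print(x$per_type, row.names = FALSE, digits = 3)
  invisible(x)
}
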