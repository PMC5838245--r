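#' Censoring configuration
#'
#' Thresholds and window extents for motion/intensity volume censoring.
#' Defaults follow the established scrubbing convention: framewise
#' displacement >= 0.3 mm or scaled signal-intensity difference > 10 marks a
#' spike; one volume before and two after each spike are censored as well
#' (four volumes per isolated spike); subjects with more than 200 censored
#' volumes (one third of a 600-volume session) are excluded.
#'
#' @param fd_threshold_mm framewise-displacement threshold in mm (spike when
#'   FD >= threshold)
#' @param intensity_threshold scaled signal-change threshold (spike when
#'   value > threshold)
#' @param mask_before volumes censored before each spike
#' @param mask_after volumes censored after each spike
#' @param max_censored_volumes exclusion bound: excluded when the total
#'   censored count is strictly greater than this
#' @param rotation_radius_mm head radius used to convert rotations to arc
#'   length in FD
#' @return an object of class `censoring_config`
#' @export
censoring_config <- function(fd_threshold_mm = 0.3,
                             intensity_threshold = 10,
                             mask_before = 1L,
                             mask_after = 2L,
                             max_censored_volumes = 200L,
                             rotation_radius_mm = 50) {
  stopifnot(fd_threshold_mm > 0, intensity_threshold > 0,
            mask_before >= 0, mask_after >= 0,
            max_censored_volumes >= 0, rotation_radius_mm > 0)
  structure(list(fd_threshold_mm = fd_threshold_mm,
                 intensity_threshold = intensity_threshold,
                 mask_before = as.integer(mask_before),
                 mask_after = as.integer(mask_after),
                 max_censored_volumes = as.integer(max_censored_volumes),
                 rotation_radius_mm = rotation_radius_mm),
            class = "censoring_config")
}

#' Framewise displacement from realignment parameters
#'
#' FD at volume t is the sum of absolute backward differences of the six
#' rigid-body realignment parameters, with the three rotations (radians)
#' converted to arc length on a sphere of radius `rotation_radius_mm`.
#' The first volume has no predecessor and is assigned FD = 0.
#'
#' @param trace numeric matrix, volumes x 6 (tx, ty, tz in mm; rx, ry, rz in
#'   radians)
#' @param rotation_radius_mm rotation-to-translation conversion radius (mm)
#' @return numeric vector of FD values (mm), one per volume
#' @export
compute_fd <- function(trace, rotation_radius_mm = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) stop("realignment trace must have 6 columns")
  if (!all(is.finite(trace))) stop("non-finite values in realignment trace")
  scaled <- trace
  scaled[, 4:6] <- scaled[, 4:6] * rotation_radius_mm
  d <- abs(diff(scaled))
  c(0, rowSums(d))
}

#' Scaled whole-volume signal-change trace (DVARS-like)
#'
#' For each volume t >= 2, the mean over voxels of the squared intensity
#' difference to the previous volume, divided by the grand mean intensity of
#' the whole series. The first volume is assigned 0.
#'
#' @param run a `bold_run` (see [generate_cohort()]) or a 4D array
#' @return numeric vector, one value per volume
#' @export
compute_scaled_signal_change <- function(run) {
  dat <- if (inherits(run, "bold_run")) run$data else run
  stopifnot(length(dim(dat)) == 4)
  nt <- dim(dat)[4]
  if (nt < 2) stop("need at least 2 volumes")
  v <- matrix(dat, ncol = nt)
  grand <- mean(v)
  if (abs(grand) < .Machine$double.eps * 100)
    stop("degenerate data: grand mean intensity is zero")
  msd <- colMeans((v[, -1, drop = FALSE] - v[, -nt, drop = FALSE])^2)
  c(0, msd / grand)
}

#' Build the temporal censoring mask and spike regressors
#'
#' Volumes where FD meets the threshold (>=) or the scaled signal change
#' exceeds it (>) are spikes. Around every spike a window from
#' `mask_before` volumes earlier to `mask_after` volumes later is censored
#' (clipped at the run boundaries); with the defaults an isolated interior
#' spike censors exactly four volumes. One indicator regressor per censored
#' volume is returned for absorption in the run-level model.
#'
#' @param fd_trace FD per volume (mm), from [compute_fd()]
#' @param intensity_trace scaled signal change per volume, from
#'   [compute_scaled_signal_change()]
#' @param config a [censoring_config()]
#' @return an object of class `censoring_result` with elements `fd_trace`,
#'   `intensity_trace`, `spike_frames`, `censored_mask`, `spike_regressors`
#'   (volumes x n_censored 0/1 matrix), `n_censored`, `excluded`
#' @export
build_temporal_mask <- function(fd_trace, intensity_trace,
                                config = censoring_config()) {
  n <- length(fd_trace)
  if (length(intensity_trace) != n)
    stop("fd_trace and intensity_trace lengths differ (",
         n, " vs ", length(intensity_trace), ")")
  spikes <- which(fd_trace >= config$fd_threshold_mm |
                    intensity_trace > config$intensity_threshold)
  censored <- logical(n)
  for (s in spikes) {
    lo <- max(1L, s - config$mask_before)
    hi <- min(n, s + config$mask_after)
    censored[lo:hi] <- TRUE
  }
  idx <- which(censored)
  reg <- matrix(0, nrow = n, ncol = length(idx))
  if (length(idx)) {
    reg[cbind(idx, seq_along(idx))] <- 1
    colnames(reg) <- paste0("spike_", idx)
  }
  structure(list(fd_trace = fd_trace,
                 intensity_trace = intensity_trace,
                 spike_frames = spikes,
                 censored_mask = censored,
                 spike_regressors = reg,
                 n_censored = length(idx),
                 excluded = FALSE),
            class = "censoring_result")
}

#' Subject-level exclusion rule over all runs
#'
#' A subject is excluded from group analyses when strictly more than
#' `max_censored_volumes` volumes are censored across all runs of the
#' session (with defaults, > 200 of 600, i.e. over one third).
#'
#' @param results list of per-run `censoring_result` objects
#' @param config a [censoring_config()]
#' @return list with `n_censored_total`, `excluded`, and the per-run counts
#' @export
apply_exclusion_rule <- function(results, config = censoring_config()) {
  if (!length(results)) stop("incomplete subject: no censoring results supplied")
  ok <- vapply(results, inherits, logical(1), what = "censoring_result")
  if (!all(ok)) stop("incomplete subject: missing or invalid run result")
  per_run <- vapply(results, function(r) r$n_censored, integer(1))
  total <- sum(per_run)
  list(n_censored_total = total,
       per_run = per_run,
       excluded = total > config$max_censored_volumes)
}
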