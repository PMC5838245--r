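#' Canonical double-gamma haemodynamic response function
#'
#' Standard two-gamma HRF: response peak at 6 s, undershoot peaking at 16 s,
#' peak-to-undershoot ratio 6; unit-scaled so the kernel peak equals 1.
#'
#' @param t time in seconds (vector)
#' @param peak_s time-to-peak of the positive lobe
#' @param undershoot_s time-to-peak of the undershoot
#' @param ratio peak-to-undershoot amplitude ratio
#' @return HRF values at `t`
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6) {
  a1 <- peak_s; a2 <- undershoot_s
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    stats::dgamma(t, shape = a2, rate = 1) / ratio
  h[t < 0] <- 0
  h / max(h)
}

# HRF-convolved regressor for one condition's (onset, duration) events,
# sampled at volume acquisition times. Oversampled at dt_s for accuracy.
convolve_events <- function(onsets_s, durations_s, n_volumes, tr_s,
                            dt_s = 0.1) {
  run_dur <- n_volumes * tr_s
  tgrid <- seq(0, run_dur + 32, by = dt_s)
  box <- numeric(length(tgrid))
  durations_s <- rep(durations_s, length.out = length(onsets_s))
  for (e in seq_along(onsets_s)) {
    on <- onsets_s[e]
    off <- on + max(durations_s[e], dt_s)  # impulse for zero-duration events
    box[tgrid >= on & tgrid < off] <- 1
  }
  kern <- hrf_double_gamma(seq(0, 32, by = dt_s))
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(tgrid)] * dt_s
  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  stats::approx(tgrid, conv, xout = vol_t, rule = 2)$y
}

#' 24-parameter Volterra expansion of realignment parameters
#'
#' Expands the six rigid-body parameters R_t into the motion confound basis
#' R_t, R_t^2, R_{t-1}, R_{t-1}^2 (24 columns). Lagged columns take the
#' value 0 at the first volume.
#'
#' @param trace volumes x 6 realignment matrix
#' @return volumes x 24 matrix with descriptive column names
#' @export
volterra_expansion <- function(trace) {
  trace <- as.matrix(trace)
  stopifnot(ncol(trace) == 6)
  lag1 <- rbind(0, trace[-nrow(trace), , drop = FALSE])
  out <- cbind(trace, trace^2, lag1, lag1^2)
  nm <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(paste0("mot_", nm), paste0("mot_", nm, "_sq"),
                     paste0("mot_", nm, "_lag"), paste0("mot_", nm, "_lagsq"))
  out
}

#' Run-level design matrix for nuisance modelling
#'
#' Assembles, per run: HRF-convolved task condition regressors, the
#' 24-column Volterra motion expansion, white-matter and ventricle mean
#' signal columns, one indicator per censored volume, and a baseline block
#' (intercept + linear drift). Column labels carry a `block` attribute
#' partitioning them into task / motion24 / tissue / spike / baseline.
#'
#' @param task data.frame with columns `condition`, `onset_s`, `duration_s`
#'   (may have zero rows for a task-free run)
#' @param trace volumes x 6 realignment matrix
#' @param tissue_signals volumes x 2 matrix (white matter, ventricle means)
#' @param censoring a `censoring_result` for the run
#' @param tr_s repetition time in seconds
#' @param n_volumes number of volumes in the run
#' @return numeric design matrix with attribute `block`
#' @export
build_design_matrix <- function(task, trace, tissue_signals, censoring,
                                tr_s, n_volumes) {
  trace <- as.matrix(trace)
  tissue_signals <- as.matrix(tissue_signals)
  if (nrow(trace) != n_volumes)
    stop("realignment trace has ", nrow(trace), " rows, run has ",
         n_volumes, " volumes")
  if (nrow(tissue_signals) != n_volumes || ncol(tissue_signals) != 2)
    stop("tissue_signals must be ", n_volumes, " x 2")
  if (length(censoring$censored_mask) != n_volumes)
    stop("censoring result length mismatch")

  cols <- list(); blocks <- character(0)
  if (!is.null(task) && nrow(task) > 0) {
    for (cc in unique(task$condition)) {
      ev <- task[task$condition == cc, , drop = FALSE]
      cols[[paste0("task_", cc)]] <-
        convolve_events(ev$onset_s, ev$duration_s, n_volumes, tr_s)
      blocks <- c(blocks, "task")
    }
  }
  mot <- volterra_expansion(trace)
  for (j in seq_len(ncol(mot))) cols[[colnames(mot)[j]]] <- mot[, j]
  blocks <- c(blocks, rep("motion24", 24))
  cols[["tissue_wm"]] <- tissue_signals[, 1]
  cols[["tissue_vent"]] <- tissue_signals[, 2]
  blocks <- c(blocks, "tissue", "tissue")
  sr <- censoring$spike_regressors
  if (ncol(sr)) {
    for (j in seq_len(ncol(sr))) cols[[colnames(sr)[j]]] <- sr[, j]
    blocks <- c(blocks, rep("spike", ncol(sr)))
  }
  cols[["intercept"]] <- rep(1, n_volumes)
  cols[["drift"]] <- seq_len(n_volumes) - (n_volumes + 1) / 2
  blocks <- c(blocks, "baseline", "baseline")

  X <- do.call(cbind, cols)
  attr(X, "block") <- stats::setNames(blocks, colnames(X))
  X
}

# Moore-Penrose pseudoinverse via SVD (rank-deficiency tolerant)
pinv <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Voxel-wise ordinary-least-squares residuals
#'
#' Fits y = X b per voxel and returns r = y - X b-hat, with rank deficiency
#' handled by the pseudoinverse. Censored volumes carry their own indicator
#' column in X, so their residuals are exactly zero.
#'
#' @param run a `bold_run`, or a voxels x volumes numeric matrix
#' @param X design matrix from [build_design_matrix()]
#' @param censored_mask logical censored-volume mask carried into the output
#' @return a `residual_series`: list with `data` (voxels x volumes),
#'   `dim3`, `affine`, `tr_s`, `censored_mask`, `run_starts`
#' @export
fit_glm_residuals <- function(run, X, censored_mask = NULL) {
  if (inherits(run, "bold_run")) {
    nt <- dim(run$data)[4]
    Y <- t(matrix(run$data, ncol = nt))      # volumes x voxels
    dim3 <- dim(run$data)[1:3]; affine <- run$affine; tr_s <- run$tr_s
  } else {
    Y <- t(as.matrix(run))                   # caller passes voxels x volumes
    dim3 <- attr(run, "dim3"); affine <- attr(run, "affine")
    tr_s <- attr(run, "tr_s")
  }
  if (nrow(Y) != nrow(X))
    stop("design has ", nrow(X), " rows but run has ", nrow(Y), " volumes")
  if (!all(is.finite(Y))) stop("non-finite voxel intensities")
  P <- pinv(X)
  R <- Y - X %*% (P %*% Y)
  R <- R - X %*% (P %*% R)   # one refinement pass: orthogonality to ~eps
  if (is.null(censored_mask)) censored_mask <- logical(nrow(Y))
  # censored frames carry their own indicator column: their residual is
  # exactly zero in exact arithmetic; enforce it against round-off
  blocks <- attr(X, "block")
  if (!is.null(blocks) && any(blocks == "spike")) {
    absorbed <- rowSums(X[, blocks == "spike", drop = FALSE]) > 0
    R[absorbed, ] <- 0
  }
  structure(list(data = t(R), dim3 = dim3, affine = affine, tr_s = tr_s,
                 censored_mask = censored_mask,
                 run_starts = 1L),
            class = "residual_series")
}

#' Band-pass transfer function
#'
#' Magnitude response of the zero-phase Butterworth-shaped band-pass used by
#' [bandpass_filter()]: the product of an order-`order` low-pass at
#' `high_hz` and high-pass at `low_hz` magnitude response.
#'
#' @param f frequency in Hz (vector)
#' @param low_hz high-pass corner (default 0.009)
#' @param high_hz low-pass corner (default 0.08)
#' @param order filter order (default 4)
#' @return gain in [0, 1] at each frequency
#' @export
bandpass_response <- function(f, low_hz = 0.009, high_hz = 0.08, order = 4) {
  lp <- 1 / sqrt(1 + (f / high_hz)^(2 * order))
  hp <- ifelse(f <= 0, 0, 1 / sqrt(1 + (low_hz / f)^(2 * order)))
  lp * hp
}

#' Zero-phase band-pass filter of a residual series
#'
#' Applies, per run segment, a zero-phase frequency-domain filter whose
#' magnitude response is the Butterworth-shaped band-pass of
#' [bandpass_response()] (default retention band 0.009-0.08 Hz). Each
#' segment is demeaned first; DC is fully removed.
#'
#' @param series a `residual_series` (possibly concatenated) or a voxels x
#'   volumes matrix
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   0 < low < high < Nyquist
#' @param tr_s repetition time (taken from the series when available)
#' @param order filter order
#' @return filtered object of the same shape
#' @export
bandpass_filter <- function(series, low_hz = 0.009, high_hz = 0.08,
                            tr_s = NULL, order = 4) {
  is_rs <- inherits(series, "residual_series")
  if (is_rs) {
    if (is.null(tr_s)) tr_s <- series$tr_s
    M <- series$data
    starts <- series$run_starts
  } else {
    M <- as.matrix(series)
    starts <- 1L
  }
  if (is.null(tr_s)) stop("tr_s required")
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  nt <- ncol(M)
  bounds <- c(starts, nt + 1L)
  for (r in seq_len(length(bounds) - 1L)) {
    idx <- bounds[r]:(bounds[r + 1L] - 1L)
    seg <- M[, idx, drop = FALSE]
    n <- length(idx)
    freqs <- (seq_len(n) - 1) / (n * tr_s)
    freqs <- pmin(freqs, 1 / tr_s - freqs)        # two-sided spectrum
    H <- bandpass_response(freqs, low_hz, high_hz, order)
    seg <- seg - rowMeans(seg)
    sp <- t(stats::mvfft(t(seg)))
    seg_f <- Re(t(stats::mvfft(t(sp * rep(H, each = nrow(seg))),
                               inverse = TRUE))) / n
    M[, idx] <- seg_f
  }
  if (is_rs) { series$data <- M; series } else M
}

#' Concatenate per-run residual series into one intrinsic time course
#'
#' @param runs list of `residual_series`, one per run, in the configured
#'   task order
#' @return a single `residual_series` with `run_starts` recording boundaries
#' @export
concatenate_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  d0 <- runs[[1]]$dim3; a0 <- runs[[1]]$affine
  for (r in runs) {
    if (!identical(r$dim3, d0) || !isTRUE(all.equal(r$affine, a0)))
      stop("grid/affine mismatch across runs")
  }
  nts <- vapply(runs, function(r) ncol(r$data), integer(1))
  starts <- cumsum(c(1L, nts[-length(nts)]))
  structure(list(data = do.call(cbind, lapply(runs, `[[`, "data")),
                 dim3 = d0, affine = a0, tr_s = runs[[1]]$tr_s,
                 censored_mask = unlist(lapply(runs, `[[`, "censored_mask")),
                 run_starts = as.integer(starts)),
            class = "residual_series")
}
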