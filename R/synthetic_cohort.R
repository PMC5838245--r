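# Synthetic two-session remission cohort generator. Emulates the statistical
# structure the downstream analysis assumes: two bilateral posterior
# cingulate seed spheres and an anterior cingulate/medial prefrontal target
# region whose inter-regional correlation differs by outcome group
# (controls ~ remitters > non-remitters), task-evoked responses, tissue
# nuisance signals, motion spikes, and a follow-up session in which
# non-remitter hypo-connectivity partially attenuates.

#' Cohort specification
#'
#' Defaults state the emulated study: 38 non-remitters, 37 remitters, 31
#' healthy controls; five 120-volume runs at TR 2.5 s per session; seed
#' spheres at (-11, -52, 37) and (12, -52, 35); target region centered at
#' (-2, 50, -6); planted seed-target correlation 0.6 for controls and
#' remitters versus 0.15 for non-remitters, giving a between-group effect
#' of about d = 1.2 on the Fisher-z scale at the default between-subject
#' spread; the non-remitter correlation rises by 0.2 at the follow-up
#' session without reaching remitter levels.
#'
#' @param n_remit,n_nonremit,n_control group sizes
#' @param grid_shape voxel grid dimensions (default 24 x 42 x 24 at 3 mm:
#'   the smallest even-sized 3 mm grid whose world extent contains all three
#'   anatomical coordinates in its interior)
#' @param voxel_size_mm isotropic voxel size
#' @param affine voxel-to-world map (default from [make_affine()])
#' @param n_runs,volumes_per_run,tr_s acquisition structure
#' @param seed_centers_mm list of two seed sphere centers (world mm)
#' @param target_center_mm target region center (world mm)
#' @param region_radius_mm radius of the planted target region
#' @param connectivity_by_group named vector of target correlations rho for
#'   `control`, `remitter`, `nonremitter`
#' @param post_shift_nonremit correlation increment for the non-remitter
#'   follow-up session
#' @param subject_sd_z total between-subject SD of true voxel-wise target
#'   connectivity on the Fisher-z scale; the default 0.45 makes the planted
#'   remitter versus non-remitter gap (atanh(0.6) - atanh(0.15) = 0.54) a
#'   voxel-level d of about 1.2, the effect size the voxel-wise analysis
#'   operates on
#' @param voxel_sd_z voxel-level component of `subject_sd_z` (must be
#'   smaller): individual connectivity maps differ voxel by voxel, not only
#'   regionally; the region-shared component is
#'   sqrt(subject_sd_z^2 - voxel_sd_z^2), so region-averaged (cluster
#'   extracted) values show a larger d (~1.6 at the defaults)
#' @param noise_sd voxel noise SD (in units of the latent signal SD)
#' @param task_amplitude amplitude of the evoked task response
#' @param tissue_amplitude coupling of the global tissue signals
#' @param spike_rate expected motion spikes per run
#' @param spike_amp_mm translation amplitude of a motion spike
#' @param baseline mean image intensity (arbitrary scanner units)
#' @param signal_scale intensity SD of the fluctuating part
#' @param rng_seed integer seed making the cohort fully reproducible
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_remit = 37, n_nonremit = 38, n_control = 31,
                        grid_shape = c(24, 42, 24),
                        voxel_size_mm = 3,
                        affine = make_affine(voxel_size_mm),
                        n_runs = 5, volumes_per_run = 120, tr_s = 2.5,
                        seed_centers_mm = list(c(-11, -52, 37),
                                               c(12, -52, 35)),
                        target_center_mm = c(-2, 50, -6),
                        region_radius_mm = 7,
                        connectivity_by_group = c(control = 0.6,
                                                  remitter = 0.6,
                                                  nonremitter = 0.15),
                        post_shift_nonremit = 0.2,
                        subject_sd_z = 0.45,
                        voxel_sd_z = 0.3,
                        noise_sd = 1, task_amplitude = 2,
                        tissue_amplitude = 0.5,
                        spike_rate = 3, spike_amp_mm = 0.5,
                        baseline = 1000, signal_scale = 10,
                        rng_seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (any(c(n_remit, n_nonremit, n_control, n_runs, volumes_per_run) <= 0))
      stop("invalid spec: all counts must be positive")
    if (any(abs(connectivity_by_group) >= 1))
      stop("invalid spec: |rho| must be < 1 for every group")
    if (length(grid_shape) != 3 || any(grid_shape < 2))
      stop("invalid spec: grid_shape must be 3 positive integers")
    pts <- rbind(do.call(rbind, seed_centers_mm), target_center_mm)
    vox <- world_to_voxel(pts, affine)
    if (any(vox < 1) || any(vox > rep(grid_shape, each = nrow(vox))))
      stop("invalid spec: a region center maps outside the voxel grid")
    if (region_radius_mm <= 0 || noise_sd < 0 || spike_amp_mm < 0)
      stop("invalid spec: radii/noise/spike amplitudes must be non-negative")
    if (voxel_sd_z >= subject_sd_z)
      stop("invalid spec: voxel_sd_z must be below the total subject_sd_z")
  })
  invisible(spec)
}

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# unit-SD band-limited (default 0.01-0.08 Hz) latent signal
band_limited_signal <- function(n, tr_s, low_hz = 0.01, high_hz = 0.08) {
  x <- rnorm(n)
  y <- bandpass_filter(matrix(x, 1), low_hz, high_hz, tr_s = tr_s)[1, ]
  s <- sd(y)
  if (s == 0) return(y)
  y / s
}

truncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n); got <- 0
  while (got < n) {
    x <- rnorm(n, mean, sd)
    x <- x[x >= lo & x <= hi]
    take <- min(length(x), n - got)
    if (take) { out[(got + 1):(got + take)] <- x[seq_len(take)]; got <- got + take }
  }
  out
}

#' Simulate a realignment-parameter trace with planted motion spikes
#'
#' Produces smooth low-amplitude drift (baseline framewise displacement
#' well below 0.3 mm) plus step displacements at spike frames drawn by a
#' thinned Bernoulli process with expectation `spike_rate` per run.
#'
#' @param n_volumes volumes in the run
#' @param spike_rate expected number of spikes in the run
#' @param spike_amp_mm translation step amplitude at a spike (mm)
#' @param rng_seed optional integer seed; when NULL the current RNG stream
#'   is used
#' @return volumes x 6 matrix with attribute `spike_frames` (ground truth)
#' @export
simulate_motion_trace <- function(n_volumes, spike_rate = 3,
                                  spike_amp_mm = 0.5, rng_seed = NULL) {
  stopifnot(n_volumes > 0, spike_amp_mm >= 0, spike_rate >= 0)
  gen <- function() {
    # random-walk drift: per-frame increments far below the 0.3 mm threshold
    dtr <- matrix(rnorm(n_volumes * 3, 0, 0.015), n_volumes, 3)
    drot <- matrix(rnorm(n_volumes * 3, 0, 0.0002), n_volumes, 3)
    p <- min(1, spike_rate / n_volumes)
    spikes <- which(rbinom(n_volumes, 1, p) == 1 & seq_len(n_volumes) > 1)
    for (s in spikes) {
      ax <- sample(3, 1)
      dtr[s, ax] <- dtr[s, ax] + sample(c(-1, 1), 1) * spike_amp_mm
    }
    trace <- cbind(apply(dtr, 2, cumsum), apply(drot, 2, cumsum))
    attr(trace, "spike_frames") <- spikes
    trace
  }
  if (is.null(rng_seed)) gen() else with_seed(rng_seed, gen())
}

# simple block task design shared by all synthetic runs
default_task_design <- function(n_volumes, tr_s, name = "task") {
  dur <- n_volumes * tr_s
  onsets <- seq(20, dur - 40, by = 60)
  data.frame(condition = "stim", onset_s = onsets, duration_s = 20)
}

# draw per-subject ground truth: covariates + true connectivity by session
draw_ground_truth <- function(spec) {
  groups <- c(rep("nonremitter", spec$n_nonremit),
              rep("remitter", spec$n_remit),
              rep("control", spec$n_control))
  n <- length(groups)
  id <- sprintf("sub-%03d", seq_len(n))
  shared_sd <- sqrt(spec$subject_sd_z^2 - spec$voxel_sd_z^2)
  z1 <- atanh(spec$connectivity_by_group[groups]) +
    rnorm(n, 0, shared_sd)
  rho1 <- tanh(z1)
  rho2 <- rho1 + ifelse(groups == "nonremitter",
                        spec$post_shift_nonremit, 0)
  rho2 <- pmin(rho2, 0.95)
  age <- numeric(n); dur <- numeric(n); h0 <- numeric(n); h8 <- numeric(n)
  anx <- numeric(n); els <- numeric(n); bmi <- numeric(n)
  for (g in unique(groups)) {
    i <- groups == g
    m <- sum(i)
    if (g == "nonremitter") {
      age[i] <- truncnorm1(m, 34.98, 13.69, 18, 70)
      dur[i] <- truncnorm1(m, 14.61, 13.26, 0.5, 50)
      h0[i] <- round(truncnorm1(m, 20.50, 3.32, 16, 40))
      h8[i] <- round(truncnorm1(m, 14, 4, 8, 30))
      anx[i] <- round(truncnorm1(m, 6.87, 2.06, 0, 14))
      els[i] <- round(truncnorm1(m, 4.34, 2.09, 0, 12))
      bmi[i] <- truncnorm1(m, 25.31, 4.91, 16, 45)
    } else if (g == "remitter") {
      age[i] <- truncnorm1(m, 28.34, 7.10, 18, 70)
      dur[i] <- truncnorm1(m, 8.32, 6.48, 0.5, 50)
      h0[i] <- round(truncnorm1(m, 21.78, 4.34, 16, 40))
      h8[i] <- sample(0:7, m, replace = TRUE)
      anx[i] <- round(truncnorm1(m, 6.97, 1.89, 0, 14))
      els[i] <- round(truncnorm1(m, 3.22, 2.69, 0, 12))
      bmi[i] <- truncnorm1(m, 26.16, 6.29, 16, 45)
    } else {
      age[i] <- truncnorm1(m, 29.93, 10.91, 18, 70)
      dur[i] <- NA; h0[i] <- round(truncnorm1(m, 1.10, 1.30, 0, 6))
      h8[i] <- round(truncnorm1(m, 1.10, 1.30, 0, 6))
      anx[i] <- round(truncnorm1(m, 0.45, 0.63, 0, 4))
      els[i] <- round(truncnorm1(m, 0.88, 1.28, 0, 8))
      bmi[i] <- truncnorm1(m, 25.0, 4.0, 16, 45)
    }
  }
  patient <- groups != "control"
  ca <- integer(n)
  ca[patient] <- rbinom(sum(patient), 1, 35 / 75)
  drug <- rep(NA_character_, n)
  dose <- rep(NA_real_, n)
  drug[patient] <- sample(c("escitalopram", "sertraline", "venlafaxine"),
                          sum(patient), replace = TRUE)
  dose[patient & drug == "escitalopram"] <-
    truncnorm1(sum(patient & drug == "escitalopram", na.rm = TRUE), 12.5, 9, 5, 40)
  dose[patient & drug == "sertraline"] <-
    truncnorm1(sum(patient & drug == "sertraline", na.rm = TRUE), 59.26, 27, 25, 150)
  dose[patient & drug == "venlafaxine"] <-
    truncnorm1(sum(patient & drug == "venlafaxine", na.rm = TRUE), 90.62, 31, 37.5, 225)
  data.frame(subject_id = id, group = groups, drug_arm = drug,
             rho_ses1 = unname(rho1), rho_ses2 = unname(rho2),
             age = round(age, 1), duration_years = round(dur, 1),
             hrsd17_baseline = h0, hrsd17_week8 = h8,
             anxiety_hrsd = anx,
             comorbid_anxiety = ca,
             early_life_stressors = els,
             bmi = round(bmi, 1),
             cognitive_score = round(rnorm(n, 0, 1), 2),
             dose_mg = round(dose, 2),
             stringsAsFactors = FALSE)
}

# one BOLD run for one subject/session given true rho. The target latent is
# built from an in-sample orthonormalized pair (s, u_perp), so that with
# zero voxel noise the realized seed-target correlation equals rho exactly
# rather than within the sizeable sampling error of band-limited series.
simulate_bold_run <- function(spec, rho, task_name, seed_mask, target_mask) {
  nt <- spec$volumes_per_run
  nv <- prod(spec$grid_shape)
  s <- band_limited_signal(nt, spec$tr_s)      # seed driver
  u <- band_limited_signal(nt, spec$tr_s)      # target-specific component
  s <- (s - mean(s)) / sd(s)
  u <- u - mean(u)
  u <- u - s * sum(u * s) / sum(s * s)         # exact in-sample orthogonality
  u <- u / sd(u)
  wm <- band_limited_signal(nt, spec$tr_s)
  vent <- band_limited_signal(nt, spec$tr_s)
  task <- default_task_design(nt, spec$tr_s)
  evoked <- convolve_events(task$onset_s, task$duration_s, nt, spec$tr_s)
  trace <- simulate_motion_trace(nt, spec$spike_rate, spec$spike_amp_mm)

  dat <- matrix(rnorm(nv * nt, 0, spec$noise_sd), nv, nt)
  sv <- which(seed_mask); tv <- which(target_mask)
  dat[sv, ] <- dat[sv, ] + rep(s, each = length(sv))
  # per-voxel true connectivity varies around the subject's regional rho
  rho_v <- tanh(atanh(rho) + rnorm(length(tv), 0, spec$voxel_sd_z))
  dat[tv, ] <- dat[tv, ] + rho_v %o% s + sqrt(1 - rho_v^2) %o% u
  gain <- runif(nv, 0.5, 1.5)
  dat <- dat + gain %o% (spec$task_amplitude * evoked) +
    spec$tissue_amplitude * (gain %o% wm) +
    spec$tissue_amplitude * rep(vent, each = nv)
  dat <- spec$baseline + spec$signal_scale * dat
  structure(list(data = array(dat, dim = c(spec$grid_shape, nt)),
                 affine = spec$affine, tr_s = spec$tr_s,
                 task_name = task_name, task = task,
                 motion = trace, tissue = cbind(wm, vent),
                 spike_frames = attr(trace, "spike_frames")),
            class = "bold_run")
}

#' Generate a full synthetic cohort at the BOLD level
#'
#' For every subject and session, produces `n_runs` BOLD runs sharing the
#' grid and affine: a latent band-limited signal drives the seed region;
#' the target region receives rho * s plus an independent band-limited
#' component, so that the planted seed-target correlation equals the
#' subject's true rho; task-evoked responses, global tissue nuisance
#' signals, voxel noise, and motion traces with planted spikes are added.
#' Deterministic given `rng_seed`.
#'
#' Memory scales as grid x volumes x runs x subjects; BOLD-level cohorts
#' are intended for reduced grids/sample sizes. Group-level testing at the
#' full sample size uses [simulate_zmap_cohort()].
#'
#' @param spec a [cohort_spec()]
#' @param sessions which sessions to generate (1, 2, or both)
#' @return list with `subjects` (per subject: `id`, `group`, `sessions`,
#'   each session holding `runs`), `ground_truth` (data.frame), and
#'   `phenotype` (via [make_phenotype_table()])
#' @export
generate_cohort <- function(spec = cohort_spec(), sessions = 1:2) {
  validate_cohort_spec(spec)
  with_seed(spec$rng_seed, {
    gt <- draw_ground_truth(spec)
    seed_mask <- seed_union_mask(seed_spec(spec$seed_centers_mm, 5),
                                 spec$grid_shape, spec$affine)
    target_mask <- make_sphere_mask(spec$target_center_mm,
                                    spec$region_radius_mm,
                                    spec$grid_shape, spec$affine)
    task_names <- paste0("task", seq_len(spec$n_runs))
    subjects <- vector("list", nrow(gt))
    for (i in seq_len(nrow(gt))) {
      ses <- list()
      for (sn in sessions) {
        rho <- if (sn == 1) gt$rho_ses1[i] else gt$rho_ses2[i]
        runs <- lapply(task_names, function(tk)
          simulate_bold_run(spec, rho, tk, seed_mask, target_mask))
        names(runs) <- task_names
        ses[[paste0("ses-", sn)]] <- list(runs = runs)
      }
      subjects[[i]] <- list(id = gt$subject_id[i], group = gt$group[i],
                            sessions = ses)
    }
    list(subjects = subjects, ground_truth = gt,
         phenotype = make_phenotype_table(gt),
         seed_mask = seed_mask, target_mask = target_mask)
  })
}

#' Generate a cohort of connectivity z-maps directly (group-level world)
#'
#' Scaled-down counterpart of [generate_cohort()] for testing group
#' inference and classification at the full sample size: instead of
#' synthesizing BOLD series, each subject's Fisher-z map is drawn directly
#' from the model the BOLD generator plants - target-region voxels carry
#' the subject's true z plus correlation-estimation noise of SD
#' 1/sqrt(n_frames - 3), background voxels carry estimation noise only.
#'
#' @param spec a [cohort_spec()]
#' @param n_frames nominal retained-frame count setting estimation noise
#'   (default `n_runs * volumes_per_run`)
#' @param sessions sessions to draw
#' @return list with `zmaps` (list of lists by session), `ground_truth`,
#'   `phenotype`, `target_mask`
#' @export
simulate_zmap_cohort <- function(spec = cohort_spec(),
                                 n_frames = spec$n_runs * spec$volumes_per_run,
                                 sessions = 1) {
  validate_cohort_spec(spec)
  with_seed(spec$rng_seed, {
    gt <- draw_ground_truth(spec)
    target_mask <- make_sphere_mask(spec$target_center_mm,
                                    spec$region_radius_mm,
                                    spec$grid_shape, spec$affine)
    noise_sd <- 1 / sqrt(n_frames - 3)
    nv <- prod(spec$grid_shape)
    tv <- which(target_mask)
    zmaps <- list()
    for (sn in sessions) {
      zl <- vector("list", nrow(gt))
      for (i in seq_len(nrow(gt))) {
        z <- rnorm(nv, 0, noise_sd)
        rho <- if (sn == 1) gt$rho_ses1[i] else gt$rho_ses2[i]
        z[tv] <- atanh(rho) + rnorm(length(tv), 0, spec$voxel_sd_z) +
          rnorm(length(tv), 0, noise_sd)
        zl[[i]] <- structure(list(data = array(z, dim = spec$grid_shape),
                                  affine = spec$affine,
                                  subject = gt$subject_id[i],
                                  session = paste0("ses-", sn),
                                  seed = NULL, n_frames = n_frames,
                                  zero_variance = integer(0)),
                             class = "zmap")
      }
      zmaps[[paste0("ses-", sn)]] <- zl
    }
    list(zmaps = zmaps, ground_truth = gt,
         phenotype = make_phenotype_table(gt), target_mask = target_mask)
  })
}

#' Desk-scale cohort specification with a compact synthetic geometry
#'
#' The default grid (24 x 42 x 24 at 3 mm) is sized so the real anatomical
#' seed/target coordinates are interior; BOLD-level simulation on it is
#' heavy. This wrapper supplies a small self-consistent world - a
#' 14 x 16 x 14 grid centered on the origin with nearby synthetic seed and
#' target centers - for fast end-to-end tests. All other defaults are
#' inherited from [cohort_spec()].
#'
#' @param n_remit,n_nonremit,n_control group sizes (small defaults)
#' @param n_runs,volumes_per_run acquisition structure
#' @param rng_seed integer seed
#' @param ... further arguments passed to [cohort_spec()]
#' @return object of class `cohort_spec`
#' @export
toy_cohort_spec <- function(n_remit = 6, n_nonremit = 6, n_control = 4,
                            n_runs = 2, volumes_per_run = 120,
                            rng_seed = 1L, ...) {
  cohort_spec(n_remit = n_remit, n_nonremit = n_nonremit,
              n_control = n_control,
              grid_shape = c(14, 16, 14),
              affine = make_affine(3, c(-19.5, -22.5, -19.5)),
              n_runs = n_runs, volumes_per_run = volumes_per_run,
              seed_centers_mm = list(c(-9, -15, 9), c(9, -15, 9)),
              target_center_mm = c(0, 15, -3),
              region_radius_mm = 6,
              rng_seed = rng_seed, ...)
}

#' Planted between-group effect sizes implied by a cohort specification
#'
#' Cohen's d of target connectivity, remitters versus non-remitters,
#' implied by the planted correlations, the between-subject spread, and
#' correlation-estimation noise at `n_frames` retained frames. `"voxel"`
#' is the effect size at a single target voxel (the scale of the
#' voxel-wise analysis); `"regional"` is the effect size on the
#' region-shared (ground-truth / cluster-averaged) connectivity.
#'
#' @param spec a [cohort_spec()]
#' @param n_frames retained frames entering each subject's correlation
#' @param level `"voxel"` or `"regional"`
#' @return numeric effect size
#' @export
planted_cohens_d <- function(spec, n_frames = spec$n_runs * spec$volumes_per_run,
                             level = c("voxel", "regional")) {
  level <- match.arg(level)
  gap <- atanh(spec$connectivity_by_group[["remitter"]]) -
    atanh(spec$connectivity_by_group[["nonremitter"]])
  sdz <- if (level == "voxel") spec$subject_sd_z
         else sqrt(spec$subject_sd_z^2 - spec$voxel_sd_z^2)
  gap / sqrt(sdz^2 + 1 / (n_frames - 3))
}

#' Phenotype table from cohort ground truth
#'
#' One row per subject with all covariates and outcomes, in the CSV schema
#' written by [write_phenotype()]. Controls carry an empty drug arm.
#'
#' @param ground_truth ground-truth data.frame from [generate_cohort()] or
#'   [simulate_zmap_cohort()]
#' @return data.frame
#' @export
make_phenotype_table <- function(ground_truth) {
  need <- c("subject_id", "group", "drug_arm", "age", "duration_years",
            "hrsd17_baseline", "hrsd17_week8", "anxiety_hrsd",
            "comorbid_anxiety", "early_life_stressors", "bmi",
            "cognitive_score", "dose_mg")
  miss <- setdiff(need, names(ground_truth))
  if (length(miss))
    stop("incomplete ground truth: missing ", paste(miss, collapse = ", "))
  pat <- ground_truth$group != "control"
  bad <- pat & (is.na(ground_truth$age) | is.na(ground_truth$duration_years) |
                  is.na(ground_truth$hrsd17_baseline) |
                  is.na(ground_truth$hrsd17_week8))
  if (any(bad))
    stop("incomplete record(s): ",
         paste(ground_truth$subject_id[bad], collapse = ", "))
  ground_truth[, need]
}
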