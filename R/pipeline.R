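# Pipeline orchestration: simulate -> qc -> residuals -> connectivity ->
# group -> classify, over an on-disk dataset tree, with a JSON manifest
# capturing parameters and seeds so any stage can be re-executed.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and seeds. Serialized as JSON in
#' the output manifest.
#'
#' @param root dataset root directory (inputs)
#' @param out_dir output directory
#' @param cohort a [cohort_spec()] used by the `simulate` stage
#' @param censoring a [censoring_config()]
#' @param band band-pass edges, `c(low_hz, high_hz)`
#' @param seed a [seed_spec()]
#' @param model a [group_model_spec()]
#' @param perm a [permutation_config()]
#' @param roi_center_mm,roi_radius_mm classification ROI sphere
#' @param task_order run order; default from the cohort spec
#' @param write_residuals write residual 4D NIfTIs during `residuals`
#' @param rng_seed master seed recorded in the manifest
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(root, out_dir = file.path(root, "derivatives"),
                            cohort = cohort_spec(),
                            censoring = censoring_config(),
                            band = c(0.009, 0.08),
                            seed = seed_spec(cohort$seed_centers_mm),
                            model = group_model_spec(),
                            perm = permutation_config(),
                            roi_center_mm = cohort$target_center_mm,
                            roi_radius_mm = 10,
                            task_order = NULL,
                            write_residuals = FALSE,
                            rng_seed = 1L) {
  if (is.null(task_order))
    task_order <- paste0("task", seq_len(cohort$n_runs))
  structure(as.list(environment()), class = "pipeline_config")
}

manifest_add <- function(out_dir, stage, params, files) {
  path <- file.path(out_dir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else list()
  man[[stage]] <- list(stage = stage, params = params,
                       files = as.list(files),
                       time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# qc + residuals + band-pass + concatenation + seed map for one session
process_subject_session <- function(runs, config) {
  cens <- list(); res_runs <- list()
  for (tk in names(runs)) {
    run <- runs[[tk]]
    fd <- compute_fd(run$motion, config$censoring$rotation_radius_mm)
    ssc <- compute_scaled_signal_change(run)
    cr <- build_temporal_mask(fd, ssc, config$censoring)
    cens[[tk]] <- cr
    X <- build_design_matrix(run$task, run$motion, run$tissue, cr,
                             run$tr_s, dim(run$data)[4])
    rs <- fit_glm_residuals(run, X, censored_mask = cr$censored_mask)
    rs <- bandpass_filter(rs, config$band[1], config$band[2])
    res_runs[[tk]] <- rs
  }
  excl <- apply_exclusion_rule(cens, config$censoring)
  series <- concatenate_runs(res_runs)
  seed_series <- extract_seed_series(series, config$seed)
  list(censoring = cens, exclusion = excl, series = series,
       seed_series = seed_series)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order over the dataset tree. Every
#' output file is listed in `out_dir/manifest.json` together with the
#' stage parameters and seeds; re-running with an identical configuration
#' reproduces identical numeric outputs.
#'
#' @param config a [pipeline_config()]
#' @param stages subset of `c("simulate", "qc", "connectivity", "group",
#'   "classify")` (the residual model is computed within `qc` /
#'   `connectivity` as needed)
#' @return invisibly, a list of per-stage results
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "qc", "connectivity",
                                    "group", "classify")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  if ("simulate" %in% stages) {
    coh <- generate_cohort(config$cohort)
    dir.create(config$root, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (s in coh$subjects)
      files <- c(files, write_subject_dataset(s, config$root))
    write_phenotype(coh$phenotype, file.path(config$root, "participants.csv"))
    jsonlite::write_json(coh$ground_truth,
                         file.path(config$root, "ground_truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest_add(config$out_dir, "simulate",
                 list(rng_seed = config$cohort$rng_seed,
                      n = c(config$cohort$n_remit, config$cohort$n_nonremit,
                            config$cohort$n_control)),
                 c(file.path(config$root, "participants.csv")))
    out$simulate <- coh$ground_truth
  }

  pheno <- read_phenotype(file.path(config$root, "participants.csv"))
  subjects <- pheno$subject_id
  sessions <- intersect(c("ses-1", "ses-2"),
                        unique(unlist(lapply(subjects, function(s)
                          basename(list.dirs(file.path(config$root, s),
                                             recursive = FALSE))))))

  if (any(c("qc", "connectivity") %in% stages)) {
    qc_rows <- list(); zfiles <- character(0); qc_sum <- list()
    zdir <- file.path(config$out_dir, "zmaps")
    dir.create(zdir, showWarnings = FALSE)
    manifest_rows <- list()
    for (sid in subjects) {
      for (ses in sessions) {
        if (!dir.exists(file.path(config$root, sid, ses))) next
        ds <- load_subject_dataset(config$root, sid, ses,
                                   task_order = config$task_order)
        pr <- process_subject_session(ds$runs, config)
        qc_sum[[paste(sid, ses)]] <-
          list(subject = sid, session = ses,
               n_censored = pr$exclusion$n_censored_total,
               excluded = pr$exclusion$excluded)
        for (tk in names(pr$censoring)) {
          cr <- pr$censoring[[tk]]
          qc_rows[[paste(sid, ses, tk)]] <-
            data.frame(subject = sid, session = ses, run = tk,
                       frame = seq_along(cr$fd_trace),
                       fd = cr$fd_trace, intensity = cr$intensity_trace,
                       censored = cr$censored_mask)
        }
        if ("connectivity" %in% stages) {
          zp <- ""
          if (!pr$exclusion$excluded) {
            zm <- seed_zmap(pr$series, pr$seed_series, subject = sid,
                            session = ses, seed = config$seed)
            zp <- file.path(zdir, paste0(sid, "_", ses, "_zmap.nii.gz"))
            write_nifti(zm$data, zp, affine = zm$affine)
            zfiles <- c(zfiles, zp)
          }
          manifest_rows[[paste(sid, ses)]] <-
            data.frame(subject = sid, session = ses, path = zp,
                       retained_frames = sum(!pr$series$censored_mask),
                       excluded = pr$exclusion$excluded)
        }
      }
    }
    qc_tab <- do.call(rbind, qc_rows)
    qc_path <- file.path(config$out_dir, "qc_censoring.tsv")
    write.table(qc_tab, qc_path, sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unname(qc_sum),
                         file.path(config$out_dir, "qc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out$qc <- qc_sum
    files <- c(qc_path, file.path(config$out_dir, "qc_summary.json"))
    if ("connectivity" %in% stages) {
      mtab <- do.call(rbind, manifest_rows)
      mpath <- file.path(config$out_dir, "zmap_manifest.tsv")
      write.table(mtab, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, mpath, zfiles)
      out$connectivity <- mtab
    }
    manifest_add(config$out_dir, "qc",
                 list(censoring = unclass(config$censoring),
                      band = config$band), files)
  }

  if (any(c("group", "classify") %in% stages)) {
    mpath <- file.path(config$out_dir, "zmap_manifest.tsv")
    if (!file.exists(mpath))
      stop("stage dependency missing: run the connectivity stage first")
    mtab <- read.table(mpath, sep = "\t", header = TRUE)
    kept <- mtab[!mtab$excluded, ]
    load_maps <- function(ses) {
      rows <- kept[kept$session == ses, ]
      lapply(seq_len(nrow(rows)), function(i) {
        nii <- read_nifti(rows$path[i])
        structure(list(data = nii$data, affine = nii$affine,
                       subject = rows$subject[i], session = ses,
                       seed = config$seed, n_frames = rows$retained_frames[i],
                       zero_variance = integer(0)), class = "zmap")
      })
    }
    zm1 <- load_maps("ses-1")
    ids1 <- vapply(zm1, `[[`, character(1), "subject")
    ph <- pheno[match(ids1, pheno$subject_id), ]

    if ("group" %in% stages) {
      pat <- ph$group %in% c("remitter", "nonremitter")
      Y <- zmap_stack(zm1[pat])
      res <- permutation_cluster_fwe(Y, ph[pat, ], config$model, config$perm)
      ctab <- do.call(rbind, lapply(res$clusters, function(cl)
        data.frame(p_fwe = cl$p_fwe, extent = cl$extent,
                   peak_x = cl$peak_mm[1], peak_y = cl$peak_mm[2],
                   peak_z = cl$peak_mm[3], peak_stat = cl$peak_stat,
                   retained = cl$retained)))
      cpath <- file.path(config$out_dir, "cluster_table.tsv")
      if (is.null(ctab)) ctab <- data.frame()
      write.table(ctab, cpath, sep = "\t", row.names = FALSE, quote = FALSE)
      gres <- list(n_clusters = length(res$clusters))
      retained <- Filter(function(cl) cl$retained, res$clusters)
      if (length(retained)) {
        cl <- retained[[1]]
        vals1 <- extract_cluster_values(cl, zm1)
        gres$planned <- list()
        for (g in c("remitter", "nonremitter")) {
          sel <- ph$group %in% c(g, "control")
          gres$planned[[g]] <-
            planned_group_comparison(vals1[sel], ph$group[sel], ph$age[sel])
        }
        if ("ses-2" %in% kept$session) {
          zm2 <- load_maps("ses-2")
          ids2 <- vapply(zm2, `[[`, character(1), "subject")
          vals2 <- extract_cluster_values(cl, zm2)
          gres$paired <- list()
          for (g in c("remitter", "nonremitter", "control")) {
            sel1 <- which(ph$group == g & ids1 %in% ids2)
            if (length(sel1) >= 3) {
              pre <- vals1[sel1]
              post <- vals2[match(ids1[sel1], ids2)]
              gres$paired[[g]] <- paired_change_test(pre, post)
            }
          }
        }
        gres$d_cluster <- local({
          pat_idx <- which(ph$group %in% c("remitter", "nonremitter"))
          v <- vals1[pat_idx]; gr <- ph$group[pat_idx]
          (mean(v[gr == "remitter"]) - mean(v[gr == "nonremitter"])) /
            sd(v - stats::ave(v, gr))
        })
      }
      jsonlite::write_json(gres, file.path(config$out_dir, "group_results.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      manifest_add(config$out_dir, "group",
                   list(model = unclass(config$model),
                        perm = unclass(config$perm)),
                   c(cpath, file.path(config$out_dir, "group_results.json")))
      out$group <- res
    }

    if ("classify" %in% stages) {
      # planted target map stands in for the meta-analytic source map
      source_map <- make_sphere_mask(config$cohort$target_center_mm,
                                     config$cohort$region_radius_mm,
                                     attr(zmap_stack(zm1), "dim3"),
                                     zm1[[1]]$affine)
      roi <- build_roi_mask(source_map, zm1[[1]]$affine,
                            config$roi_center_mm, config$roi_radius_mm)
      pat <- which(ph$group %in% c("remitter", "nonremitter"))
      fc <- vapply(zm1[pat], function(z) mean(z$data[roi$mask]), numeric(1))
      lab <- label_remission(ph$hrsd17_week8[pat], ph$hrsd17_baseline[pat])
      covs <- ph[pat, config$model$covariates, drop = FALSE]
      hier <- fit_logistic_with_lr(lab$remitter, covs, fc)
      apparent <- roc_analysis(predict(hier$fit_full, type = "response"),
                               lab$remitter)
      cv <- loocv_predict(lab$remitter, covs, fc)
      cres <- list(roi_voxels = roi$n_voxels,
                   lr_chisq = hier$lr_chisq, lr_df = hier$lr_df,
                   lr_p = hier$lr_p,
                   wald_fc = unname(hier$wald["fc_z", "z"]),
                   separation = hier$separation,
                   auc_apparent = apparent$auc,
                   operating_point = apparent$operating_point,
                   auc_cv = cv$roc$auc,
                   accuracy_cv = cv$accuracy_fixed,
                   sensitivity_cv = cv$sensitivity_fixed,
                   specificity_cv = cv$specificity_fixed)
      jsonlite::write_json(cres,
                           file.path(config$out_dir, "classification.json"),
                           auto_unbox = TRUE, digits = NA)
      roc_path <- file.path(config$out_dir, "roc_curve.tsv")
      write.table(cv$roc$curve, roc_path, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      manifest_add(config$out_dir, "classify",
                   list(roi_center = config$roi_center_mm,
                        roi_radius = config$roi_radius_mm),
                   c(file.path(config$out_dir, "classification.json"),
                     roc_path))
      out$classify <- cres
    }
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `qc`, `connectivity`, `group`, `classify`, and
#' `all`, each taking `--root`, `--out`, and `--seed` overrides. Intended
#' for `Rscript -e 'dmnpredict::pipeline_cli()' <subcommand> ...`.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`)
#' @return invisibly, the pipeline result
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <simulate|qc|connectivity|group|classify|all> ",
                          "--root DIR [--out DIR] [--seed N]")
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  root <- opt("--root", "dataset")
  seed <- as.integer(opt("--seed", "1"))
  coh <- toy_cohort_spec(n_remit = as.integer(opt("--n-remit", "6")),
                         n_nonremit = as.integer(opt("--n-nonremit", "6")),
                         n_control = as.integer(opt("--n-control", "4")),
                         n_runs = as.integer(opt("--n-runs", "2")),
                         rng_seed = seed)
  config <- pipeline_config(root = root,
                            out_dir = opt("--out", file.path(root, "derivatives")),
                            cohort = coh,
                            perm = permutation_config(
                              n_permutations = as.integer(opt("--n-perm", "999")),
                              rng_seed = seed),
                            rng_seed = seed)
  stages <- if (cmd == "all") c("simulate", "qc", "connectivity", "group",
                                "classify") else cmd
  run_pipeline(config, stages)
}
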