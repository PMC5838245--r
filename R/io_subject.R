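# Dataset tree layout (BIDS-like, tool-agnostic):
#   <root>/participants.csv
#   <root>/ground_truth.json                (synthetic cohorts only)
#   <root>/<subject>/<session>/func/task-<name>_bold.nii.gz
#   <root>/<subject>/<session>/func/task-<name>_events.tsv   condition onsets
#   <root>/<subject>/<session>/func/task-<name>_motion.txt   6 columns
#   <root>/<subject>/<session>/func/task-<name>_tissue.txt   2 columns

#' Write / read a realignment trace
#'
#' Whitespace-delimited text, six columns (tx ty tz in mm, rx ry rz in
#' radians), one row per volume.
#'
#' @param trace volumes x 6 matrix
#' @param path file path
#' @return `path` (write) or the trace matrix (read)
#' @export
write_motion_trace <- function(trace, path) {
  trace <- as.matrix(trace)
  stopifnot(ncol(trace) == 6)
  write.table(format(trace, digits = 10, scientific = TRUE, trim = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop(path, ": expected 6 columns, found ", ncol(m))
  dimnames(m) <- NULL
  m
}

#' Write / read the phenotype table
#'
#' CSV with header; one row per subject with group/outcome labels, drug
#' arm, covariates, and baseline characteristics.
#'
#' @param pheno data.frame
#' @param path file path
#' @export
write_phenotype <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           na.strings = c("NA", ""), check.names = FALSE)
}

#' Write a synthetic subject's runs to the dataset tree
#'
#' @param subject a subject entry from [generate_cohort()]
#' @param root dataset root directory
#' @return invisibly, the files written
#' @export
write_subject_dataset <- function(subject, root) {
  files <- character(0)
  for (ses in names(subject$sessions)) {
    fdir <- file.path(root, subject$id, ses, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (run in subject$sessions[[ses]]$runs) {
      base <- file.path(fdir, paste0("task-", run$task_name))
      write_nifti(run$data, paste0(base, "_bold.nii.gz"),
                  affine = run$affine, tr_s = run$tr_s)
      write_motion_trace(run$motion, paste0(base, "_motion.txt"))
      write.table(format(run$tissue, digits = 10, trim = TRUE),
                  paste0(base, "_tissue.txt"), row.names = FALSE,
                  col.names = FALSE, quote = FALSE)
      if (!is.null(run$task))
        write.table(run$task, paste0(base, "_events.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
      files <- c(files, paste0(base, c("_bold.nii.gz", "_motion.txt",
                                       "_tissue.txt", "_events.tsv")))
    }
  }
  invisible(files)
}

#' Load one subject's session from a dataset tree
#'
#' Validates run count, volume counts, trace lengths, and affine
#' consistency across runs.
#'
#' @param root dataset root
#' @param subject_id subject directory name
#' @param session session directory name (default "ses-1")
#' @param task_order character vector fixing the run order
#' @return list with `runs` (list of `bold_run`) and `phenotype` (the
#'   subject's row of participants.csv, if present)
#' @export
load_subject_dataset <- function(root, subject_id, session = "ses-1",
                                 task_order = NULL) {
  fdir <- file.path(root, subject_id, session, "func")
  if (!dir.exists(fdir)) stop("no such subject/session directory: ", fdir)
  bolds <- list.files(fdir, pattern = "_bold\\.nii(\\.gz)?$")
  tasks <- sub("^task-", "", sub("_bold\\.nii(\\.gz)?$", "", bolds))
  if (!length(tasks)) stop("no BOLD runs under ", fdir)
  if (!is.null(task_order)) {
    missing <- setdiff(task_order, tasks)
    if (length(missing)) stop("missing runs for tasks: ",
                              paste(missing, collapse = ", "))
    tasks <- task_order
  } else tasks <- sort(tasks)
  runs <- list(); aff0 <- NULL
  for (tk in tasks) {
    base <- file.path(fdir, paste0("task-", tk))
    nii_path <- if (file.exists(paste0(base, "_bold.nii.gz")))
      paste0(base, "_bold.nii.gz") else paste0(base, "_bold.nii")
    nii <- read_nifti(nii_path)
    nt <- dim(nii$data)[4]
    mot_path <- paste0(base, "_motion.txt")
    if (!file.exists(mot_path)) stop("missing realignment trace: ", mot_path)
    mot <- read_motion_trace(mot_path)
    if (nrow(mot) != nt)
      stop(mot_path, ": ", nrow(mot), " rows for ", nt, " volumes")
    tis_path <- paste0(base, "_tissue.txt")
    tis <- if (file.exists(tis_path)) {
      tm <- as.matrix(read.table(tis_path)); dimnames(tm) <- NULL
      if (nrow(tm) != nt)
        stop(tis_path, ": ", nrow(tm), " rows for ", nt, " volumes")
      tm
    } else matrix(0, nt, 2)
    if (is.null(aff0)) aff0 <- nii$affine
    else if (!isTRUE(all.equal(aff0, nii$affine, tolerance = 1e-4)))
      stop("affine mismatch between runs of ", subject_id, "/", session)
    ev_path <- paste0(base, "_events.tsv")
    task <- if (file.exists(ev_path))
      read.table(ev_path, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE) else NULL
    runs[[tk]] <- structure(list(data = nii$data, affine = nii$affine,
                                 tr_s = nii$tr_s, task_name = tk,
                                 task = task, motion = mot, tissue = tis),
                            class = "bold_run")
  }
  pheno <- NULL
  ppath <- file.path(root, "participants.csv")
  if (file.exists(ppath)) {
    tab <- read_phenotype(ppath)
    pheno <- tab[tab$subject_id == subject_id, , drop = FALSE]
  }
  list(runs = runs, phenotype = pheno)
}
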