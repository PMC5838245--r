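#' Group prediction model specification
#'
#' Step-1 voxel-wise model: connectivity z ~ outcome + covariates, with an
#' optional antidepressant factor and outcome-by-drug interaction. The
#' default covariate set is baseline symptom severity, illness duration,
#' and age; the outcome contrast is remitter minus non-remitter, tested
#' one-sided by default.
#'
#' @param outcome `"remission"` (factor remitter/non-remitter) or
#'   `"percent_reduction"` (continuous symptom-reduction variant)
#' @param covariates phenotype columns entered as nuisance covariates
#' @param drug_interaction include drug main effects and the
#'   outcome-by-drug interaction; the tested statistic becomes the
#'   interaction F
#' @param sidedness `"greater"` (one-sided, remitter > non-remitter),
#'   `"less"`, or `"two_sided"`
#' @return object of class `group_model_spec`
#' @export
group_model_spec <- function(outcome = c("remission", "percent_reduction"),
                             covariates = c("age", "duration_years",
                                            "hrsd17_baseline"),
                             drug_interaction = FALSE,
                             sidedness = c("greater", "less", "two_sided")) {
  structure(list(outcome = match.arg(outcome), covariates = covariates,
                 drug_interaction = drug_interaction,
                 sidedness = match.arg(sidedness)),
            class = "group_model_spec")
}

#' Permutation inference configuration
#'
#' @param n_permutations number of label permutations (>= 100)
#' @param cluster_forming_p voxel-level forming threshold (one-sided)
#' @param fwe_alpha cluster-level family-wise error level
#' @param connectivity 6 (faces), 18 (faces+edges), or 26
#'   (faces+edges+corners) neighborhood
#' @param rng_seed optional seed for the permutation draws
#' @return object of class `permutation_config`
#' @export
permutation_config <- function(n_permutations = 1000,
                               cluster_forming_p = 0.001,
                               fwe_alpha = 0.001,
                               connectivity = 26,
                               rng_seed = NULL) {
  stopifnot(n_permutations >= 100,
            cluster_forming_p > 0, cluster_forming_p < 1,
            fwe_alpha > 0, fwe_alpha < 1,
            connectivity %in% c(6, 18, 26))
  structure(as.list(environment()), class = "permutation_config")
}

#' Percent symptom reduction
#'
#' @param baseline,week8 symptom-scale scores
#' @return (baseline - week8) / baseline * 100
#' @export
percent_reduction <- function(baseline, week8) {
  (baseline - week8) / baseline * 100
}

# build full/reduced design matrices for the group model on patients
build_group_design <- function(pheno, model) {
  pheno <- as.data.frame(pheno)
  miss_cov <- setdiff(model$covariates, names(pheno))
  if (length(miss_cov))
    stop("missing covariate column(s): ", paste(miss_cov, collapse = ", "))
  if (any(!stats::complete.cases(pheno[, model$covariates, drop = FALSE])))
    stop("covariates incomplete for some modeled subjects")
  if (model$outcome == "remission") {
    if (!all(pheno$group %in% c("remitter", "nonremitter")))
      stop("remission model expects patients only (remitter/nonremitter)")
    out_col <- as.numeric(pheno$group == "remitter")
    if (length(unique(out_col)) < 2) stop("outcome factor has a single level")
    if (min(table(out_col)) < 3) stop("need >= 3 subjects per outcome cell")
  } else {
    out_col <- percent_reduction(pheno$hrsd17_baseline, pheno$hrsd17_week8)
  }
  covs <- scale(as.matrix(pheno[, model$covariates, drop = FALSE]))
  X_red <- cbind(intercept = 1, covs)
  test_label <- if (model$outcome == "remission") "remitter" else "pct_reduction"
  X_mid <- cbind(X_red, stats::setNames(data.frame(out_col), test_label))
  X_mid <- as.matrix(X_mid); colnames(X_mid)[ncol(X_mid)] <- test_label
  if (!model$drug_interaction) {
    X_full <- X_mid
    X_reduced <- X_red
    test_cols <- test_label
    type <- "t"
  } else {
    drug <- factor(pheno$drug_arm)
    if (nlevels(drug) < 2) stop("drug factor has fewer than 2 levels")
    D <- stats::model.matrix(~drug)[, -1, drop = FALSE]
    inter <- D * out_col
    colnames(inter) <- paste0(colnames(D), ":", test_label)
    X_reduced <- cbind(X_mid, D)
    X_full <- cbind(X_reduced, inter)
    test_cols <- colnames(inter)
    type <- "F"
  }
  r <- qr(X_full)
  if (r$rank < ncol(X_full)) {
    bad <- colnames(X_full)[r$pivot[(r$rank + 1):ncol(X_full)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(X_full = X_full, X_red = X_reduced, test_cols = test_cols,
       type = type)
}

#' Voxel-wise group prediction contrast
#'
#' Least-squares fit of z ~ outcome + covariates (plus drug and
#' outcome-by-drug terms when the interaction flag is set) at every voxel.
#' Returns the remitter-minus-non-remitter t map, or the interaction F map.
#'
#' @param Y subjects x voxels matrix from [zmap_stack()], or a list of
#'   `zmap` objects
#' @param pheno phenotype data.frame aligned with the rows of `Y`
#' @param model a [group_model_spec()]
#' @return list with `stat` (3D array), `type` ("t"/"F"), `df`, `df_num`,
#'   and the designs used
#' @export
voxelwise_group_contrast <- function(Y, pheno, model = group_model_spec()) {
  if (is.list(Y) && !is.matrix(Y)) Y <- zmap_stack(Y)
  dim3 <- attr(Y, "dim3"); affine <- attr(Y, "affine")
  des <- build_group_design(pheno, model)
  n <- nrow(Y)
  if (nrow(des$X_full) != n) stop("phenotype rows do not match data rows")
  stats_v <- compute_stat_map(Y, des)
  list(stat = array(stats_v$stat, dim = dim3), type = des$type,
       df = stats_v$df, df_num = stats_v$df_num, design = des,
       dim3 = dim3, affine = affine)
}

# vectorized per-voxel t or F statistics for a prepared design
compute_stat_map <- function(Y, des) {
  X <- des$X_full
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  qf_ <- qr(X)
  Qf <- qr.Q(qf_)
  tot <- colSums(Y^2)
  rss_full <- pmax(tot - colSums((t(Qf) %*% Y)^2), 1e-300)
  if (des$type == "t") {
    XtXinv <- chol2inv(chol(crossprod(X)))
    j <- match(des$test_cols, colnames(X))
    a <- (XtXinv %*% t(X))[j, ]
    est <- as.numeric(a %*% Y)
    se <- sqrt(rss_full / df * XtXinv[j, j])
    list(stat = est / se, df = df, df_num = 1L,
         avec = a, c_xtx_c = XtXinv[j, j])
  } else {
    Qr <- qr.Q(qr(des$X_red))
    rss_red <- tot - colSums((t(Qr) %*% Y)^2)
    q <- length(des$test_cols)
    Fv <- ((rss_red - rss_full) / q) / (rss_full / df)
    list(stat = Fv, df = df, df_num = q)
  }
}

#' Permutation cluster-extent family-wise error inference
#'
#' Forms clusters of supra-threshold voxels at the cluster-forming
#' threshold, then builds the null distribution of the maximum cluster
#' extent by Freedman-Lane permutation: outcome labels are permuted on the
#' covariate-adjusted residuals, so nuisance effects are held fixed. The
#' family-wise p of each observed cluster is
#' (1 + number of permuted maxima >= observed extent) / (n_permutations + 1).
#'
#' @param Y subjects x voxels matrix (or list of `zmap`s)
#' @param pheno phenotype rows aligned with `Y`
#' @param model a [group_model_spec()]
#' @param config a [permutation_config()]
#' @return list with `clusters` (list of `cluster_result`: `voxels`,
#'   `extent`, `peak_stat`, `peak_ijk`, `peak_mm`, `p_fwe`, `retained`),
#'   `stat_map`, `threshold`, `null_max_extent`
#' @export
permutation_cluster_fwe <- function(Y, pheno, model = group_model_spec(),
                                    config = permutation_config()) {
  if (is.list(Y) && !is.matrix(Y)) Y <- zmap_stack(Y)
  dim3 <- attr(Y, "dim3"); affine <- attr(Y, "affine")
  des <- build_group_design(pheno, model)
  n <- nrow(Y)
  sm <- compute_stat_map(Y, des)
  one_sided <- des$type == "F" || model$sidedness != "two_sided"
  stat <- sm$stat
  if (des$type == "t" && model$sidedness == "less") stat <- -stat
  thresh <- if (des$type == "t") {
    if (one_sided) qt(1 - config$cluster_forming_p, sm$df)
    else qt(1 - config$cluster_forming_p / 2, sm$df)
  } else qf(1 - config$cluster_forming_p, sm$df_num, sm$df)
  supra <- if (des$type == "t" && !one_sided) abs(stat) >= thresh
           else stat >= thresh
  labels <- label_clusters_cpp(supra, as.integer(dim3),
                               as.integer(config$connectivity))
  n_clust <- max(labels)

  # Freedman-Lane: fitted + permuted residuals of the reduced model
  Qr <- qr.Q(qr(des$X_red))
  fit_red <- Qr %*% (t(Qr) %*% Y)
  res_red <- Y - fit_red
  draw <- function() {
    perms <- vapply(seq_len(config$n_permutations),
                    function(i) sample.int(n) - 1L, integer(n))
    Qf <- qr.Q(qr(des$X_full))
    perm_max_extent_cpp(fit_red, res_red, Qf, Qr,
                        if (des$type == "t") {
                          av <- sm$avec
                          if (model$sidedness == "less") -av else av
                        } else matrix(0, 1, n),
                        if (des$type == "t") sm$c_xtx_c else 1,
                        sm$df, sm$df_num, thresh, des$type == "F",
                        one_sided, as.integer(dim3),
                        as.integer(config$connectivity), perms)
  }
  null_max <- if (is.null(config$rng_seed)) draw()
              else with_seed(config$rng_seed, draw())

  clusters <- list()
  if (n_clust > 0) {
    ord <- order(tabulate(labels[labels > 0]), decreasing = TRUE)
    for (ci in ord) {
      vox <- which(labels == ci)
      ext <- length(vox)
      pk <- vox[which.max(stat[vox])]        # smallest index wins ties
      pk_ijk <- arrayInd(pk, dim3)
      p_fwe <- (1 + sum(null_max >= ext)) / (config$n_permutations + 1)
      clusters[[length(clusters) + 1]] <-
        structure(list(voxels = vox, extent = ext,
                       peak_stat = sm$stat[pk],
                       peak_ijk = as.integer(pk_ijk),
                       peak_mm = as.numeric(voxel_to_world(pk_ijk, affine)),
                       p_fwe = p_fwe,
                       retained = p_fwe <= config$fwe_alpha),
                  class = "cluster_result")
    }
  }
  list(clusters = clusters, stat_map = array(sm$stat, dim = dim3),
       type = des$type, df = sm$df, threshold = thresh,
       null_max_extent = null_max, dim3 = dim3, affine = affine)
}

#' Per-subject mean connectivity over a cluster
#'
#' @param cluster a `cluster_result` (or any object with a `voxels` index
#'   set)
#' @param zmaps list of `zmap` objects, or a subjects x voxels matrix
#' @return named numeric vector, one value per subject; subjects with a
#'   missing map yield NA with a warning
#' @export
extract_cluster_values <- function(cluster, zmaps) {
  vox <- cluster$voxels
  if (!length(vox)) stop("empty cluster")
  if (is.matrix(zmaps))
    return(rowMeans(zmaps[, vox, drop = FALSE]))
  vals <- vapply(zmaps, function(z) {
    if (is.null(z)) return(NA_real_)
    mean(z$data[vox])
  }, numeric(1))
  if (anyNA(vals)) warning("missing session map for ",
                           sum(is.na(vals)), " subject(s)")
  names(vals) <- vapply(zmaps, function(z)
    if (is.null(z)) NA_character_ else as.character(z$subject), character(1))
  vals
}

#' Planned comparison of a patient group against controls
#'
#' Dummy-coded multiple regression of cluster connectivity on group
#' membership with age as covariate; Cohen's d is recovered from the
#' adjusted contrast as t * sqrt(1/n1 + 1/n2).
#'
#' @param values cluster connectivity per subject
#' @param group two-level factor/character (e.g. remitter vs control)
#' @param age optional age covariate
#' @param ref reference level (default "control")
#' @return list with `estimate`, `t`, `p` (two-sided), `df`, `d`, `n`
#' @export
planned_group_comparison <- function(values, group, age = NULL,
                                     ref = "control") {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly two groups required")
  other <- setdiff(lev, ref)
  if (length(other) != 1) stop("reference level '", ref, "' not found")
  g01 <- as.numeric(group == other)
  n1 <- sum(g01 == 1); n2 <- sum(g01 == 0)
  if (min(n1, n2) < 3) stop("need >= 3 subjects per group")
  if (sd(values) == 0) stop("degenerate: zero variance in values")
  dat <- if (is.null(age)) data.frame(y = values, g = g01)
         else data.frame(y = values, g = g01, age = as.numeric(age))
  fit <- lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  tval <- sm["g", "t value"]
  list(estimate = sm["g", "Estimate"], t = tval,
       p = sm["g", "Pr(>|t|)"], df = fit$df.residual,
       d = tval * sqrt(1 / n1 + 1 / n2), n = c(n1 = n1, n2 = n2))
}

#' Paired pre/post change test
#'
#' One-sample t test on per-subject session differences (post - pre).
#'
#' @param values_pre,values_post paired connectivity values
#' @return list with `t`, `p` (two-sided), `df`, `mean_change`, `n`
#' @export
paired_change_test <- function(values_pre, values_post) {
  if (length(values_pre) != length(values_post))
    stop("pre/post lengths differ")
  keep <- stats::complete.cases(values_pre, values_post)
  d <- values_post[keep] - values_pre[keep]
  n <- length(d)
  if (n < 3) stop("need >= 3 complete pairs")
  if (sd(d) == 0 && mean(d) == 0)
    return(list(t = 0, p = 1, df = n - 1, mean_change = 0, n = n))
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_change = mean(d), n = n)
}

#' Pooled two-sample t test from summary statistics
#'
#' t = (mean2 - mean1) / (s_p * sqrt(1/n1 + 1/n2)) with the pooled variance
#' s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2), df = n1 + n2 - 2.
#' Used to audit printed descriptive tables.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return list with `t`, `df`, `p` (two-sided)
#' @export
summary_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  tval <- (mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}
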