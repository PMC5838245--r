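make_fake_maps <- function(n, dims, fun) {
  Y <- t(vapply(seq_len(n), fun, numeric(prod(dims))))
  attr(Y, "dim3") <- dims
  attr(Y, "affine") <- centered_affine(dims)
  Y
}

fake_pheno <- function(group) {
  n <- length(group)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = group,
             age = rnorm(n, 32, 10), duration_years = rexp(n, 0.1),
             hrsd17_baseline = rnorm(n, 21, 4),
             drug_arm = sample(c("escitalopram", "sertraline", "venlafaxine"),
                               n, replace = TRUE))
}

test_that("voxel t equals the textbook two-sample t without covariates", {
  set.seed(101)
  dims <- c(4, 4, 3)
  group <- rep(c("remitter", "nonremitter"), each = 12)
  Y <- make_fake_maps(24, dims, function(i) rnorm(prod(dims)))
  ph <- fake_pheno(group)
  model <- group_model_spec(covariates = character(0))
  res <- voxelwise_group_contrast(Y, ph, model)
  expect_equal(res$df, 22)
  oracle <- apply(Y, 2, function(v)
    unname(stats::t.test(v[group == "remitter"], v[group == "nonremitter"],
                         var.equal = TRUE)$statistic))
  expect_equal(as.numeric(res$stat), oracle, tolerance = 1e-10)
})

test_that("null data give ~5% of voxels at p < 0.05", {
  set.seed(55)
  dims <- c(10, 10, 8)                     # 800 voxels
  group <- rep(c("remitter", "nonremitter"), each = 20)
  ph <- fake_pheno(group)
  frac <- replicate(5, {
    Y <- make_fake_maps(40, dims, function(i) rnorm(prod(dims)))
    res <- voxelwise_group_contrast(Y, ph)
    mean(pt(res$stat, res$df, lower.tail = FALSE) < 0.05)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.015)
})

test_that("rank-deficient designs name the collinear column", {
  group <- rep(c("remitter", "nonremitter"), each = 6)
  ph <- fake_pheno(group)
  ph$dup <- ph$age
  expect_error(
    build_group_design(ph, group_model_spec(covariates = c("age", "dup"))),
    "collinear")
})

test_that("cluster labeling matches an igraph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(202)
  for (conn in c(6, 26)) {
    for (rep in 1:10) {
      dims <- c(7, 6, 5)
      mask <- runif(prod(dims)) < 0.25
      labels <- label_clusters_cpp(mask, as.integer(dims), as.integer(conn))
      vox <- which(mask)
      if (length(vox) < 2) next
      ijk <- arrayInd(vox, dims)
      edges <- NULL
      for (a in seq_along(vox)) for (b in seq_len(a - 1)) {
        d <- abs(ijk[a, ] - ijk[b, ])
        adj <- if (conn == 6) sum(d) == 1 else max(d) == 1
        if (adj) edges <- rbind(edges, c(a, b))
      }
      g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(vox),
                                                          seq_along(vox))),
                                       directed = FALSE)
      comp <- igraph::components(g)$membership[seq_along(vox)]
      # same partition: label pairs agree
      got <- labels[vox]
      expect_equal(outer(got, got, "=="), outer(comp, comp, "=="),
                   ignore_attr = TRUE)
    }
  }
})

test_that("permutation p-values obey the add-one rule and ordering invariance", {
  set.seed(77)
  dims <- c(6, 6, 5)
  group <- rep(c("remitter", "nonremitter"), each = 15)
  ph <- fake_pheno(group)
  eff <- as.numeric(group == "remitter") * 2
  Y <- make_fake_maps(30, dims, function(i) rnorm(prod(dims)))
  Y[, 1:12] <- Y[, 1:12] + eff             # strong planted block
  cfg <- permutation_config(n_permutations = 199, fwe_alpha = 0.05,
                            rng_seed = 11)
  res <- permutation_cluster_fwe(Y, ph, group_model_spec(), cfg)
  expect_gt(length(res$clusters), 0)
  ps <- vapply(res$clusters, `[[`, numeric(1), "p_fwe")
  expect_true(all(ps >= 1 / 200 & ps <= 1))
  expect_equal(res$clusters[[1]]$p_fwe, 1 / 200)   # exceeds all permuted maxima

  # invariance to subject ordering
  perm <- sample(30)
  Y2 <- Y[perm, ]; attr(Y2, "dim3") <- dims; attr(Y2, "affine") <- attr(Y, "affine")
  res2 <- permutation_cluster_fwe(Y2, ph[perm, ], group_model_spec(), cfg)
  expect_equal(res2$clusters[[1]]$extent, res$clusters[[1]]$extent)
  expect_equal(res2$clusters[[1]]$p_fwe, res$clusters[[1]]$p_fwe)
})

test_that("family-wise error is controlled under the global null with covariates", {
  # Freedman-Lane calibration: P(any retained at alpha 0.05) in [0.02, 0.09].
  # Max-extent permutation tests are mildly conservative because cluster
  # extents are small integers with heavy ties; a liberal forming
  # threshold and face-only adjacency keep the null granular enough for
  # the Monte-Carlo check to be informative.
  set.seed(303)
  dims <- c(16, 16, 12)
  group <- rep(c("remitter", "nonremitter"), each = 20)
  cfg <- permutation_config(n_permutations = 199, cluster_forming_p = 0.05,
                            fwe_alpha = 0.05, connectivity = 6)
  hits <- vapply(1:200, function(r) {
    ph <- fake_pheno(group)
    Y <- make_fake_maps(40, dims, function(i)
      rnorm(prod(dims)) + 0.5 * ph$age[i] / 10)   # covariate effect present
    res <- permutation_cluster_fwe(Y, ph, group_model_spec(), cfg)
    any(vapply(res$clusters, `[[`, logical(1), "retained"))
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("cluster value extraction equals the brute-force average", {
  set.seed(8)
  dims <- c(5, 5, 4)
  zmaps <- lapply(1:6, function(i)
    structure(list(data = array(rnorm(prod(dims)), dims),
                   affine = centered_affine(dims), subject = paste0("s", i),
                   session = "ses-1", n_frames = 600,
                   zero_variance = integer(0)), class = "zmap"))
  cl <- list(voxels = c(3L, 17L, 44L))
  vals <- extract_cluster_values(cl, zmaps)
  oracle <- vapply(zmaps, function(z) mean(z$data[cl$voxels]), numeric(1))
  expect_equal(unname(vals), oracle)

  one <- list(voxels = 9L)
  expect_equal(unname(extract_cluster_values(one, zmaps)[2]),
               zmaps[[2]]$data[9])
  uni <- zmaps; for (i in 1:6) uni[[i]]$data[] <- 0.7
  expect_equal(unname(extract_cluster_values(cl, uni)), rep(0.7, 6))
  expect_warning(extract_cluster_values(cl, c(zmaps[-1], list(NULL))),
                 "missing")
})

test_that("planned comparison satisfies the d-t identity and null behavior", {
  set.seed(21)
  # without covariate the d-t identity is exact
  vals <- rnorm(60)
  group <- rep(c("remitter", "control"), each = 30)
  r <- planned_group_comparison(vals, group)
  expect_equal(r$d, r$t * sqrt(1 / 30 + 1 / 30))
  # identical distributions: p roughly uniform, d near zero on average
  ps <- replicate(200, {
    v <- rnorm(40)
    planned_group_comparison(v, rep(c("remitter", "control"), each = 20),
                             age = rnorm(40, 30, 8))$p
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_error(planned_group_comparison(rnorm(4), c("a", "a", "control",
                                                    "control")), ">= 3")
})

test_that("planted regional effect is recovered by the planned comparison", {
  # planted d = 1.2 at n = 38 vs 31 -> estimate within [0.7, 1.7] mostly
  set.seed(99)
  d_est <- replicate(150, {
    v <- c(rnorm(38, 1.2, 1), rnorm(31, 0, 1))
    g <- rep(c("remitter", "control"), c(38, 31))
    planned_group_comparison(v, g, age = rnorm(69, 30, 8))$d
  })
  expect_gte(mean(d_est >= 0.7 & d_est <= 1.7), 0.9)
})

test_that("paired change test is the one-sample t on differences", {
  pre <- rnorm(20)
  expect_equal(paired_change_test(pre, pre)$t, 0)
  expect_equal(paired_change_test(pre, pre)$p, 1)
  post <- pre + rnorm(20, 0.3, 0.2)
  r <- paired_change_test(pre, post)
  tt <- t.test(post - pre)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  # planted +0.2 shift (sd 0.2, n = 38) detected in >= 90% of replicates
  set.seed(5)
  hits <- replicate(100, {
    p0 <- rnorm(38)
    paired_change_test(p0, p0 + rnorm(38, 0.2, 0.2))$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
  expect_error(paired_change_test(1:2, 2:3), ">= 3")
})

test_that("interaction model under a null interaction rarely retains clusters", {
  set.seed(404)
  dims <- c(8, 8, 6)
  cfg <- permutation_config(n_permutations = 199, fwe_alpha = 0.05)
  model <- group_model_spec(drug_interaction = TRUE)
  hits <- vapply(1:40, function(r) {
    group <- rep(c("remitter", "nonremitter"), each = 20)
    ph <- fake_pheno(group)
    # outcome main effect present, no drug interaction
    Y <- make_fake_maps(40, dims, function(i)
      rnorm(prod(dims)) + (group[i] == "remitter") * 0.5)
    res <- permutation_cluster_fwe(Y, ph, model, cfg)
    any(vapply(res$clusters, `[[`, logical(1), "retained"))
  }, logical(1))
  expect_gte(mean(!hits), 0.85)
})

test_that("summary-statistic t reproduces printed descriptive contrasts", {
  # age and illness-duration contrasts from the emulated study table
  age <- summary_two_sample_t(34.98, 13.69, 38, 28.34, 7.10, 37)
  expect_equal(age$t, -2.63, tolerance = 0.005)
  expect_equal(age$df, 73)
  expect_lt(age$p, 0.02)
  dur <- summary_two_sample_t(14.61, 13.26, 38, 8.32, 6.48, 37)
  expect_equal(dur$t, -2.60, tolerance = 0.005)
  expect_equal(summary_two_sample_t(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(summary_two_sample_t(1, 0, 10, 2, 1, 10), "positive")
  expect_error(summary_two_sample_t(1, 1, 1, 2, 1, 10), "n >= 2")
})
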