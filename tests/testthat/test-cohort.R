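test_that("subject time series are seeded-reproducible and shaped by the config", {
  cfg <- tiny_config()
  a <- generate_subject_timeseries("control", cfg, seed = 9)
  b <- generate_subject_timeseries("control", cfg, seed = 9)
  expect_identical(a, b)
  expect_equal(dim(a), c(cfg$n_rois, cfg$n_timepoints))
  expect_error(generate_subject_timeseries("mouse", cfg), "patient")
})

test_that("within-module correlation is higher for controls than patients", {
  cfg <- tiny_config()
  mods <- rep(1:3, each = 10)
  within_mean <- function(ts) {
    p <- correlation_matrix(ts)
    same <- outer(mods, mods, "==") & upper.tri(p)
    mean(p[same])
  }
  wp <- sapply(1:8, function(i)
    within_mean(generate_subject_timeseries("patient", cfg, seed = i)))
  wc <- sapply(1:8, function(i)
    within_mean(generate_subject_timeseries("control", cfg, seed = 100 + i)))
  expect_gt(mean(wc), mean(wp))
})

test_that("with no patient effect the two groups share one distribution", {
  cfg <- tiny_config(patient_effect = 0)
  # identical seeds must give bitwise-identical matrices across group labels
  expect_identical(generate_subject_timeseries("patient", cfg, seed = 3),
                   generate_subject_timeseries("control", cfg, seed = 3))
  # null calibration: two-sample test on mean within-module correlation is
  # non-significant in nearly all replicates
  mods <- rep(1:3, each = 10)
  within_mean <- function(ts) {
    p <- correlation_matrix(ts)
    mean(p[outer(mods, mods, "==") & upper.tri(p)])
  }
  pvals <- sapply(1:20, function(rep) {
    wp <- sapply(1:6, function(i)
      within_mean(generate_subject_timeseries("patient", cfg,
                                              seed = rep * 1000 + i)))
    wc <- sapply(1:6, function(i)
      within_mean(generate_subject_timeseries("control", cfg,
                                              seed = rep * 1000 + 500 + i)))
    stats::t.test(wp, wc)$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("assign_score applies the linear link, noise, and clipping", {
  cfg0 <- tiny_config(score_noise_sd = 0, score_intercept = 0,
                      score_slope = 100)
  expect_equal(assign_score(0.23, cfg0), 23)
  cfg_hi <- tiny_config(score_noise_sd = 0, score_intercept = 40,
                        score_slope = 0)
  expect_equal(assign_score(0.5, cfg_hi), 30)
  cfg_lo <- tiny_config(score_noise_sd = 0, score_intercept = -10,
                        score_slope = 0)
  expect_equal(assign_score(0.5, cfg_lo), 0)
  expect_error(assign_score(Inf, cfg0), "finite")
})

test_that("regression of generated scores on Elocal AUC recovers the slope", {
  cfg <- tiny_config(score_noise_sd = 1, score_intercept = 0,
                     score_slope = 80)
  set.seed(77)
  auc <- runif(200, 0.1, 0.3)
  scores <- sapply(seq_along(auc), function(i)
    assign_score(auc[i], cfg, seed = 5000 + i))
  fit <- stats::lm(scores ~ auc)
  expect_lt(abs(coef(fit)[["auc"]] - 80) / 80, 0.15)
})

test_that("generate_cohort is deterministic, counts subjects, and encodes the group effect", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  expect_s3_class(coh, "cohort")
  expect_equal(nrow(coh$manifest), 12)
  expect_false(any(duplicated(coh$manifest$subject_id)))
  expect_true(all(coh$manifest$score >= 0 & coh$manifest$score <= 30))
  coh2 <- generate_cohort(cfg)
  expect_identical(serialize(coh, NULL), serialize(coh2, NULL))
  m <- coh$manifest
  expect_lt(mean(m$elocal_auc[m$group == "patient"]),
            mean(m$elocal_auc[m$group == "control"]))
  expect_lt(mean(m$score[m$group == "patient"]),
            mean(m$score[m$group == "control"]))
  expect_error(cohort_config(n_patients = 0), "n_patients")
})

test_that("patient Elocal AUC deficit is stable across generator seeds", {
  deficits <- sapply(1:6, function(s) {
    cfg <- tiny_config(seed = s, patient_effect = 0.3, score_noise_sd = 0)
    m <- generate_cohort(cfg)$manifest
    mean(m$elocal_auc[m$group == "control"]) -
      mean(m$elocal_auc[m$group == "patient"])
  })
  expect_gte(mean(deficits > 0), 0.95)
})

test_that("cohorts round-trip through delimited text, manifest and YAML config", {
  cfg <- cohort_config(n_patients = 2, n_controls = 2, n_rois = 12,
                       n_timepoints = 25, module_size = 4, seed = 8)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$manifest$score, coh$manifest$score, tolerance = 1e-9)
  expect_equal(back$config, coh$config)
  for (id in names(coh$subjects))
    expect_equal(unname(back$subjects[[id]]), coh$subjects[[id]],
                 tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_rois = 2), "n_rois")
  expect_error(cohort_config(n_timepoints = 10), "n_timepoints")
  expect_error(cohort_config(score_noise_sd = -1), "score_noise_sd")
  expect_error(cohort_config(connectivity_strength_control = 1.2))
  expect_error(cohort_config(connectivity_strength_control = 0.5,
                             patient_effect = 0.6), "patient_effect")
})
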