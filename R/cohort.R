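# Synthetic two-group cohort generator. The generator emulates the study
# design the pipeline assumes: a patient group and a control group of
# 90-ROI BOLD time series whose binarised networks differ in local
# efficiency (patients lower), and a 0-30 cognition score that is a noisy
# monotone function of each subject's Elocal AUC.

#' Configuration of a synthetic cohort
#'
#' Parameters of the latent-module generative model and the score link.
#' ROIs are partitioned into consecutive modules of \code{module_size};
#' every ROI carries a shared module signal with loading
#' \code{connectivity_strength_control} (reduced by \code{patient_effect}
#' for patients) plus independent unit-variance noise, so within-module
#' correlations are higher in controls than in patients. Each subject's
#' cognition score is \code{score_intercept + score_slope * ElocalAUC}
#' plus Gaussian noise, clipped to the 0-30 scale.
#'
#' Defaults emulate a cohort of 50 patients and 40 controls with 90 regions
#' and 230 retained volumes (a typical 240-volume run minus 10 discarded
#' start-up volumes — the run length is an assumption, not a measured
#' protocol value). The score-link defaults were calibrated once against
#' the generator so that group mean scores land near 21.5 (patients) and
#' 27.4 (controls); see the methods vignette.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_rois Number of regions (default 90).
#' @param n_timepoints Timepoints per subject (default 230, >= 20).
#' @param module_size Regions per latent module (default 10).
#' @param connectivity_strength_control Latent-signal loading for controls,
#'   in (0, 1).
#' @param patient_effect Loading reduction applied to patients (>= 0, and
#'   smaller than the control loading).
#' @param score_intercept,score_slope Score-link coefficients (points, and
#'   points per unit Elocal AUC).
#' @param score_noise_sd Score noise SD in points (>= 0).
#' @param seed Master integer seed; fixes the whole cohort.
#' @return Object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_patients = 50, n_controls = 40, n_rois = 90,
                          n_timepoints = 230, module_size = 10,
                          connectivity_strength_control = 0.7,
                          patient_effect = 0.2,
                          score_intercept = -61, score_slope = 400,
                          score_noise_sd = 1.5, seed = 1) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    n_controls = assert_count(n_controls, "n_controls"),
    n_rois = assert_count(n_rois, "n_rois", min = 3L),
    n_timepoints = assert_count(n_timepoints, "n_timepoints", min = 20L),
    module_size = assert_count(module_size, "module_size", min = 2L),
    connectivity_strength_control =
      assert_number(connectivity_strength_control,
                    "connectivity_strength_control",
                    lower = 0, upper = 1, strict_lower = TRUE),
    patient_effect = assert_number(patient_effect, "patient_effect",
                                   lower = 0),
    score_intercept = assert_number(score_intercept, "score_intercept"),
    score_slope = assert_number(score_slope, "score_slope"),
    score_noise_sd = assert_number(score_noise_sd, "score_noise_sd",
                                   lower = 0),
    seed = assert_count(seed, "seed", min = 0L))
  if (cfg$connectivity_strength_control >= 1)
    stop("'connectivity_strength_control' must be < 1")
  if (cfg$patient_effect >= cfg$connectivity_strength_control)
    stop("'patient_effect' must be smaller than the control loading")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d patients / %d controls, %d ROIs x %d timepoints\n",
              x$n_patients, x$n_controls, x$n_rois, x$n_timepoints))
  cat(sprintf("  loading %.2f (controls), patient effect -%.2f; score = %.1f + %.1f * ElocalAUC + N(0, %.2f^2), clipped to [0, 30]; seed %d\n",
              x$connectivity_strength_control, x$patient_effect,
              x$score_intercept, x$score_slope, x$score_noise_sd, x$seed))
  invisible(x)
}

roi_modules <- function(config) {
  rep(seq_len(ceiling(config$n_rois / config$module_size)),
      each = config$module_size)[seq_len(config$n_rois)]
}

#' Simulate one subject's ROI time-series matrix
#'
#' @param group "patient" or "control".
#' @param config A \code{cohort_config}.
#' @param seed Integer seed; NULL uses the current random stream.
#' @return \code{n_rois x n_timepoints} numeric matrix.
#' @export
generate_subject_timeseries <- function(group, config, seed = NULL) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% c("patient", "control"))
    stop("'group' must be \"patient\" or \"control\"")
  stopifnot(inherits(config, "cohort_config"))
  loading <- config$connectivity_strength_control -
    if (group == "patient") config$patient_effect else 0
  local_seed(seed, {
    mods <- roi_modules(config)
    tp <- config$n_timepoints
    latent <- matrix(stats::rnorm(max(mods) * tp), nrow = max(mods))
    noise <- matrix(stats::rnorm(config$n_rois * tp), nrow = config$n_rois)
    loading * latent[mods, , drop = FALSE] + noise
  })
}

#' Map a local-efficiency AUC to a clinical cognition score
#'
#' score = clip(intercept + slope * elocal_auc + N(0, sd^2), 0, 30).
#'
#' @param elocal_auc Subject's Elocal AUC (finite scalar).
#' @param config A \code{cohort_config}.
#' @param seed Integer seed for the noise draw; NULL uses the current
#'   stream.
#' @return Score in [0, 30].
#' @export
assign_score <- function(elocal_auc, config, seed = NULL) {
  assert_number(elocal_auc, "elocal_auc")
  stopifnot(inherits(config, "cohort_config"))
  local_seed(seed, {
    raw <- config$score_intercept + config$score_slope * elocal_auc +
      stats::rnorm(1L, 0, config$score_noise_sd)
    min(max(raw, 0), 30)
  })
}

#' Generate a full synthetic cohort
#'
#' Simulates every subject's time series, computes each subject's Elocal
#' AUC over the standard sparsity grid (via the connectome and graph-metric
#' stages), and assigns a clinical score from it. Per-subject seeds are
#' derived from the master seed by counter, so subject generation is
#' order-independent and the whole cohort is reproducible byte-for-byte.
#'
#' @param config A \code{cohort_config}.
#' @param grid Sparsity grid used for the score-driving Elocal AUC.
#' @return Object of class \code{"cohort"}: list with \code{config},
#'   \code{subjects} (named list of time-series matrices) and
#'   \code{manifest} (data.frame: subject_id, group, score, elocal_auc).
#' @export
generate_cohort <- function(config = cohort_config(),
                            grid = sparsity_grid()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients + config$n_controls
  groups <- rep(c("patient", "control"),
                c(config$n_patients, config$n_controls))
  ids <- sprintf("sub%03d", seq_len(n))
  subjects <- vector("list", n)
  names(subjects) <- ids
  score <- elocal <- numeric(n)
  for (i in seq_len(n)) {
    ts <- generate_subject_timeseries(groups[i], config,
                                      seed = derive_seed(config$seed, "ts", i))
    z <- fisher_z(correlation_matrix(ts))
    mc <- metric_curves(z, grid = grid, metrics = "Elocal", null_n = 0)
    elocal[i] <- unname(mc$aucs["Elocal"])
    score[i] <- assign_score(elocal[i], config,
                             seed = derive_seed(config$seed, "score", i))
    subjects[[i]] <- ts
  }
  structure(list(config = config, subjects = subjects,
                 manifest = data.frame(subject_id = ids, group = groups,
                                       score = score, elocal_auc = elocal,
                                       stringsAsFactors = FALSE)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic cohort: %d subjects (%d patients, %d controls), %d ROIs x %d timepoints\n",
              nrow(m), sum(m$group == "patient"), sum(m$group == "control"),
              x$config$n_rois, x$config$n_timepoints))
  for (g in c("patient", "control"))
    cat(sprintf("  %-8s mean score %.2f (SD %.2f), mean Elocal AUC %.4f\n", g,
                mean(m$score[m$group == g]), stats::sd(m$score[m$group == g]),
                mean(m$elocal_auc[m$group == g])))
  invisible(x)
}

#' Write / read a cohort as plain text
#'
#' \code{write_cohort} writes one header-free tab-delimited matrix per
#' subject (ROIs as rows), a \code{manifest.csv} (subject_id, group, score,
#' path) and a \code{config.yaml} that round-trips the configuration.
#' \code{read_cohort} reads the directory back.
#'
#' @param cohort A \code{cohort}.
#' @param dir Output directory (created if missing).
#' @return \code{write_cohort}: the directory, invisibly;
#'   \code{read_cohort}: a \code{cohort} (without the stored
#'   \code{elocal_auc} column recomputation).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$manifest$subject_id, ".tsv"))
  for (i in seq_along(paths))
    utils::write.table(cohort$subjects[[i]], paths[i], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  man <- cohort$manifest
  man$path <- basename(paths)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_cohort_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  config <- read_cohort_config(file.path(dir, "config.yaml"))
  subjects <- lapply(file.path(dir, man$path), read_timeseries)
  names(subjects) <- man$subject_id
  man$path <- NULL
  structure(list(config = config, subjects = subjects, manifest = man),
            class = "cohort")
}

#' Round-trip a cohort configuration through YAML
#'
#' @param config A \code{cohort_config}.
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
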