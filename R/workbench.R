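#' Disease progression rate
#'
#' `(48 - ALSFRS-R) / disease duration` in points per month.
#'
#' @param alsfrs_r ALSFRS-R total score(s), 0-48.
#' @param duration_months disease duration in months, > 0.
#' @export
progression_rate <- function(alsfrs_r, duration_months) {
  if (any(alsfrs_r < 0 | alsfrs_r > 48)) stop("ALSFRS-R must be in [0, 48]")
  if (any(duration_months <= 0)) stop("disease duration must be positive")
  (48 - alsfrs_r) / duration_months
}

#' Load a cohort written by [write_cohort()]
#'
#' Reads the manifest and all per-subject files, enforces subject-ID
#' alignment across the time-series, confound and score tables, and errors
#' on duplicate IDs.  Subjects with missing scores are kept (NA); they are
#' dropped per dependent variable, with a logged count, inside
#' [run_full_analysis()].
#'
#' @param dir directory holding `manifest.json`.
#' @param roi_set ROI set to attach (default the 17-node set).
#' @return an `fc_cohort`-like bundle (no ground truth unless present).
#' @export
load_inputs <- function(dir, roi_set = default_roi_set()) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ids <- names(manifest$files$timeseries)
  if (anyDuplicated(ids)) stop("duplicate subject IDs in manifest")
  ts <- lapply(ids, function(s) {
    as.matrix(utils::read.delim(
      file.path(dir, manifest$files$timeseries[[s]]), check.names = FALSE))
  })
  motion <- lapply(ids, function(s) {
    as.matrix(utils::read.table(file.path(dir, manifest$files$motion[[s]])))
  })
  names(ts) <- names(motion) <- ids
  confounds <- utils::read.csv(file.path(dir, manifest$files$confounds))
  scores <- utils::read.csv(file.path(dir, manifest$files$scores))
  if (anyDuplicated(confounds$subject) || anyDuplicated(scores$subject)) {
    stop("duplicate subject IDs in tables")
  }
  if (!setequal(confounds$subject, ids) || !setequal(scores$subject, ids)) {
    stop("subject-ID mismatch across input files")
  }
  confounds <- confounds[match(ids, confounds$subject), ]
  scores <- scores[match(ids, scores$subject), ]
  truth <- NULL
  tf <- manifest$files$truth
  if (!is.null(tf) && file.exists(file.path(dir, tf))) {
    truth <- jsonlite::read_json(file.path(dir, tf), simplifyVector = TRUE)
  }
  structure(list(ts = ts, motion = motion, tissue = NULL,
                 confounds = confounds, scores = scores, truth = truth,
                 config = list(roi_set = roi_set,
                               tr = manifest$tr %||% 2,
                               rng_seed = manifest$seed)),
            class = "fc_cohort")
}

validate_run_config <- function(config) {
  known <- c("input_dir", "cohort", "roi", "dependent_vars", "C_grid",
             "epsilon", "k_inner", "n_perm", "rng_seed", "output_dir",
             "lesions", "specificity", "loss")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config$roi <- match.arg(config$roi %||% "base", c("base", "extended"))
  config$dependent_vars <- config$dependent_vars %||% c("ALSFRS_R", "MoCA")
  config$C_grid <- config$C_grid %||% default_C_grid()
  config$k_inner <- config$k_inner %||% 5
  config$n_perm <- config$n_perm %||% 1000
  config$rng_seed <- config$rng_seed %||% 1
  config$loss <- config$loss %||% "eps_insensitive"
  config$lesions <- config$lesions %||% list()
  config$specificity <- isTRUE(config$specificity)
  config
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the yaml package is needed for YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  validate_run_config(config)
}

#' Run the full prediction analysis
#'
#' Orchestrates the whole workflow for each dependent variable: connectivity
#' features, kernel stack (edges + confound kernel), nested LOO prediction,
#' permutation test, then optional lesion and network-specificity runs.
#' Writes a JSON report (with a provenance block: config hash, seeds,
#' package version) plus predictions/weights CSVs under `output_dir`.
#'
#' @param config named list, or path to a YAML/JSON file, with keys:
#'   `input_dir` (a [write_cohort()] directory) or `cohort` (an in-memory
#'   `fc_cohort`), `roi` ("base"/"extended"), `dependent_vars`, `C_grid`,
#'   `epsilon`, `k_inner`, `n_perm`, `rng_seed`, `output_dir`, `lesions`
#'   (list of group vectors), `specificity` (logical), `loss`.  Unknown keys
#'   are rejected.
#' @return the report list, invisibly; all artifacts are on disk.
#' @export
run_full_analysis <- function(config) {
  config <- read_run_config(config)
  out <- config$output_dir %||% stop("config needs output_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cohort <- config$cohort %||%
    load_inputs(config$input_dir,
                roi_set = default_roi_set(config$roi == "extended"))
  fc <- cohort_fc(cohort, denoise = !is.null(cohort$tissue))
  confounds <- cohort$confounds[, c("age", "gender", "mean_fd")]
  stack <- build_kernel_stack(fc, confounds)

  results <- list()
  for (dv in config$dependent_vars) {
    if (!dv %in% names(cohort$scores)) stop("no score column ", dv)
    y <- cohort$scores[[dv]]
    keep <- which(is.finite(y))
    dropped <- stack$n - length(keep)
    if (dropped > 0) {
      message(dropped, " subject(s) missing ", dv, ": excluded per-variable")
    }
    svar <- stack_rows(stack, keep)
    loo <- loo_fcmkl(svar, y[keep], C_grid = config$C_grid,
                     epsilon = config$epsilon, k_inner = config$k_inner,
                     rng_seed = config$rng_seed, loss = config$loss,
                     refit = TRUE)
    perm <- permutation_test(svar, y[keep], loo, n_perm = config$n_perm,
                             rng_seed = config$rng_seed)
    utils::write.csv(
      data.frame(subject = svar$subject, actual = y[keep], predicted =
                   loo$pred, outer_fold_C = loo$Csel),
      file.path(out, paste0("predictions_", dv, ".csv")), row.names = FALSE)
    utils::write.csv(kernel_contributions(loo$model)$kernel,
                     file.path(out, paste0("weights_", dv, ".csv")),
                     row.names = FALSE)
    lesions <- lapply(config$lesions, function(grps) {
      lesion_run(svar, y[keep], grps, full = loo, n_perm = config$n_perm,
                 C_grid = config$C_grid, epsilon = config$epsilon,
                 k_inner = config$k_inner, rng_seed = config$rng_seed,
                 loss = config$loss)$report
    })
    if (length(lesions)) {
      utils::write.csv(do.call(rbind, lesions),
                       file.path(out, paste0("lesion_", dv, ".csv")),
                       row.names = FALSE)
    }
    results[[dv]] <- list(
      n = length(keep), dropped_missing = dropped,
      r = loo$r, rmse = loo$rmse, p_r = perm$p_r, p_rmse = perm$p_rmse,
      C_full = loo$C_full,
      group_contributions = as.list(kernel_contributions(loo$model)$group),
      lesions = lesions)
  }

  bonf <- bonferroni_threshold(0.05, length(config$dependent_vars))
  cfg_for_hash <- config[setdiff(names(config), "cohort")]
  tmp <- tempfile(); jsonlite::write_json(cfg_for_hash, tmp, auto_unbox = TRUE,
                                          force = TRUE)
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("fcmkl")),
      config_hash = unname(tools::md5sum(tmp)),
      rng_seed = config$rng_seed,
      gender_coding = "1 = male, 0 = female",
      timestamp = format(Sys.time(), tz = "UTC")),
    bonferroni = list(alpha = bonf$alpha, m_tests = bonf$m_tests,
                      threshold = bonf$threshold),
    results = results)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
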