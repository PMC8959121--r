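#' Configuration of a synthetic resting-state cohort
#'
#' Defines a cohort with known connectivity-to-behavior structure: each
#' subject gets a latent ROI-ROI correlation matrix (a shared base matrix
#' whose *informative* seed edges are perturbed per subject), ROI time
#' series drawn from that matrix, random-walk motion traces, tissue noise
#' signals, confounds, and behavioral scores generated as
#' `intercept + sum_e beta_e * (z_e - z_base_e) + confound effects +
#' Gaussian noise`, clipped to the instrument range (edges enter as
#' deviations from the cohort base connectivity, so the intercept is the
#' population mean score).
#'
#' Defaults emulate the study conditions: 34 subjects, 240 volumes at
#' TR = 2 s, the 17-node ROI set, age ~ N(48.2, 11.5^2) truncated to
#' [18, 90], gender ~ Bernoulli(0.65) coded 0/1, and three score channels --
#' ALSFRS-R (range 0-48) and MoCA (0-30) driven by the same three
#' informative edges (shared connectivity fingerprint), MMSE (0-30) pure
#' noise.  Edge effects are graded across the three informative edges
#' (heterogeneous involvement) and, with the noise SDs, calibrated in a
#' pilot run so that the best linear predictor from the *measured* Fisher-z
#' edges explains half the score variance (true R^2 = 0.5); total SDs match
#' the reported cohort (about 7 for ALSFRS-R, 3 for MoCA).
#'
#' @param n_subjects number of subjects (>= 6).
#' @param n_volumes time points per subject (>= 32; default 240).
#' @param tr repetition time in seconds (default 2).
#' @param roi_set an [roi_set()] (default the 17-node set).
#' @param base_within,base_between base correlation for within-/
#'   between-network ROI pairs.
#' @param base_correlation optional named vector overriding base
#'   correlations for specific edges (`"SEED->TARGET"`), values in (-1, 1).
#' @param informative_edges edge labels carrying behavioral signal; must be
#'   seed edges of `roi_set`.
#' @param subject_edge_sd across-subject SD of the informative-edge latent z.
#' @param score_channels list of channels; each a list with `name`,
#'   `intercept`, `edge_effects` (score units per z unit, recycled over the
#'   informative edges), `confound_effects` (age, gender, mean_fd),
#'   `noise_sd`, `range`.
#' @param ar1 temporal AR(1) coefficient of the series (0 = independent
#'   draws; default 0 since correlation estimates are the target).
#' @param motion_step_sd random-walk step SDs, mm and radians.
#' @param n_tissue_voxels columns of the simulated noise-tissue matrix.
#' @param rng_seed integer seed; the whole cohort is reproducible from it.
#' @export
cohort_config <- function(n_subjects = 34, n_volumes = 240, tr = 2,
                          roi_set = default_roi_set(),
                          base_within = 0.45, base_between = 0.15,
                          base_correlation = NULL,
                          informative_edges = c("MPFC->SMA",
                                                "PCC->dmPFC",
                                                "PCC->L_insula"),
                          subject_edge_sd = 0.4,
                          score_channels = default_score_channels(),
                          ar1 = 0, motion_step_sd = c(0.02, 4e-4),
                          n_tissue_voxels = 60, rng_seed = 1) {
  stopifnot(n_subjects >= 6, n_volumes >= 32, tr > 0, subject_edge_sd >= 0)
  bad <- setdiff(informative_edges, roi_set$edges$label)
  if (length(bad)) {
    stop("informative edges not in the ROI set's seed-edge list: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(base_correlation)) {
    if (any(abs(base_correlation) >= 1)) {
      stop("invalid correlation structure: |r| >= 1 for ",
           paste(names(base_correlation)[abs(base_correlation) >= 1],
                 collapse = ", "))
    }
  }
  for (ch in score_channels) {
    stopifnot(is.character(ch$name), ch$noise_sd >= 0,
              length(ch$range) == 2)
  }
  structure(list(n_subjects = n_subjects, n_volumes = n_volumes, tr = tr,
                 roi_set = roi_set, base_within = base_within,
                 base_between = base_between,
                 base_correlation = base_correlation,
                 informative_edges = informative_edges,
                 subject_edge_sd = subject_edge_sd,
                 score_channels = score_channels, ar1 = ar1,
                 motion_step_sd = motion_step_sd,
                 n_tissue_voxels = n_tissue_voxels, rng_seed = rng_seed),
            class = "cohort_config")
}

#' Default score channels of the synthetic cohort
#'
#' ALSFRS-R and MoCA load on the same three informative edges; MMSE is pure
#' noise (no connectivity signal); disease duration (months, lognormal with
#' mean about 25 and SD about 27) is attached for progression-rate work.
#' @export
default_score_channels <- function() {
  list(
    list(name = "ALSFRS_R", intercept = 34.4,
         edge_effects = c(9.5, 6.6, 4.7),
         confound_effects = c(age = 0, gender = 0, mean_fd = 0),
         noise_sd = 4.9, range = c(0, 48)),
    list(name = "MoCA", intercept = 25.1,
         edge_effects = c(4, 2.8, 2),
         confound_effects = c(age = -0.05, gender = 0, mean_fd = 0),
         noise_sd = 2.05, range = c(0, 30)),
    list(name = "MMSE", intercept = 28.2,
         edge_effects = c(0, 0, 0),
         confound_effects = c(age = 0, gender = 0, mean_fd = 0),
         noise_sd = 2.1, range = c(0, 30)))
}

# base ROI-ROI correlation matrix from the network rules + edge overrides
base_cor_matrix <- function(config) {
  roi <- config$roi_set$roi
  R <- nrow(roi)
  net <- roi$network
  B <- matrix(config$base_between, R, R)
  for (nw in unique(net)) {
    idx <- which(net == nw)
    B[idx, idx] <- config$base_within
  }
  diag(B) <- 1
  dimnames(B) <- list(roi$name, roi$name)
  ov <- config$base_correlation
  for (lab in names(ov)) {
    e <- config$roi_set$edges[config$roi_set$edges$label == lab, ]
    if (nrow(e) == 0) stop("unknown edge in base_correlation: ", lab)
    B[e$seed, e$target] <- B[e$target, e$seed] <- ov[[lab]]
  }
  B
}

# nearest-PSD projection: eigenvalue clipping at `floor`, then diagonal
# renormalization back to unit variance
psd_project <- function(M, floor = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < floor) {
    M <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    d <- sqrt(diag(M))
    M <- M / tcrossprod(d)
  }
  (M + t(M)) / 2
}

# square root factor for sampling: M = S %*% t(S)
psd_factor <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(e$values))
}

#' Generate a synthetic cohort
#'
#' Fully reproducible from `config$rng_seed` (the caller's RNG state is left
#' untouched).  Per-subject latent correlation matrices are built by
#' perturbing the informative edges of the base matrix and projecting to the
#' nearest positive semidefinite correlation matrix (eigenvalue clipping at
#' 1e-8, diagonal renormalized), which guarantees a valid sampling
#' covariance for arbitrary perturbations.
#'
#' @param config a [cohort_config()].
#' @return object of class `fc_cohort`: `ts` (list of T x R matrices),
#'   `motion`, `tissue`, `confounds` (age, gender, mean_fd), `scores` (one
#'   column per channel plus `duration_months`), and `truth`
#'   (see [ground_truth()]).  Score-range clipping events are counted in
#'   `truth$clipped`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(config$rng_seed, {
    n <- config$n_subjects
    Tn <- config$n_volumes
    roi <- config$roi_set$roi
    R <- nrow(roi)
    B <- base_cor_matrix(config)
    edges <- config$roi_set$edges
    inf_idx <- match(config$informative_edges, edges$label)

    # per-subject latent z for every seed edge (informative ones perturbed)
    z_base <- atanh(B[cbind(edges$seed, edges$target)])
    z_lat <- matrix(rep(z_base, each = n), n, nrow(edges))
    colnames(z_lat) <- edges$label
    if (length(inf_idx)) {
      z_lat[, inf_idx] <- z_lat[, inf_idx] +
        matrix(rnorm(n * length(inf_idx), 0, config$subject_edge_sd),
               n, length(inf_idx))
    }

    ts <- vector("list", n)
    motion <- vector("list", n)
    tissue <- vector("list", n)
    mean_fd <- numeric(n)
    for (s in seq_len(n)) {
      M <- B
      M[cbind(edges$seed[inf_idx], edges$target[inf_idx])] <-
        tanh(z_lat[s, inf_idx])
      M[cbind(edges$target[inf_idx], edges$seed[inf_idx])] <-
        tanh(z_lat[s, inf_idx])
      M <- psd_project(M)
      S <- psd_factor(M)
      E <- matrix(rnorm(Tn * R), Tn, R) %*% t(S)
      if (config$ar1 > 0) {
        phi <- config$ar1
        X <- E * sqrt(1 - phi^2)
        X[1, ] <- E[1, ]
        for (t in 2:Tn) X[t, ] <- phi * X[t - 1, ] + sqrt(1 - phi^2) * E[t, ]
        E <- X
      }
      colnames(E) <- roi$name
      ts[[s]] <- E

      mo <- cbind(
        apply(matrix(rnorm(Tn * 3, 0, config$motion_step_sd[1]), Tn, 3),
              2, cumsum),
        apply(matrix(rnorm(Tn * 3, 0, config$motion_step_sd[2]), Tn, 3),
              2, cumsum))
      colnames(mo) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
      motion[[s]] <- mo
      mean_fd[s] <- compute_fd(mo)$mean_fd

      V <- config$n_tissue_voxels
      L <- matrix(rnorm(Tn * 3), Tn, 3)
      W <- matrix(rnorm(3 * V), 3, V)
      tissue[[s]] <- L %*% W + matrix(rnorm(Tn * V, 0, 0.5), Tn, V)
    }
    names(ts) <- names(motion) <- names(tissue) <-
      sprintf("sub%03d", seq_len(n))

    age <- rnorm(n, 48.2, 11.5)
    age <- pmin(90, pmax(18, age))
    gender <- rbinom(n, 1, 0.65)
    confounds <- data.frame(subject = names(ts), age = age, gender = gender,
                            mean_fd = mean_fd)

    duration <- rlnorm(n, meanlog = 2.826, sdlog = 0.877)
    scores <- data.frame(subject = names(ts))
    truth_scores <- list()
    clipped <- integer(0)
    betas <- list()
    for (ch in config$score_channels) {
      beta <- rep_len(ch$edge_effects, length(inf_idx))
      ce <- ch$confound_effects
      # edges enter as deviations from the cohort base z, so the intercept
      # is the population mean score
      zc <- sweep(z_lat[, inf_idx, drop = FALSE], 2, z_base[inf_idx])
      signal <- ch$intercept +
        (if (length(inf_idx)) drop(zc %*% beta) else 0) +
        ce[["age"]] * age + ce[["gender"]] * gender +
        ce[["mean_fd"]] * mean_fd
      noisy <- signal + rnorm(n, 0, ch$noise_sd)
      clip <- pmin(ch$range[2], pmax(ch$range[1], noisy))
      clipped[ch$name] <- sum(clip != noisy)
      scores[[ch$name]] <- clip
      truth_scores[[ch$name]] <- signal
      betas[[ch$name]] <- setNames(beta, config$informative_edges)
    }
    scores$duration_months <- duration

    truth <- list(z_latent = z_lat,
                  informative_edges = config$informative_edges,
                  coefficients = betas,
                  true_scores = truth_scores,
                  clipped = clipped,
                  rng_seed = config$rng_seed)
    structure(list(ts = ts, motion = motion, tissue = tissue,
                   confounds = confounds, scores = scores,
                   truth = truth, config = config),
              class = "fc_cohort")
  })
}

#' Generate a signal-free cohort
#'
#' As [generate_cohort()] but with every behavioral coefficient (edge and
#' confound effects) set to zero: scores are intercept + noise, clipped.
#'
#' @param config a [cohort_config()].
#' @export
make_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$score_channels <- lapply(config$score_channels, function(ch) {
    ch$edge_effects <- 0 * ch$edge_effects
    ch$confound_effects[] <- 0
    ch
  })
  generate_cohort(config)
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort an `fc_cohort`.
#' @return list: `z_latent` (subjects x edges latent Fisher z),
#'   `informative_edges`, per-channel generative `coefficients` and
#'   noise-free `true_scores`, clipping counts, and the seed.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "fc_cohort"))
  cohort$truth
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat("synthetic cohort:", length(x$ts), "subjects,",
      nrow(x$ts[[1]]), "volumes x", ncol(x$ts[[1]]), "ROIs\n")
  cat("informative edges:",
      paste(x$truth$informative_edges, collapse = ", "), "\n")
  if (any(x$truth$clipped > 0)) {
    cl <- x$truth$clipped[x$truth$clipped > 0]
    cat("score clipping events:",
        paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Connectivity features of a synthetic cohort
#'
#' Runs the packaged signal pipeline on every subject: nuisance regression
#' (motion + derivatives + tissue components + trend), band-pass of the
#' residuals, then seed connectivity.
#'
#' @param cohort an `fc_cohort`.
#' @param denoise run the nuisance-regression step (default TRUE)?
#' @export
cohort_fc <- function(cohort, denoise = TRUE) {
  nuis <- if (denoise) {
    lapply(seq_along(cohort$ts), function(s) {
      build_nuisance(cohort$motion[[s]], cohort$tissue[[s]])
    })
  }
  fc_features(cohort$ts, cohort$config$roi_set, nuisance_list = nuis,
              tr = cohort$config$tr)
}

#' Write a cohort to disk (TSV/CSV/JSON)
#'
#' Per-subject time-series TSV (ROI-named columns), 6-column motion text,
#' confound CSV, scores CSV, ground-truth JSON, and a manifest JSON listing
#' all files and the seed.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(timeseries = character(0), motion = character(0))
  for (s in names(cohort$ts)) {
    f <- file.path(dir, paste0(s, "_timeseries.tsv"))
    utils::write.table(cohort$ts[[s]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files$timeseries[s] <- basename(f)
    f <- file.path(dir, paste0(s, "_motion.txt"))
    utils::write.table(cohort$motion[[s]], f, sep = " ",
                       row.names = FALSE, col.names = FALSE)
    files$motion[s] <- basename(f)
  }
  utils::write.csv(cohort$confounds, file.path(dir, "confounds.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$z_latent <- as.data.frame(truth$z_latent)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = cohort$config$rng_seed,
                   n_subjects = length(cohort$ts),
                   n_volumes = nrow(cohort$ts[[1]]),
                   tr = cohort$config$tr,
                   files = list(timeseries = as.list(files$timeseries),
                                motion = as.list(files$motion),
                                confounds = "confounds.csv",
                                scores = "scores.csv",
                                truth = "truth.json"))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}
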