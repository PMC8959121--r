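test_that("cohort generation is reproducible and leaves the RNG alone", {
  cfg <- cohort_config(n_subjects = 6, n_volumes = 40, rng_seed = 42)
  set.seed(999)
  before <- rnorm(1)
  set.seed(999)
  c1 <- generate_cohort(cfg)
  after <- rnorm(1)
  expect_equal(after, before)            # caller's RNG stream untouched
  c2 <- generate_cohort(cfg)
  expect_identical(c1$ts, c2$ts)         # byte-identical cohorts
  expect_identical(c1$scores, c2$scores)
  c3 <- generate_cohort(cohort_config(n_subjects = 6, n_volumes = 40,
                                      rng_seed = 43))
  expect_false(identical(c1$scores, c3$scores))
})

test_that("long runs reproduce the latent edge correlation", {
  # single informative edge at true r = 0.5; with T = 20000 the empirical
  # Fisher z of the raw series must sit within 0.03 of atanh(0.5) for every
  # subject (direct Pearson correlation as the oracle)
  cfg <- cohort_config(n_subjects = 6, n_volumes = 20000,
                       informative_edges = "MPFC->SMA",
                       base_correlation = c("MPFC->SMA" = 0.5),
                       subject_edge_sd = 0, rng_seed = 7)
  coh <- generate_cohort(cfg)
  for (s in seq_along(coh$ts)) {
    z <- atanh(cor(coh$ts[[s]][, "MPFC"], coh$ts[[s]][, "SMA"]))
    expect_lt(abs(z - atanh(0.5)), 0.03)
  }
})

test_that("null generator: no score-connectivity association", {
  # all behavioral coefficients zero: across many seeds the mean sample
  # correlation between scores and each edge's latent z is ~0
  n <- 12
  m <- replicate(100, {
    coh <- make_null_cohort(cohort_config(
      n_subjects = n, n_volumes = 32,
      rng_seed = sample.int(1e6, 1)))
    cor(coh$scores$ALSFRS_R, coh$truth$z_latent[, coh$truth$informative_edges])
  })
  expect_lt(abs(mean(m)), 2 / sqrt(100 * n))
})

test_that("null scores are intercept + clipped noise with the right spread", {
  cfg <- cohort_config(n_subjects = 200, n_volumes = 32, rng_seed = 11)
  coh <- make_null_cohort(cfg)
  tr <- ground_truth(coh)
  expect_true(all(unlist(lapply(tr$coefficients, function(b) b == 0))))
  noise_sd <- cfg$score_channels[[1]]$noise_sd
  expect_lt(abs(sd(coh$scores$ALSFRS_R) - noise_sd) / noise_sd, 0.15)
  expect_true(all(coh$scores$ALSFRS_R >= 0 & coh$scores$ALSFRS_R <= 48))
})

test_that("across-subject variance of informative-edge z is faithful", {
  cfg <- cohort_config(n_subjects = 500, n_volumes = 32, rng_seed = 5)
  coh <- generate_cohort(cfg)
  z <- coh$truth$z_latent[, coh$truth$informative_edges]
  for (j in seq_len(ncol(z))) {
    expect_lt(abs(sd(z[, j]) - cfg$subject_edge_sd) / cfg$subject_edge_sd,
              0.10)
  }
})

test_that("extreme perturbations still give valid sampling covariances", {
  cfg <- cohort_config(n_subjects = 8, n_volumes = 40, subject_edge_sd = 1.5,
                       rng_seed = 3)
  coh <- generate_cohort(cfg)  # PSD projection must absorb any perturbation
  for (s in seq_along(coh$ts)) expect_true(all(is.finite(coh$ts[[s]])))
  # empirical correlation matrices are proper
  C <- cor(coh$ts[[1]])
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("config validation", {
  expect_error(cohort_config(n_subjects = 4), "n_subjects")
  expect_error(cohort_config(informative_edges = "SMA->MPFC"),
               "not in the ROI set")
  expect_error(cohort_config(base_correlation = c("MPFC->SMA" = 1.2)),
               "invalid correlation structure")
})

test_that("ground truth round-trips through write/load", {
  coh <- quick_cohort(n = 6, seed = 9, n_volumes = 40)
  tr <- ground_truth(coh)
  expect_equal(tr$informative_edges,
               coh$config$informative_edges)
  d <- file.path(tempdir(), "cohort-rt")
  write_cohort(coh, d)
  back <- load_inputs(d)
  expect_equal(back$truth$informative_edges, tr$informative_edges)
  expect_equal(unname(as.matrix(back$truth$z_latent)),
               unname(tr$z_latent), tolerance = 1e-12)
  # informative labels are a subset of the kernel labels built downstream
  fc <- cohort_fc(coh, denoise = FALSE)
  st <- build_kernel_stack(fc, coh$confounds[, c("age", "gender", "mean_fd")])
  expect_true(all(tr$informative_edges %in% st$labels))
  unlink(d, recursive = TRUE)
})

test_that("clipping events are counted", {
  cfg <- cohort_config(n_subjects = 50, n_volumes = 32, rng_seed = 2)
  # force heavy ceiling: intercept right at the maximum
  cfg$score_channels[[1]]$intercept <- 47
  coh <- generate_cohort(cfg)
  expect_gt(coh$truth$clipped[["ALSFRS_R"]], 0)
  expect_true(all(coh$scores$ALSFRS_R <= 48))
})
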