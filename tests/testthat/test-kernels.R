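test_that("linear kernel is the row inner-product matrix", {
  expect_equal(linear_kernel(matrix(c(1, -1), 2, 1)),
               matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(linear_kernel(diag(2)), diag(2))
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3)
  K <- linear_kernel(X)
  # brute-force double loop oracle
  Kb <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) Kb[i, j] <- sum(X[i, ] * X[j, ])
  expect_equal(K, Kb)
  expect_error(linear_kernel(matrix(1, 1, 3)), "n >= 2")
})

test_that("kernel centering: projection property, idempotence, no leakage", {
  set.seed(2)
  X <- matrix(rnorm(8 * 2), 8, 2)
  K <- linear_kernel(X)
  train <- 1:5
  Kc <- center_kernel(K, train)
  # training-block rows sum to ~0
  expect_lt(max(abs(rowSums(Kc[train, train]))), 1e-8)
  # idempotent on the training block
  Kcc <- center_kernel(Kc, train)
  expect_equal(Kcc[train, train], Kc[train, train], tolerance = 1e-12)
  # constant feature -> exactly zero kernel
  K1 <- linear_kernel(matrix(3, 6, 1))
  expect_equal(max(abs(center_kernel(K1, 1:6))), 0)
  # test rows use training means only: altering a test subject's feature
  # must not change the training block
  X2 <- X; X2[7, ] <- X2[7, ] + 100
  Kc2 <- center_kernel(linear_kernel(X2), train)
  expect_equal(Kc2[train, train], Kc[train, train])
  # and centering in kernel space equals centering the features
  Xc <- sweep(X, 2, colMeans(X[train, , drop = FALSE]))
  expect_equal(Kc, linear_kernel(Xc), ignore_attr = TRUE)
})

test_that("kernel normalization: unit mean training diagonal", {
  expect_equal(normalize_kernel(2 * diag(2)), diag(2), ignore_attr = TRUE)
  expect_error(normalize_kernel(matrix(0, 3, 3)), "degenerate kernel")
  set.seed(3)
  K <- linear_kernel(matrix(rnorm(21), 7, 3))
  tr <- 2:6
  Kn <- normalize_kernel(K, tr)
  expect_equal(sum(diag(Kn)[tr]), length(tr), tolerance = 1e-8)
})

test_that("build_kernel_stack: one kernel per edge plus one confound kernel", {
  coh <- quick_cohort(n = 8, seed = 2)
  fc <- cohort_fc(coh, denoise = FALSE)
  conf <- coh$confounds[, c("age", "gender", "mean_fd")]
  st <- build_kernel_stack(fc, conf)
  expect_equal(st$M, 32L)  # 31 edges + 1 confound kernel
  expect_equal(st$groups[st$M], "CONFOUND")
  expect_length(st$zcols, 3L)

  ext <- generate_cohort(cohort_config(n_subjects = 8, rng_seed = 2,
                                       roi_set = default_roi_set(TRUE)))
  st40 <- build_kernel_stack(cohort_fc(ext, denoise = FALSE),
                             ext$confounds[, c("age", "gender", "mean_fd")])
  expect_equal(st40$M, 40L)

  # group partition: every kernel in exactly one lesion group
  lg <- fcmkl:::edge_lesion_group(st$groups)
  expect_true(all(lg %in% c("SMN", "DMN", "FPN", "SN", "CONFOUND")))
  expect_equal(sum(st$groups == "DMN-core"), 1L)

  expect_error(build_kernel_stack(fc, conf[1:3, ]), "misalignment")
  bad <- conf; bad$gender[1] <- 2
  expect_error(build_kernel_stack(fc, bad), "0/1")
})

test_that("fit-time preprocessing equals explicit kernel centering+normalization", {
  # the solver works on preprocessed features; its implied kernels must be
  # exactly center_kernel + normalize_kernel of the raw kernels
  st <- toy_stack(n = 9, M = 3, seed = 4, confound = TRUE)
  train <- seq_len(st$n)
  prep <- fcmkl:::stack_prep(st, train)
  X <- fcmkl:::apply_stack_prep(st, prep, train)
  for (m in seq_len(st$M)) {
    cols <- which(st$grp == m - 1L)
    Fm <- st$F[, cols, drop = FALSE]
    if (m == st$M) {  # confound kernel: z-scored columns first
      Fm <- scale(Fm)
    }
    Kref <- normalize_kernel(center_kernel(linear_kernel(Fm), train), train,
                             unit = "trace")
    Kimp <- linear_kernel(X[, cols, drop = FALSE])
    expect_equal(Kimp, Kref, ignore_attr = TRUE, tolerance = 1e-10)
    # PSD and symmetric
    expect_lt(max(abs(Kimp - t(Kimp))), 1e-10)
    expect_gt(min(eigen(Kimp, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("lesion subsetting removes whole groups and guards the stack", {
  coh <- quick_cohort(n = 8, seed = 5)
  st <- build_kernel_stack(cohort_fc(coh, denoise = FALSE),
                           coh$confounds[, c("age", "gender", "mean_fd")])
  sub <- subset_stack(st, c("SMN", "CONFOUND"))
  expect_equal(sub$M, 32L - 6L - 1L)
  expect_false(any(fcmkl:::edge_lesion_group(sub$groups) %in%
                     c("SMN", "CONFOUND")))
  expect_length(sub$zcols, 0L)
  # DMN lesion takes the DMN-core edge with it
  subd <- subset_stack(st, "DMN")
  expect_false(any(subd$groups %in% c("DMN", "DMN-core")))
  expect_error(subset_stack(st, c("SMN", "DMN", "FPN", "SN")),
               "remove all connectivity kernels")
  expect_identical(subset_stack(st, character(0)), st)
})
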