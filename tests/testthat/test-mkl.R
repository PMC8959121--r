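test_that("constant response gives the null model exactly", {
  st <- toy_stack(n = 10, M = 4, seed = 1)
  f <- fcmkl(st, rep(5, 10), C = 10, epsilon = 0.5)
  expect_equal(unname(coef(f)), rep(0, 4))
  expect_equal(f$b, 5)
  expect_equal(f$objective, 0)
  expect_true(kernel_contributions(f)$null_model)
  expect_equal(predict(f, newdata = st$F), rep(5, 10))
})

test_that("sparsity: a predictive kernel beats pure-noise kernels", {
  set.seed(2)
  n <- 14
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, 0, 0.05)
  F <- cbind(x, matrix(rnorm(n * 3), n, 3))
  st <- structure(list(F = F, grp = 0:3, M = 4, labels = paste0("K", 1:4),
                       groups = rep("FC", 4), zcols = integer(), n = n,
                       subject = paste0("s", 1:n)), class = "kernel_stack")
  f <- fcmkl(st, y, C = 100)
  kc <- kernel_contributions(f)
  expect_lt(sum(kc$kernel$contribution[-1]), 0.05)  # noise weight < 5%
  expect_gt(kc$kernel$contribution[1], 0.95)
})

test_that("objective matches the generic convex-programming reference", {
  # small spot-check; the full 20-instance sweep runs in the acceptance suite
  set.seed(3)
  for (i in 1:3) {
    n <- 10 + i
    st <- toy_stack(n = n, M = 3 + i, seed = i, confound = TRUE)
    y <- rnorm(n)
    C <- c(0.1, 1, 10)[i]
    eps <- 0.1 * sd(y)
    fit <- fcmkl(st, y, C = C, epsilon = eps)
    oo <- scipy_reference_objective(st, y, C, eps)
    expect_lt(abs(fit$objective - oo) / max(1e-12, abs(oo)), 1e-4)
    # independent recomputation of the objective at the returned solution
    expect_lt(abs(primal_objective(st, fit) - fit$objective) /
                max(1, fit$objective), 1e-8)
    # the dual bound never exceeds the primal
    expect_lte(fit$dual_lb, fit$objective + 1e-8)
  }
})

test_that("single-kernel fit agrees with an independent eps-SVR solver", {
  skip_if_not_installed("kernlab")
  set.seed(4)
  ok <- 0
  for (i in 1:6) {
    n <- 12
    st <- toy_stack(n = n, M = 1, seed = 100 + i)
    y <- st$F[, 1] * 1.5 + rnorm(n, 0, 0.4)
    C <- c(1, 10, 100)[1 + i %% 3]
    eps <- 0.1 * sd(y)
    fit <- fcmkl(st, y, C = C, epsilon = eps)
    d1 <- unname(coef(fit))
    if (d1 < 1e-6) next
    # at the optimum the single-kernel block-L1 problem equals standard
    # eps-SVR (penalty ||w||^2/2) on the kernel scaled by the fitted
    # weight, so the reference solver's objective + d1/2 reproduces ours
    prep <- fcmkl:::stack_prep(st, seq_len(n))
    X <- fcmkl:::apply_stack_prep(st, prep, seq_len(n))
    K <- tcrossprod(X) * d1
    sv <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                        C = C, epsilon = eps, scaled = FALSE)
    f_ref <- drop(kernlab::predict(
      sv, kernlab::as.kernelMatrix(K[, kernlab::SVindex(sv), drop = FALSE])))
    # rank-1 kernel: exact basis change recovers the reference coefficient
    co <- coef(lm(f_ref ~ drop(X)))
    obj_ref <- 0.5 * co[[2]]^2 / d1 +
      C * sum(pmax(0, abs(y - f_ref) - eps)) + d1 / 2
    expect_lt(abs(fit$objective - obj_ref) / max(1, obj_ref), 1e-4)
    ok <- ok + 1
  }
  expect_gte(ok, 3)
})

test_that("interpolation limit: eps = 0 and huge C fits training scores", {
  set.seed(5)
  n <- 10
  G <- tcrossprod(matrix(rnorm(n * n), n, n))
  f <- fcmkl(list(G), rnorm(n), C = 1e6, epsilon = 0,
             control = mkl_control(tol_kkt = 1e-7))
  expect_lt(max(abs(fitted(f) - f$y)), 1e-3)
})

test_that("prediction mechanics: zero model, duplicates, cross kernels", {
  st <- toy_stack(n = 12, M = 3, seed = 6)
  set.seed(6)
  y <- drop(st$F %*% c(1, 0.5, 0)) + rnorm(12, 0, 0.2)
  f <- fcmkl(st, y, C = 10)
  # duplicating a test subject duplicates its prediction
  nd <- st$F[c(3, 3, 7), ]
  p <- predict(f, newdata = nd)
  expect_equal(p[1], p[2])
  # cross-kernel path must agree with the feature path for FC-only stacks
  cross <- lapply(seq_len(st$M), function(m) {
    Fall <- rbind(st$F, nd)
    K <- linear_kernel(Fall[, m, drop = FALSE])
    Kc <- center_kernel(K, train = 1:12)
    Kn <- normalize_kernel(Kc, train = 1:12, unit = "trace")
    out <- Kn[13:15, 1:12, drop = FALSE]
    attr(out, "centered") <- TRUE; attr(out, "normalized") <- TRUE
    out
  })
  expect_equal(predict(f, cross_kernels = cross), p, tolerance = 1e-4)
  # state flags are checked
  raw <- lapply(cross, function(K) { attributes(K) <- list(dim = dim(K)); K })
  expect_error(predict(f, cross_kernels = raw), "kernel state mismatch")
  expect_error(predict(f, newdata = st$F[, 1:2]), "kernel state mismatch")
})

test_that("contributions are permutation-invariant and normalized", {
  st <- signal_stack(n = 16, M = 5, k_signal = 2, seed = 7)
  f <- fcmkl(st$stack, st$y, C = 10)
  kc <- kernel_contributions(f)
  expect_equal(sum(kc$kernel$contribution), 1)
  expect_true(all(kc$kernel$weight >= 0))
  # reorder kernels: contributions follow labels
  st2 <- st$stack
  ord <- c(3, 1, 5, 2, 4)
  st2$F <- st2$F[, ord]; st2$labels <- st2$labels[ord]
  st2$grp <- as.integer(0:4)
  f2 <- fcmkl(st2, st$y, C = 10)
  kc2 <- kernel_contributions(f2)
  m <- match(kc$kernel$label, kc2$kernel$label)
  expect_equal(kc2$kernel$contribution[m], kc$kernel$contribution,
               tolerance = 1e-4)
})

test_that("C -> 0 limit: null model with the tube location as intercept", {
  st <- toy_stack(n = 11, M = 3, seed = 8)
  set.seed(8)
  y <- rnorm(11, 20, 4)
  eps <- 0.1 * sd(y)
  f <- fcmkl(st, y, C = 1e-6, epsilon = eps)
  expect_true(kernel_contributions(f)$null_model)
  # b minimizes the eps-insensitive location loss (grid-search oracle)
  loss <- function(b) sum(pmax(0, abs(y - b) - eps))
  bg <- seq(min(y), max(y), length.out = 20001)
  expect_lt(loss(f$b) - min(vapply(bg, loss, numeric(1))), 1e-6)
})

test_that("active-kernel count is non-decreasing in C on a fixture", {
  st <- signal_stack(n = 18, M = 6, k_signal = 2, noise = 0.5, seed = 9)
  nact <- vapply(default_C_grid(), function(C) {
    f <- fcmkl(st$stack, st$y, C = C, epsilon = 0.1 * sd(st$y))
    sum(kernel_contributions(f)$kernel$weight > 0)
  }, numeric(1))
  expect_true(all(diff(nact) >= 0))
})

test_that("squared-loss variant fits and matches a ridge oracle when dense", {
  set.seed(10)
  n <- 15
  st <- toy_stack(n = n, M = 2, seed = 10)
  y <- drop(st$F %*% c(2, -1)) + rnorm(n, 0, 0.3)
  f <- fcmkl(st, y, C = 100, loss = "squared")
  expect_gt(cor(fitted(f), y), 0.95)
  expect_lte(f$dual_lb, f$objective + 1e-8)
})
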