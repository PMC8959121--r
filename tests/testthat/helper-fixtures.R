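# shared fixtures built in code

# a tiny feature-backed stack of rank-1 kernels (plus optionally one
# multi-feature kernel), mimicking edge kernels + a confound kernel
toy_stack <- function(n = 12, M = 4, seed = 1, confound = FALSE) {
  set.seed(seed)
  dims <- rep(1, M)
  if (confound) dims[M] <- 3
  F <- matrix(rnorm(n * sum(dims)), n)
  grp <- rep(seq_len(M) - 1L, dims)
  structure(list(F = F, grp = as.integer(grp), M = M,
                 labels = paste0("K", seq_len(M)),
                 groups = c(rep("FC", M - confound),
                            if (confound) "CONFOUND"),
                 zcols = if (confound) (sum(dims) - 2):sum(dims) else integer(),
                 n = n, subject = paste0("s", seq_len(n))),
            class = "kernel_stack")
}

# a small cohort-like stack with signal on known kernels
signal_stack <- function(n = 20, M = 8, k_signal = 2, noise = 0.3,
                         seed = 1) {
  set.seed(seed)
  F <- matrix(rnorm(n * M), n, M)
  y <- drop(F[, seq_len(k_signal), drop = FALSE] %*%
              rep(1, k_signal)) + rnorm(n, 0, noise)
  st <- structure(list(F = F, grp = as.integer(seq_len(M) - 1L), M = M,
                       labels = paste0("K", seq_len(M)),
                       groups = rep("FC", M), zcols = integer(), n = n,
                       subject = paste0("s", seq_len(n))),
                  class = "kernel_stack")
  list(stack = st, y = y, signal = seq_len(k_signal))
}

# objective of the block-L1 MKL problem evaluated directly at the fit's
# returned coefficients, independent of the solver's own bookkeeping
primal_objective <- function(stack, fit) {
  prep <- fcmkl:::stack_prep(stack, seq_len(stack$n),
                             unit_trace = fit$kernel_norm == "trace")
  X <- fcmkl:::apply_stack_prep(stack, prep, seq_len(stack$n))
  pen <- sum(vapply(seq_len(stack$M) - 1L, function(g) {
    sqrt(sum(fit$w[stack$grp == g]^2))
  }, numeric(1)))
  r <- fit$y - drop(X %*% fit$w) - fit$b
  loss <- if (fit$loss == "squared") sum(r^2) else {
    sum(pmax(0, abs(r) - fit$epsilon))
  }
  pen + fit$C * loss
}

# run the scipy reference solver on a stack's preprocessed features
scipy_reference_objective <- function(stack, y, C, eps) {
  prep <- fcmkl:::stack_prep(stack, seq_len(stack$n))
  X <- fcmkl:::apply_stack_prep(stack, prep, seq_len(stack$n))
  pf <- tempfile(fileext = ".json")
  of <- tempfile(fileext = ".json")
  jsonlite::write_json(list(X = X, grp = stack$grp, y = y, C = C, eps = eps),
                       pf, digits = NA, auto_unbox = TRUE)
  script <- system.file("python", "mkl_reference.py", package = "fcmkl",
                        mustWork = TRUE)
  status <- system2("python", c(script, pf, of))
  stopifnot(status == 0)
  jsonlite::read_json(of)$objective
}

# quick cohort for pipeline tests
quick_cohort <- function(n = 12, seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n, rng_seed = seed, ...))
}
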