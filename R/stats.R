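#' Permutation test for nested-CV predictive performance
#'
#' Shuffles the scores `n_perm` times and re-runs the *full* nested
#' leave-one-out pipeline -- including the inner C selection -- for each
#' permutation.  P-values use the add-one estimator, so they are never
#' exactly zero:
#' `p_r = (1 + #\{null r >= observed r\}) / (n_perm + 1)` and
#' `p_rmse = (1 + #\{null rmse <= observed rmse\}) / (n_perm + 1)`.
#'
#' @param stack the `kernel_stack` the observed run used.
#' @param y the observed scores.
#' @param observed the completed [loo_fcmkl()] result for (stack, y).
#' @param n_perm number of permutations (default 1000).
#' @param rng_seed seed for fold assignment and shuffles; defaults to the
#'   observed run's seed so the inner-fold design matches.
#' @inheritParams loo_fcmkl
#' @return object of class `fcmkl_perm` with the null distributions and
#'   p-values.
#' @export
permutation_test <- function(stack, y, observed, n_perm = 1000,
                             rng_seed = observed$seed,
                             C_grid = observed$C_grid,
                             epsilon = observed$epsilon,
                             k_inner = observed$k_inner,
                             loss = observed$loss,
                             inner_criterion =
                               observed$inner_criterion %||% "r",
                             kernel_norm = observed$kernel_norm %||% "trace",
                             control_cv = cv_control_default(),
                             control_fit = fit_control_default()) {
  if (!inherits(observed, "fcmkl_loo")) {
    stop("`observed` must be a completed loo_fcmkl() run")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  ea <- eps_args(epsilon)
  res <- cpp_perm(stack$F, stack$grp, stack$M, as.integer(stack$zcols - 1L),
                  as.numeric(y), as.numeric(C_grid), ea[1], ea[2],
                  loss == "squared", inner_criterion == "mse",
                  kernel_norm == "trace", as.integer(k_inner),
                  as.integer(n_perm), as.integer(rng_seed),
                  control_cv$tol_kkt, control_cv$max_outer,
                  control_cv$inner_rel, control_cv$inner_maxit,
                  control_cv$gamma_rel,
                  control_cv$mu_rel %||% 0.1 * control_cv$gamma_rel,
                  control_fit$tol_kkt, control_fit$max_outer,
                  control_fit$inner_rel, control_fit$inner_maxit,
                  control_fit$gamma_rel,
                  control_fit$mu_rel %||% 0.1 * control_fit$gamma_rel)
  null_r <- as.numeric(res$null_r)
  null_rmse <- as.numeric(res$null_rmse)
  structure(list(n_perm = n_perm, null_r = null_r, null_rmse = null_rmse,
                 observed_r = observed$r, observed_rmse = observed$rmse,
                 p_r = (1 + sum(null_r >= observed$r)) / (n_perm + 1),
                 p_rmse = (1 + sum(null_rmse <= observed$rmse)) / (n_perm + 1),
                 seed = rng_seed), class = "fcmkl_perm")
}

#' @export
print.fcmkl_perm <- function(x, ...) {
  cat(sprintf("permutation test (%d permutations):\n", x$n_perm))
  cat(sprintf("  r    = %.3f, p = %.4f\n", x$observed_r, x$p_r))
  cat(sprintf("  rMSE = %.3f, p = %.4f\n", x$observed_rmse, x$p_rmse))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m_tests number of comparisons (default 3: the three outcome
#'   scores tested).
#' @return list with the full-precision `threshold`, its 3-decimal rounding
#'   `threshold_rounded`, and `is_significant(p)` (strict inequality).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests = 3) {
  thr <- alpha / m_tests
  list(threshold = thr, threshold_rounded = round(thr, 3),
       alpha = alpha, m_tests = m_tests,
       is_significant = function(p) p < thr)
}

#' Meng's Z test for two dependent correlations
#'
#' Compares two correlations `r1`, `r2` that share a common variable (e.g.
#' two models' predictions correlated with the same actual scores), given
#' the correlation `r12` between the two predictor vectors:
#' \deqn{\bar r^2 = (r_1^2 + r_2^2)/2, \quad
#'       f = \min\!\left(1, \frac{1 - r_{12}}{2(1-\bar r^2)}\right), \quad
#'       h = \frac{1 - f \bar r^2}{1 - \bar r^2},}
#' \deqn{z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2)
#'       \sqrt{\frac{N-3}{2 (1 - r_{12}) h}}.}
#'
#' @param r1,r2 the two dependent correlations (each with the common
#'   variable), both strictly inside (-1, 1).
#' @param r12 correlation between the two predictors.
#' @param N number of observations (>= 4).
#' @return object of class `meng_z` with `z`, `p_two_sided`, and the
#'   one-sided tails `p_less` (H1: r1 < r2) and `p_greater` (H1: r1 > r2).
#' @export
meng_z <- function(r1, r2, r12, N) {
  if (N < 4) stop("N must be >= 4")
  if (any(abs(c(r1, r2, r12)) >= 1)) stop("correlations must be in (-1, 1)")
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r1) - atanh(r2)) * sqrt((N - 3) / (2 * (1 - r12) * h))
  structure(list(r1 = r1, r2 = r2, r12 = r12, N = N, z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 p_less = stats::pnorm(z),
                 p_greater = 1 - stats::pnorm(z)), class = "meng_z")
}

#' @export
print.meng_z <- function(x, ...) {
  cat(sprintf("Meng's Z = %.3f (r1 = %.3f, r2 = %.3f, r12 = %.3f, N = %d)\n",
              x$z, x$r1, x$r2, x$r12, x$N))
  cat(sprintf("  two-sided p = %.4g; one-sided p (r1 < r2) = %.4g\n",
              x$p_two_sided, x$p_less))
  invisible(x)
}

#' Compare two models' predictive correlations (Meng's Z)
#'
#' `r1 = cor(actual, pred_A)`, `r2 = cor(actual, pred_B)`,
#' `r12 = cor(pred_A, pred_B)`; delegates to [meng_z()] with N = number of
#' subjects.
#'
#' @param actual observed scores.
#' @param pred_A,pred_B the two prediction vectors.
#' @export
compare_models <- function(actual, pred_A, pred_B) {
  stopifnot(length(actual) == length(pred_A),
            length(actual) == length(pred_B))
  clip <- function(r) min(1 - 1e-12, max(-1 + 1e-12, r))
  meng_z(clip(stats::cor(actual, pred_A)),
         clip(stats::cor(actual, pred_B)),
         clip(stats::cor(pred_A, pred_B)),
         length(actual))
}

#' Computational lesion analysis
#'
#' Removes whole kernel groups (e.g. all seed-to-SMN edges), re-runs the full
#' nested LOO pipeline on the reduced stack, permutation-tests the lesioned
#' model, and compares lesioned vs. full model with Meng's Z
#' (`r1` = lesioned model, `r2` = full model, so a *negative* z with small
#' `p_less` means the lesion reduced predictive power).
#'
#' @param stack full `kernel_stack`.
#' @param y scores.
#' @param lesion character vector of groups to remove, from
#'   `{"SMN","DMN","FPN","SN","VIS","AUD","CONFOUND"}`.  An empty lesion
#'   reproduces the full model.
#' @param full optional precomputed [loo_fcmkl()] of the full stack.
#' @param n_perm permutations for the lesioned model (0 skips).
#' @inheritParams loo_fcmkl
#' @return list with the lesioned `loo`, `perm`, `meng` vs. the full model,
#'   and a one-row `report` data frame shaped like a lesion-analysis table
#'   (rmse, permutation p, r, permutation p, Meng's Z, parametric p).
#' @export
lesion_run <- function(stack, y, lesion, full = NULL, n_perm = 1000,
                       C_grid = default_C_grid(), epsilon = NULL,
                       k_inner = 5, rng_seed = 1,
                       loss = c("eps_insensitive", "squared")) {
  loss <- match.arg(loss)
  sub <- subset_stack(stack, lesion)
  if (is.null(full)) {
    full <- loo_fcmkl(stack, y, C_grid, epsilon, k_inner, rng_seed, loss)
  }
  loo <- loo_fcmkl(sub, y, C_grid, epsilon, k_inner, rng_seed, loss)
  perm <- if (n_perm > 0) {
    permutation_test(sub, y, loo, n_perm = n_perm, rng_seed = rng_seed)
  }
  mg <- compare_models(y, loo$pred, full$pred)
  report <- data.frame(
    lesion = paste(lesion, collapse = "+"),
    rmse = loo$rmse, p_rmse = if (n_perm > 0) perm$p_rmse else NA_real_,
    r = loo$r, p_r = if (n_perm > 0) perm$p_r else NA_real_,
    meng_z = mg$z, meng_p_one_sided = mg$p_less,
    meng_p_two_sided = mg$p_two_sided, stringsAsFactors = FALSE)
  list(loo = loo, perm = perm, meng = mg, full = full, report = report)
}

#' Network-specificity comparison (base vs. extended node set)
#'
#' Builds the extended stack (visual + auditory edges added), runs the full
#' pipeline on both, and compares their predictive correlations with Meng's
#' Z (`r1` = base model, `r2` = extended model, so positive z means the
#' compact four-network model predicts better).
#'
#' @param base_fc,extended_fc `fc_features` for the 17-node and 21-node sets.
#' @param confounds confound table (see [build_kernel_stack()]).
#' @param y scores.
#' @param n_perm permutations for each model (0 skips).
#' @inheritParams loo_fcmkl
#' @export
specificity_run <- function(base_fc, extended_fc, confounds, y, n_perm = 1000,
                            C_grid = default_C_grid(), epsilon = NULL,
                            k_inner = 5, rng_seed = 1,
                            loss = c("eps_insensitive", "squared")) {
  loss <- match.arg(loss)
  base <- build_kernel_stack(base_fc, confounds)
  ext <- build_kernel_stack(extended_fc, confounds)
  if (ext$M - base$M != 8L) {
    stop("extended stack must add exactly 8 kernels (got ",
         ext$M - base$M, ")")
  }
  loo_base <- loo_fcmkl(base, y, C_grid, epsilon, k_inner, rng_seed, loss)
  loo_ext <- loo_fcmkl(ext, y, C_grid, epsilon, k_inner, rng_seed, loss)
  perm_base <- if (n_perm > 0) {
    permutation_test(base, y, loo_base, n_perm = n_perm, rng_seed = rng_seed)
  }
  perm_ext <- if (n_perm > 0) {
    permutation_test(ext, y, loo_ext, n_perm = n_perm, rng_seed = rng_seed)
  }
  mg <- compare_models(y, loo_base$pred, loo_ext$pred)
  list(base = loo_base, extended = loo_ext,
       perm_base = perm_base, perm_extended = perm_ext, meng = mg,
       report = data.frame(model = c("base", "extended"),
                           r = c(loo_base$r, loo_ext$r),
                           rmse = c(loo_base$rmse, loo_ext$rmse),
                           p_r = c(if (n_perm > 0) perm_base$p_r else NA,
                                   if (n_perm > 0) perm_ext$p_r else NA),
                           meng_z = c(mg$z, NA),
                           meng_p_greater = c(mg$p_greater, NA)))
}
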