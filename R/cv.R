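#' Default soft-margin cost grid
#' @export
default_C_grid <- function() c(1e-4, 1e-3, 1e-2, 1e-1, 1, 10, 100)

# pipeline solver tolerances: looser for the many inner-CV fits, tighter for
# the per-fold final fits.  Both are far below the noise scale of the
# cross-validated selection criterion.
cv_control_default <- function() {
  list(tol_kkt = 1e-2, max_outer = 120, inner_rel = 3e-5, inner_maxit = 10,
       gamma_rel = 0.3, mu_rel = 0.1)
}
fit_control_default <- function() {
  list(tol_kkt = 1e-3, max_outer = 300, inner_rel = 1e-7, inner_maxit = 40,
       gamma_rel = 5e-3, mu_rel = 5e-4)
}

eps_args <- function(epsilon) {
  if (is.null(epsilon)) c(0.1, -1) else c(0, as.numeric(epsilon))
}

#' Inner-loop selection of the soft-margin cost C
#'
#' k-fold cross-validation over the C grid on the given (training) stack:
#' folds are assigned by a seeded shuffle, the criterion is the mean
#' held-out squared error, and ties go to the smallest C.  Kernel centering,
#' confound standardization and normalization are recomputed inside every
#' fold from that fold's training rows only.
#'
#' @param stack training `kernel_stack`.
#' @param y training scores.
#' @param C_grid ascending grid of positive costs.
#' @param epsilon fixed tube half-width, or NULL for 0.1*sd(training y)
#'   per fit.
#' @param k folds (reduced with a warning when fewer subjects than folds).
#' @param rng_seed integer seed for the fold shuffle.
#' @param loss,control see [fcmkl()] / [mkl_control()].
#' @return list with the selected `C` and the per-C `cv_mse`.
#' @export
inner_select_C <- function(stack, y, C_grid = default_C_grid(),
                           epsilon = NULL, k = 5, rng_seed = 1,
                           loss = c("eps_insensitive", "squared"),
                           inner_criterion = c("r", "mse"),
                           kernel_norm = c("trace", "mean_diag"),
                           control = cv_control_default()) {
  loss <- match.arg(loss)
  inner_criterion <- match.arg(inner_criterion)
  kernel_norm <- match.arg(kernel_norm)
  stopifnot(is.numeric(C_grid), all(C_grid > 0), !is.unsorted(C_grid,
                                                             strictly = TRUE))
  n <- stack$n
  if (length(y) != n) stop("cohort misalignment")
  if (n < k) {
    warning("fewer training subjects (", n, ") than folds (", k,
            "); reducing to leave-one-out")
    k <- n
  }
  ea <- eps_args(epsilon)
  out <- cpp_inner_select(stack$F, stack$grp, stack$M,
                          as.integer(stack$zcols - 1L), seq_len(n) - 1L,
                          as.numeric(y), as.numeric(C_grid), ea[1], ea[2],
                          loss == "squared", inner_criterion == "mse",
                          kernel_norm == "trace", as.integer(k),
                          as.integer(rng_seed), control$tol_kkt,
                          control$max_outer, control$inner_rel,
                          control$inner_maxit, control$gamma_rel,
                          control$mu_rel %||% 0.1 * control$gamma_rel)
  names(out$cv_mse) <- paste0("C=", C_grid)
  out
}

#' Nested leave-one-out cross-validated prediction
#'
#' For each subject i: select C by [inner_select_C()]-style 5-fold CV on the
#' remaining n-1 subjects, fit the sparse MKL model on those n-1, and predict
#' subject i with kernel statistics derived from the training subjects only.
#' The outer loop follows subject order (no randomness); only the inner fold
#' assignment is seeded.
#'
#' @inheritParams inner_select_C
#' @param k_inner inner folds (default 5).
#' @param inner_criterion hyperparameter selection criterion: pooled
#'   held-out Pearson `"r"` (default, matching the r-centric evaluation) or
#'   mean squared error `"mse"`.
#' @param kernel_norm see [fcmkl()].
#' @param refit also fit a final model on all subjects at a C selected by
#'   inner CV on the full cohort (for kernel-weight interpretation)?
#' @param control_cv,control_fit solver tolerances for the inner-CV fits and
#'   the per-fold final fits.
#' @return object of class `fcmkl_loo`: out-of-sample `pred`, per-fold
#'   selected `Csel`, Pearson `r`, `rmse`, and optionally `model`.
#' @export
loo_fcmkl <- function(stack, y, C_grid = default_C_grid(), epsilon = NULL,
                      k_inner = 5, rng_seed = 1,
                      loss = c("eps_insensitive", "squared"),
                      inner_criterion = c("r", "mse"),
                      kernel_norm = c("trace", "mean_diag"),
                      refit = FALSE,
                      control_cv = cv_control_default(),
                      control_fit = fit_control_default()) {
  loss <- match.arg(loss)
  inner_criterion <- match.arg(inner_criterion)
  kernel_norm <- match.arg(kernel_norm)
  n <- stack$n
  if (length(y) != n) stop("cohort misalignment")
  if (n < 6) stop("need at least 6 subjects for leave-one-out")
  ea <- eps_args(epsilon)
  res <- cpp_loo(stack$F, stack$grp, stack$M, as.integer(stack$zcols - 1L),
                 as.numeric(y), as.numeric(C_grid), ea[1], ea[2],
                 loss == "squared", inner_criterion == "mse",
                 kernel_norm == "trace", as.integer(k_inner),
                 as.integer(rng_seed),
                 control_cv$tol_kkt, control_cv$max_outer,
                 control_cv$inner_rel, control_cv$inner_maxit,
                 control_cv$gamma_rel,
                 control_cv$mu_rel %||% 0.1 * control_cv$gamma_rel,
                 control_fit$tol_kkt, control_fit$max_outer,
                 control_fit$inner_rel, control_fit$inner_maxit,
                 control_fit$gamma_rel,
                 control_fit$mu_rel %||% 0.1 * control_fit$gamma_rel)
  out <- structure(list(pred = as.numeric(res$pred),
                        Csel = as.numeric(res$Csel),
                        r = res$r, rmse = res$rmse,
                        y = as.numeric(y), n = n,
                        seed = rng_seed, C_grid = C_grid,
                        epsilon = epsilon, loss = loss,
                        inner_criterion = inner_criterion,
                        kernel_norm = kernel_norm,
                        k_inner = k_inner), class = "fcmkl_loo")
  if (refit) {
    sel <- inner_select_C(stack, y, C_grid, epsilon, k_inner,
                          derive_seed(rng_seed, 1), loss, inner_criterion,
                          kernel_norm, control = control_cv)
    out$C_full <- sel$C
    out$model <- fcmkl(stack, y, C = sel$C, epsilon = epsilon, loss = loss,
                       kernel_norm = kernel_norm, control = control_fit)
  }
  out
}

#' @export
print.fcmkl_loo <- function(x, ...) {
  cat(sprintf("nested LOO prediction (n = %d): r = %.3f, rMSE = %.3f\n",
              x$n, x$r, x$rmse))
  cat("selected C per outer fold:",
      paste(names(table(x$Csel)), "x", table(x$Csel), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fcmkl_loo <- function(x, xlab = "actual score",
                           ylab = "predicted score", ...) {
  plot(x$y, x$pred, xlab = xlab, ylab = ylab,
       main = sprintf("r = %.3f, rMSE = %.3f", x$r, x$rmse), ...)
  abline(lm(x$pred ~ x$y), lty = 2)
  invisible(x)
}

#' Single holdout evaluation
#'
#' One seeded train/test split; C is selected by inner CV on the training
#' partition only, the model is fit on the training partition, and metrics
#' are computed on the untouched test partition.
#'
#' @inheritParams loo_fcmkl
#' @param split_fraction fraction of subjects held out as the test set.
#' @return list with test indices, predictions, `r`, `rmse`, selected C.
#' @export
holdout_fcmkl <- function(stack, y, split_fraction = 0.3,
                          C_grid = default_C_grid(), epsilon = NULL,
                          k_inner = 5, rng_seed = 1,
                          loss = c("eps_insensitive", "squared"),
                          inner_criterion = c("r", "mse"),
                          kernel_norm = c("trace", "mean_diag"),
                          control_cv = cv_control_default(),
                          control_fit = fit_control_default()) {
  loss <- match.arg(loss)
  inner_criterion <- match.arg(inner_criterion)
  kernel_norm <- match.arg(kernel_norm)
  n <- stack$n
  n_test <- round(split_fraction * n)
  if (n_test < 4 || n - n_test < 4) {
    stop("both partitions need at least 4 subjects")
  }
  test <- local_seed(rng_seed, sort(sample.int(n, n_test)))
  train <- setdiff(seq_len(n), test)
  stopifnot(length(intersect(train, test)) == 0)

  tr_stack <- stack_rows(stack, train)
  sel <- inner_select_C(tr_stack, y[train], C_grid, epsilon, k_inner,
                        derive_seed(rng_seed, 2), loss, inner_criterion,
                        kernel_norm, control = control_cv)
  fit <- fcmkl(tr_stack, y[train], C = sel$C, epsilon = epsilon, loss = loss,
               kernel_norm = kernel_norm, control = control_fit)
  pred <- predict(fit, newdata = stack$F[test, , drop = FALSE])
  perf <- performance(y[test], pred)
  list(test = test, train = train, pred = pred, r = perf$r,
       rmse = perf$rmse, C = sel$C, model = fit, seed = rng_seed)
}

#' Prediction performance: Pearson r and root mean squared error
#'
#' `r` is `NA` (with a warning) when the actual scores are constant.  When
#' the *predicted* values are constant -- e.g. an all-zero sparse model
#' predicting only its intercept -- `r` is reported as 0: no linear
#' association is credited to the model, which keeps permutation accounting
#' well-defined.
#'
#' @param actual,predicted numeric vectors of equal length >= 3.
#' @return list with `r` and `rmse`.
#' @export
performance <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 3) stop("need at least 3 observations")
  rmse <- sqrt(mean((actual - predicted)^2))
  if (stats::sd(actual) == 0) {
    warning("constant actual scores: r undefined")
    return(list(r = NA_real_, rmse = rmse))
  }
  r <- if (stats::sd(predicted) < 1e-14) 0 else stats::cor(actual, predicted)
  list(r = r, rmse = rmse)
}
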