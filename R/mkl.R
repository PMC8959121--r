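#' Control parameters for the MKL solver
#'
#' @param tol_kkt stopping tolerance on the projected-gradient/KKT residual
#'   of the kernel-weight problem (the gradient is 0.5*(1 - alpha'K_m alpha),
#'   an O(1) quantity for normalized kernels).
#' @param max_outer maximum projected-gradient iterations.
#' @param inner_rel Newton gradient tolerance of the inner epsilon-SVR
#'   solve, relative to the response scale.
#' @param inner_maxit maximum Newton iterations per smoothing stage.
#' @param gamma_rel final Huber-smoothing width of the epsilon-insensitive
#'   loss, relative to `max(epsilon, 0.02 * response scale)`; the smoothing
#'   bias on the objective is of this order.
#' @param mu_rel final smoothing width of the group norms (controls how
#'   exactly small kernel weights are driven to zero).
#' @export
mkl_control <- function(tol_kkt = 1e-6, max_outer = 20000,
                        inner_rel = 1e-10, inner_maxit = 400,
                        gamma_rel = 3e-7, mu_rel = 0.1 * gamma_rel) {
  list(tol_kkt = tol_kkt, max_outer = max_outer, inner_rel = inner_rel,
       inner_maxit = inner_maxit, gamma_rel = gamma_rel, mu_rel = mu_rel)
}

# training-fold preprocessing of a feature-backed stack:
# column demeaning, z-scoring of confound columns, per-kernel normalization
# to unit mean diagonal of the centered training kernel
stack_prep <- function(stack, train, unit_trace = TRUE) {
  Ft <- stack$F[train, , drop = FALSE]
  mu <- colMeans(Ft)
  sc <- rep(1, ncol(Ft))
  for (j in stack$zcols) {
    s <- stats::sd(Ft[, j])
    sc[j] <- if (s > 1e-12) s else 1
  }
  m <- length(train)
  gs <- vapply(seq_len(stack$M) - 1L, function(g) {
    cols <- which(stack$grp == g)
    trc <- sum(sweep(Ft[, cols, drop = FALSE], 2, mu[cols], "-")^2 /
                 rep(sc[cols]^2, each = m))
    if (trc > 1e-12) sqrt((if (unit_trace) 1 else m) / trc) else 0
  }, numeric(1))
  list(mu = mu, sc = sc, gs = gs)
}

apply_stack_prep <- function(stack, prep, rows = NULL, F = NULL) {
  X <- if (is.null(F)) stack$F[rows, , drop = FALSE] else F
  X <- sweep(sweep(X, 2, prep$mu, "-"), 2, prep$sc, "/")
  sweep(X, 2, prep$gs[stack$grp + 1L], "*")
}

# turn a list of raw PSD kernel matrices into a feature-backed stack
stack_from_kernels <- function(kernels, labels = NULL, groups = NULL) {
  n <- nrow(kernels[[1]])
  labels <- labels %||% (names(kernels) %||% paste0("K", seq_along(kernels)))
  groups <- groups %||% rep("FC", length(kernels))
  feats <- lapply(seq_along(kernels), function(m) {
    K <- as.matrix(kernels[[m]])
    if (max(abs(K - t(K))) > 1e-8) stop("kernel not symmetric: ", labels[m])
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values), 1)) {
      stop("kernel not positive semidefinite: ", labels[m])
    }
    keep <- e$values > 1e-12 * max(e$values, 0)
    if (!any(keep)) return(matrix(0, n, 1))
    e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                             sum(keep))
  })
  F <- do.call(cbind, feats)
  grp <- rep(seq_along(kernels) - 1L, vapply(feats, ncol, integer(1)))
  structure(list(F = F, grp = as.integer(grp), M = length(kernels),
                 labels = labels, groups = groups, zcols = integer(),
                 n = n, subject = paste0("sub", seq_len(n))),
            class = "kernel_stack")
}

#' Fit a sparse multiple kernel learning regression
#'
#' Minimises the block-L1 MKL objective
#' \deqn{\sum_m \|f_m\|_{H_m} + C \sum_i L_\epsilon(y_i - \sum_m f_m(x_i) - b)}
#' over one function per kernel plus an intercept, where \eqn{L_\epsilon} is
#' the epsilon-insensitive (SVR) loss (or the squared loss).  The group-norm
#' penalty drives entire kernel weights to exactly zero, so the fitted model
#' names the connections that carry predictive signal.  All kernels are mean
#' centered and normalized (unit mean training diagonal) with statistics
#' from the fitted subjects before modeling; confound columns are z-scored
#' the same way.
#'
#' @param stack a `kernel_stack` (see [build_kernel_stack()]) holding the
#'   training subjects, or a list of raw PSD kernel matrices.
#' @param y numeric response (training scores).
#' @param C soft-margin cost.
#' @param epsilon epsilon-insensitive tube half-width, in score units;
#'   default `0.1 * sd(y)`.
#' @param loss `"eps_insensitive"` (default) or `"squared"`.
#' @param kernel_norm kernel normalization: `"trace"` (unit training trace,
#'   the default used throughout the pipeline) or `"mean_diag"` (unit mean
#'   training diagonal).  The two differ only by a factor n in kernel scale,
#'   which shifts where the C grid lands.
#' @param control see [mkl_control()].
#' @return object of class `fcmkl` with per-kernel weights (`coef()`), dual
#'   coefficients, intercept, primal objective and a duality-gap certificate.
#' @export
fcmkl <- function(stack, y, C = 1, epsilon = NULL,
                  loss = c("eps_insensitive", "squared"),
                  kernel_norm = c("trace", "mean_diag"),
                  control = mkl_control()) {
  loss <- match.arg(loss)
  kernel_norm <- match.arg(kernel_norm)
  if (is.list(stack) && !inherits(stack, "kernel_stack")) {
    stack <- stack_from_kernels(stack)
  }
  y <- as.numeric(y)
  n <- stack$n
  if (length(y) != n) stop("cohort misalignment: length(y) != stack subjects")
  if (n < 4) stop("need at least 4 training subjects")
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(y)
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  if (C <= 0) stop("C must be positive")

  prep <- stack_prep(stack, seq_len(n), unit_trace = kernel_norm == "trace")
  X <- apply_stack_prep(stack, prep, seq_len(n))
  mu_rel <- control$mu_rel %||% (0.1 * control$gamma_rel)
  fit <- cpp_mkl_fit(X, stack$grp, stack$M, y, C, epsilon,
                     loss == "squared", control$tol_kkt, control$max_outer,
                     control$inner_rel, control$inner_maxit,
                     control$gamma_rel, mu_rel, numeric(0), numeric(0))
  d <- as.numeric(fit$d)
  names(d) <- stack$labels
  w <- as.numeric(fit$w)

  obj <- structure(list(
    weights = d, alpha = as.numeric(fit$alpha), b = fit$b,
    w = w, C = C, epsilon = epsilon, loss = loss,
    objective = fit$objective, dual_lb = fit$dual_lb,
    gap = fit$objective - fit$dual_lb,
    converged = fit$converged, iters = fit$iters,
    q = as.numeric(fit$q), kernel_norm = kernel_norm,
    zero_floor = 3 * mu_rel * max(1, 0.02 * (diff(range(y)) + epsilon)),
    stack = stack, prep = prep, y = y,
    call = match.call()), class = "fcmkl")
  obj$fitted <- drop(X %*% w) + fit$b
  obj
}

#' @export
coef.fcmkl <- function(object, ...) object$weights

#' @export
fitted.fcmkl <- function(object, ...) object$fitted

#' @export
residuals.fcmkl <- function(object, ...) object$y - object$fitted

#' Predict from a fitted MKL model
#'
#' @param object an `fcmkl` fit.
#' @param newdata new subjects: a `kernel_stack` with the same kernels, or a
#'   raw feature matrix with the same columns as the training stack.  The
#'   stored training statistics (feature means, confound scale, kernel
#'   normalization) are applied; nothing is re-estimated.
#' @param cross_kernels alternatively, a list of ntest x ntrain kernel cross
#'   blocks already centered and normalized with the model's training
#'   statistics (attributes `centered` and `normalized` must be set; see
#'   [center_kernel()]).
#' @param ... unused.
#' @export
predict.fcmkl <- function(object, newdata = NULL, cross_kernels = NULL, ...) {
  if (!is.null(cross_kernels)) {
    if (length(cross_kernels) != object$stack$M) {
      stop("kernel state mismatch: expected ", object$stack$M, " cross blocks")
    }
    ok <- vapply(cross_kernels, function(K) {
      isTRUE(attr(K, "centered")) && isTRUE(attr(K, "normalized"))
    }, logical(1))
    if (!all(ok)) {
      stop("kernel state mismatch: cross blocks must carry training-set ",
           "centering and normalization")
    }
    f <- 0
    for (m in seq_along(cross_kernels)) {
      f <- f + object$weights[m] *
        drop(as.matrix(cross_kernels[[m]]) %*% object$alpha)
    }
    return(unname(f + object$b))
  }
  if (is.null(newdata)) return(object$fitted)
  F <- if (inherits(newdata, "kernel_stack")) newdata$F else as.matrix(newdata)
  if (ncol(F) != ncol(object$stack$F)) {
    stop("kernel state mismatch: newdata has ", ncol(F), " feature columns, ",
         "model expects ", ncol(object$stack$F))
  }
  X <- apply_stack_prep(object$stack, object$prep, F = F)
  unname(drop(X %*% object$w) + object$b)
}

#' Per-kernel and per-group contribution weights
#'
#' Kernel weights normalized to sum to one (groups are sums over their
#' members).  Weights below `1e-8 * max(weight)` -- or below the solver's
#' group-norm smoothing floor, whichever is larger -- are treated as exactly
#' zero for reporting; an all-zero model is flagged as the null model.
#'
#' @param model an `fcmkl` fit.
#' @return list with `kernel` (data frame: label, group, weight,
#'   contribution), `group` (named vector), `null_model` flag.
#' @export
kernel_contributions <- function(model) {
  d <- model$weights
  thr <- max(1e-8 * max(d, 0), model$zero_floor %||% 0)
  d[d < thr] <- 0
  tot <- sum(d)
  contrib <- if (tot > 0) d / tot else d * 0
  kern <- data.frame(label = model$stack$labels, group = model$stack$groups,
                     weight = as.numeric(d),
                     contribution = as.numeric(contrib),
                     stringsAsFactors = FALSE)
  grp <- tapply(contrib, edge_lesion_group(model$stack$groups), sum)
  list(kernel = kern, group = grp[order(-grp)], null_model = tot == 0)
}

#' @export
print.fcmkl <- function(x, ...) {
  kc <- kernel_contributions(x)
  act <- sum(kc$kernel$weight > 0)
  cat("sparse MKL", if (x$loss == "squared") "(squared loss)" else
    sprintf("(eps-insensitive, eps = %.4g)", x$epsilon), "\n")
  cat(sprintf("C = %g; %d/%d active kernels; objective %.6g (gap %.2g)\n",
              x$C, act, x$stack$M, x$objective, x$gap))
  if (kc$null_model) cat("null model: all kernel weights zero; predicts b =",
                         format(x$b, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.fcmkl <- function(object, ...) {
  kc <- kernel_contributions(object)
  structure(list(fit = object, contributions = kc), class = "summary.fcmkl")
}

#' @export
print.summary.fcmkl <- function(x, ...) {
  print(x$fit)
  kern <- x$contributions$kernel
  kern <- kern[kern$weight > 0, , drop = FALSE]
  if (nrow(kern)) {
    kern <- kern[order(-kern$weight), ]
    cat("\nactive kernels:\n")
    print(kern, row.names = FALSE, digits = 3)
    cat("\ngroup contributions:\n")
    print(round(x$contributions$group, 3))
  }
  invisible(x)
}

#' @export
plot.fcmkl <- function(x, ...) {
  kc <- kernel_contributions(x)
  kern <- kc$kernel[kc$kernel$weight > 0, , drop = FALSE]
  if (!nrow(kern)) {
    barplot(0, names.arg = "null model", ylab = "kernel contribution")
    return(invisible(x))
  }
  kern <- kern[order(-kern$contribution), ]
  op <- par(mar = c(9, 4, 2, 1)); on.exit(par(op))
  barplot(kern$contribution, names.arg = kern$label, las = 2,
          ylab = "kernel contribution", ...)
  invisible(x)
}
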