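#' Linear kernel of a feature matrix
#'
#' @param features n x d numeric matrix (rows = subjects).
#' @return n x n inner-product matrix.
#' @export
linear_kernel <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2 || ncol(X) < 1) stop("need n >= 2 and d >= 1")
  stopifnot_finite(X, "features")
  tcrossprod(X)
}

#' Center a kernel with training-set statistics
#'
#' The training block becomes H K H with H = I - (1/m) 11'; rows/columns
#' outside the training set are centered with the training means only, so no
#' information leaks from held-out subjects.
#'
#' @param K n x n kernel matrix.
#' @param train integer indices of the training subjects.
#' @export
center_kernel <- function(K, train = seq_len(nrow(K))) {
  K <- as.matrix(K)
  if (length(train) < 1) stop("training set must be nonempty")
  # K(i,j) - mean_t K(i,t) - mean_t K(t,j) + grand mean, means over train only
  cm <- colMeans(K[train, , drop = FALSE])
  rm_ <- rowMeans(K[, train, drop = FALSE])
  gm <- mean(K[train, train])
  Kc <- sweep(sweep(K, 1, rm_), 2, cm) + gm
  attr(Kc, "centered") <- TRUE
  Kc
}

#' Normalize a kernel with training-set statistics
#'
#' `unit = "mean_diag"` divides the kernel by trace(training block)/m so the
#' training diagonal averages one; `unit = "trace"` divides by the training
#' trace itself (the convention the fitting pipeline uses by default, see
#' [fcmkl()]).
#'
#' @inheritParams center_kernel
#' @param unit normalization convention.
#' @param label kernel label used in error messages.
#' @export
normalize_kernel <- function(K, train = seq_len(nrow(K)),
                             unit = c("mean_diag", "trace"),
                             label = "kernel") {
  unit <- match.arg(unit)
  K <- as.matrix(K)
  tr <- sum(diag(K)[train])
  if (tr <= 1e-12) stop("degenerate kernel: ", label)
  Kn <- K / (if (unit == "mean_diag") tr / length(train) else tr)
  attr(Kn, "centered") <- attr(K, "centered")
  attr(Kn, "normalized") <- TRUE
  Kn
}

#' Build the kernel stack for MKL
#'
#' One linear kernel per connectivity edge (a single Fisher-z feature each)
#' plus exactly one combined confound kernel built from the z-scored age,
#' gender and mean-FD columns.  Kernels are stored feature-backed; centering,
#' confound standardization and normalization are applied at fit time with
#' training-fold statistics (see [fcmkl()]).
#'
#' @param fc `fc_features` matrix (subjects x edges) from [fc_features()].
#' @param confounds data frame with columns `age`, `gender` (0/1),
#'   `mean_fd`; NULL drops the confound kernel.
#' @return object of class `kernel_stack`.
#' @export
build_kernel_stack <- function(fc, confounds = NULL) {
  fc <- unclass(fc)
  n <- nrow(fc)
  grp_tag <- attr(fc, "group") %||% rep("FC", ncol(fc))
  F <- fc
  labels <- colnames(fc)
  groups <- grp_tag
  grp <- seq_len(ncol(fc))            # one kernel per edge column
  zcols <- integer()
  if (!is.null(confounds)) {
    need <- c("age", "gender", "mean_fd")
    if (!all(need %in% names(confounds))) {
      stop("confounds must have columns: ", paste(need, collapse = ", "))
    }
    if (nrow(confounds) != n) stop("cohort misalignment: ", nrow(confounds),
                                   " confound rows for ", n, " subjects")
    cf <- as.matrix(confounds[, need])
    stopifnot_finite(cf, "confounds")
    if (!all(cf[, "gender"] %in% c(0, 1))) stop("gender must be coded 0/1")
    F <- cbind(F, cf)
    labels <- c(labels, "confounds")
    groups <- c(groups, "CONFOUND")
    grp <- c(grp, rep(ncol(fc) + 1L, 3L))
    zcols <- ncol(fc) + 1:3
  }
  structure(list(F = unname(F), grp = as.integer(grp - 1L),
                 M = length(labels), labels = labels, groups = groups,
                 zcols = as.integer(zcols), n = n,
                 subject = rownames(fc) %||% paste0("sub", seq_len(n))),
            class = "kernel_stack")
}

#' @export
print.kernel_stack <- function(x, ...) {
  cat("kernel stack:", x$M, "kernels,", x$n, "subjects\n")
  tab <- table(edge_lesion_group(x$groups))
  cat(paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Materialize the raw kernel matrices of a stack
#'
#' @param stack a `kernel_stack`.
#' @param which kernel labels (default all).
#' @return named list of n x n matrices.
#' @export
stack_kernels <- function(stack, which = stack$labels) {
  idx <- match(which, stack$labels)
  if (anyNA(idx)) stop("unknown kernel label(s)")
  out <- lapply(idx, function(m) {
    linear_kernel(stack$F[, stack$grp == (m - 1L), drop = FALSE])
  })
  names(out) <- which
  out
}

#' Remove kernel groups from a stack (computational lesion)
#'
#' @param stack a `kernel_stack`.
#' @param drop_groups character vector of lesion groups from
#'   `{"SMN","DMN","FPN","SN","VIS","AUD","CONFOUND"}` (DMN includes the
#'   DMN-core seed-seed edge).
#' @export
subset_stack <- function(stack, drop_groups) {
  if (length(drop_groups) == 0) return(stack)
  lg <- edge_lesion_group(stack$groups)
  bad <- setdiff(drop_groups, unique(lg))
  if (length(bad)) stop("unknown lesion group(s): ", paste(bad, collapse = ", "))
  keep <- !(lg %in% drop_groups)
  if (!any(keep & stack$groups != "CONFOUND")) {
    stop("lesion would remove all connectivity kernels")
  }
  keepk <- which(keep)
  colkeep <- stack$grp %in% (keepk - 1L)
  newgrp <- match(stack$grp[colkeep] + 1L, keepk) - 1L
  zold <- logical(ncol(stack$F)); zold[stack$zcols] <- TRUE
  structure(list(F = stack$F[, colkeep, drop = FALSE],
                 grp = as.integer(newgrp), M = length(keepk),
                 labels = stack$labels[keepk], groups = stack$groups[keepk],
                 zcols = which(zold[colkeep]), n = stack$n,
                 subject = stack$subject),
            class = "kernel_stack")
}

#' Keep a subset of subjects (rows) of a stack
#' @param stack a `kernel_stack`.
#' @param rows integer row indices.
#' @export
stack_rows <- function(stack, rows) {
  s <- stack
  s$F <- stack$F[rows, , drop = FALSE]
  s$n <- length(rows)
  s$subject <- stack$subject[rows]
  s
}
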