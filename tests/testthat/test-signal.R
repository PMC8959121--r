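test_that("framewise displacement arithmetic", {
  T <- 20
  m0 <- matrix(0.5, T, 6)                       # constant motion
  fd <- compute_fd(m0)
  expect_equal(fd$fd, rep(0, T))
  expect_equal(fd$mean_fd, 0)

  m1 <- m0; m1[8:T, 1] <- m1[8:T, 1] + 1        # single 1 mm jump in x
  fd1 <- compute_fd(m1)
  expect_equal(fd1$fd[8], 1.0)
  expect_equal(sum(fd1$fd), 1.0)

  m2 <- m0; m2[5:T, 4:6] <- m2[5:T, 4:6] + 0.01 # 0.01 rad on all rotations
  fd2 <- compute_fd(m2)
  expect_equal(fd2$fd[5], 50 * 0.03)            # 1.5 mm arc length

  # FD invariant to a constant offset on all columns
  expect_equal(compute_fd(m1 + 3)$fd, fd1$fd)

  # dialect switches
  m3 <- m2[, c(4:6, 1:3)]
  expect_equal(compute_fd(m3, rotations_first = TRUE)$fd, fd2$fd)
  m4 <- m2; m4[, 4:6] <- m4[, 4:6] * 180 / pi
  expect_equal(compute_fd(m4, degrees = TRUE)$fd, fd2$fd)

  expect_error(compute_fd(matrix(c(1, NA), 2, 6)), "invalid motion")
})

test_that("nuisance matrix: derivatives, components, trend", {
  T <- 40
  set.seed(3)
  motion <- matrix(rnorm(T * 6), T, 6)
  f <- sin(seq_len(T))
  tissue_rank1 <- outer(f, rnorm(10))
  X <- build_nuisance(motion, tissue_rank1, n_components = 5)
  expect_equal(ncol(X), 19L)  # 6 motion + 6 deriv + 5 comp + intercept + trend
  # rank-1 tissue: first component is the (demeaned, unit-norm) time course
  expect_gt(abs(cor(X[, "compcor1"], f)), 0.9999)
  expect_equal(sum(X[, "compcor1"]^2), 1)
  # derivatives are backward differences with leading zero
  expect_equal(unname(X[2:T, "dmotion1"]), unname(diff(motion[, 1])))
  expect_equal(unname(X[1, "dmotion1"]), 0)
  # constant motion: derivative columns exactly zero and flagged
  Xc <- build_nuisance(matrix(1, T, 6), tissue_rank1)
  expect_true(all(Xc[, paste0("dmotion", 1:6)] == 0))
  expect_length(attr(Xc, "zero_derivative"), 6L)
  # T = 5 centered linear trend
  X5 <- build_nuisance(matrix(rnorm(30), 5, 6), matrix(rnorm(5 * 6), 5, 6))
  expect_equal(X5[, "trend"] / X5[5, "trend"] * 2, c(-2, -1, 0, 1, 2))

  expect_error(build_nuisance(motion, tissue_rank1[, 1:3]),
               "insufficient tissue voxels")
})

test_that("denoise is ordinary least squares per ROI", {
  set.seed(4)
  T <- 50
  X <- cbind(1, rnorm(T), rnorm(T))
  ts <- matrix(rnorm(T * 3), T, 3)
  res <- denoise(ts, X)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(X, res))) / max(abs(ts)), 1e-8)
  # intercept-only design: demeaning
  res0 <- denoise(ts, matrix(1, T, 1))
  expect_equal(res0, sweep(ts, 2, colMeans(ts)), ignore_attr = TRUE)
  # signal in the span of the regressors vanishes
  sig <- X %*% matrix(rnorm(9), 3, 3)
  expect_lt(max(abs(denoise(sig, X))), 1e-8)
  # collinear columns dropped with a warning, not silent failure
  expect_warning(denoise(ts, cbind(X, X[, 2])), "collinear")
})

test_that("ideal band-pass keeps in-band bins and kills the rest", {
  T <- 240; tr <- 2
  t <- seq_len(T)
  s_in <- sin(2 * pi * 0.05 * t * tr)     # exact bin inside [0.01, 0.1]
  out <- bandpass(cbind(s_in), tr)
  expect_lt(max(abs(out - s_in)) / max(abs(s_in)), 0.01)

  s_out <- sin(2 * pi * 0.2 * t * tr)     # exact bin outside the band
  expect_lt(max(abs(bandpass(cbind(s_out), tr))), 1e-9)

  expect_equal(max(abs(bandpass(cbind(rep(3, T)), tr))), 0)  # DC removed
  expect_error(bandpass(cbind(s_in), tr, high = 0.3), "Nyquist")
  # column means ~ 0 after band-pass
  set.seed(5)
  bp <- bandpass(matrix(rnorm(T * 4), T, 4), tr)
  expect_lt(max(abs(colMeans(bp))), 1e-10)
})

test_that("spherical ROI extraction matches brute-force voxel enumeration", {
  roi <- roi_set(data.frame(name = c("A", "B"), network = c("DMN", "SMN"),
                            x = c(0, 12), y = c(0, 0), z = c(0, 0),
                            radius = 5, is_seed = c(TRUE, FALSE)))
  # 3 mm grid centered at the origin, identity-aligned affine
  dims <- c(15, 9, 9); T <- 6
  affine <- rbind(c(3, 0, 0, -21), c(0, 3, 0, -12), c(0, 0, 3, -12),
                  c(0, 0, 0, 1))
  set.seed(6)
  vol <- array(rnorm(prod(dims) * T), c(dims, T))
  mask <- array(1, dims)

  # brute-force oracle: enumerate voxel centers within 5 mm of (0,0,0)
  centers <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                                   k = 0:(dims[3] - 1)))
  world <- t(affine %*% t(cbind(centers, 1)))[, 1:3]
  inA <- rowSums(world^2) <= 25
  expect_gt(sum(inA), 1)
  c_t <- sin(seq_len(T))
  for (v in which(inA)) {
    vol[centers[v, 1] + 1, centers[v, 2] + 1, centers[v, 3] + 1, ] <- c_t
  }
  ts <- extract_roi_timeseries(vol, roi, mask, affine = affine)
  # phantom: all sphere voxels carry c(t) so the extracted series is c(t)
  expect_equal(ts[, "A"], c_t, ignore_attr = TRUE)

  # selected voxel count equals the enumeration (constant-marker trick)
  vol2 <- array(0, c(dims, 1))
  for (v in which(inA)) {
    vol2[centers[v, 1] + 1, centers[v, 2] + 1, centers[v, 3] + 1, 1] <- 1
  }
  vol2[1, 1, 1, 1] <- 100  # far away, must not leak in
  ts2 <- extract_roi_timeseries(vol2, roi, mask, affine = affine)
  expect_equal(unname(ts2[1, "A"]), 1)  # mean of marker over exactly the sphere

  # an ROI with no in-mask voxels errors by name
  mask0 <- mask
  mask0[11:15, , ] <- 0  # removes B's sphere (x >= 9 mm), leaves A intact
  expect_error(extract_roi_timeseries(vol, roi, mask0, affine = affine),
               "empty ROI: B")
})

test_that("seed connectivity: Fisher z per edge with clipping", {
  roi <- roi_set(data.frame(name = c("S1", "T1"), network = c("DMN", "SMN"),
                            x = 0:1, y = 0, z = 0, radius = 5,
                            is_seed = c(TRUE, FALSE)))
  ts <- cbind(S1 = c(1, 2, 3, 4, 1, 2, 3, 4),
              T1 = c(1, 3, 2, 4, 1, 3, 2, 4))
  z <- seed_fc(ts, roi)
  expect_equal(unname(z["S1->T1"]), atanh(0.8))  # r = 0.8 exactly

  ts2 <- cbind(S1 = ts[, 1], T1 = 2 * ts[, 1] + 1)  # perfect correlation
  expect_equal(unname(seed_fc(ts2, roi)["S1->T1"]), atanh(1 - 1e-7))

  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ts3 <- cbind(S1 = sin(th), T1 = cos(th))          # orthogonal, demeaned
  expect_equal(unname(seed_fc(ts3, roi)["S1->T1"]), 0, tolerance = 1e-12)

  ts4 <- cbind(S1 = rep(1, 8), T1 = rnorm(8))
  expect_error(seed_fc(ts4, roi), "degenerate ROI signal: S1")
  expect_error(seed_fc(ts[1:4, ], roi), "at least 8")
})

test_that("Fisher z is strictly increasing in r", {
  r <- seq(-0.999, 0.999, length.out = 200)
  expect_true(all(diff(atanh(r)) > 0))
  # and the clipped transform used by seed_fc is monotone too
  rc <- pmin(1 - 1e-7, pmax(-(1 - 1e-7), c(r, 1, -1)))
  expect_true(all(diff(atanh(sort(rc))) >= 0))
})
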