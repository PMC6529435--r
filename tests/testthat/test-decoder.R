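test_that("noiseless simulation recovers the true weight matrix", {
  qs <- quick_sim(seed = 51, d = 8, n_voxels = 30, n_train = 120, n_test = 0,
                  reps = 0, region_scales = c(1, 1, 1),
                  noise = noise_spec(sd = 0, drift_amplitude = 0))
  wm <- fit_weights(qs$sim$design, qs$sim$Y)
  expect_lt(max(abs(wm$W - qs$brain$W_true)), 1e-8)
  expect_equal(nrow(wm$W), qs$d + 1)
  expect_true(all(wm$diagnostics$r2 > 1 - 1e-10))
})

test_that("fit_weights matches the hand-sized normal-equations oracle", {
  # 3 scans, bias + 1 latent regressor, 2 voxels
  X <- cbind(bias = c(1, 0.5, 0.2), z1 = c(0.3, -0.4, 0.8))
  Y <- cbind(c(1, 2, 0.5), c(-0.5, 1, 2))
  dm <- raw_design(X, role = c("bias", "latent"))
  wm <- fit_weights(dm, Y)
  # oracle: explicit 2x2 inverse, written out by hand
  A <- crossprod(X)
  det_A <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  A_inv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) / det_A
  expect_equal(unname(wm$W), unname(A_inv %*% crossprod(X, Y)),
               tolerance = 1e-12)
})

test_that("orthonormal design columns reduce fitting to a projection", {
  Q <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  colnames(Q) <- c("bias", "z1", "z2")
  Y <- matrix(rnorm(20), 10, 2)
  wm <- fit_weights(raw_design(Q, c("bias", "latent", "latent")), Y)
  expect_equal(unname(wm$W), unname(crossprod(Q, Y)), tolerance = 1e-10)
})

test_that("rank-deficient training data falls back to the pseudo-inverse with a warning", {
  X <- cbind(bias = rep(1, 6), z1 = rep(1, 6))        # collinear
  Y <- matrix(rnorm(12), 6, 2)
  expect_warning(fit_weights(raw_design(X, c("bias", "latent")), Y),
                 "pseudo-inverse|rank")
  expect_error(fit_weights(raw_design(X, c("bias", "latent")),
                           matrix(0, 3, 2)), "rows")
})

test_that("single-stimulus noiseless patterns are recovered exactly", {
  p <- c(2, -1, 0.5)
  ev <- event_table(c(20, 50), 1, "test_face", "t1")
  kern <- hrf_kernel(hrf_spec(), 2 / 16)
  reg <- facedec:::convolved_regressor(ev$onset, ev$duration, c(1, 1),
                                       60, 2, 2 / 16, kern)
  Y <- outer(reg, p) + 0.7                 # constant baseline
  pat <- estimate_test_patterns(ev, Y, tr = 2)
  expect_equal(unname(pat$patterns["t1", ]), p, tolerance = 1e-8)
  expect_equal(unname(pat$n_trials["t1"]), 2L)
})

test_that("disjoint stimuli estimate the same betas jointly and separately", {
  ids <- c("t1", "t2")
  ev <- event_table(c(20, 80, 140, 200), 1, "test_face",
                    c("t1", "t2", "t1", "t2"))
  set.seed(52)
  kern <- hrf_kernel(hrf_spec(), 2 / 16)
  p1 <- rnorm(4); p2 <- rnorm(4)
  r1 <- facedec:::convolved_regressor(c(20, 140), c(1, 1), c(1, 1), 120, 2,
                                      2 / 16, kern)
  r2 <- facedec:::convolved_regressor(c(80, 200), c(1, 1), c(1, 1), 120, 2,
                                      2 / 16, kern)
  Y <- outer(r1, p1) + outer(r2, p2)
  joint <- estimate_test_patterns(ev, Y, tr = 2)
  solo1 <- estimate_test_patterns(ev[ev$stim_id == "t1", ],
                                  Y - outer(r2, p2), tr = 2)
  expect_equal(joint$patterns["t1", ], solo1$patterns["t1", ],
               tolerance = 1e-6)
  expect_equal(unname(joint$patterns["t2", ]), p2, tolerance = 1e-6)
})

test_that("imagery blocks are decodable from averaged responses", {
  p <- c(1, -2, 0.5, 3)
  ev <- event_table(c(20, 100), 12, "imagery")
  Y <- matrix(0, 100, 4)
  for (onset in c(20, 100)) {
    rows <- (floor((onset + 4) / 2) + 1):ceiling((onset + 20) / 2)
    Y[rows, ] <- Y[rows, ] + matrix(p, length(rows), 4, byrow = TRUE)
  }
  pat <- estimate_test_patterns(ev, Y, tr = 2, condition = "imagery",
                                method = "average")
  expect_equal(nrow(pat$patterns), 1)
  expect_gt(cor(pat$patterns[1, ], p), 0.999)
  expect_error(estimate_test_patterns(ev, Y, tr = 2,
                                      condition = "test_face"), "no 'test_face'")
})

test_that("decode_latent inverts x W exactly for full-row-rank W", {
  set.seed(53)
  for (i in 1:10) {
    d <- sample(2:6, 1)
    nv <- d + 1 + sample(1:6, 1)
    W <- as_weight_matrix(matrix(rnorm((d + 1) * nv), d + 1, nv))
    x <- c(1, rnorm(d))
    dec <- decode_latent(W, as.numeric(x %*% W$W))
    expect_lt(max(abs(c(dec$bias, dec$Z) - x)), 1e-8)
  }
})

test_that("orthonormal-row W decodes by plain projection", {
  Q <- t(qr.Q(qr(matrix(rnorm(24), 8, 3))))     # 3 x 8, orthonormal rows
  W <- as_weight_matrix(Q)
  pat <- rnorm(8)
  dec <- decode_latent(W, pat)
  expect_equal(c(dec$bias, dec$Z), as.numeric(pat %*% t(Q)),
               tolerance = 1e-10)
})

test_that("decode_latent matches the explicit pseudo-inverse oracle on a hand-sized case", {
  # 2 latent dims (+bias), 3 voxels
  W <- as_weight_matrix(matrix(c(1, 0, 1,
                                 0, 2, 0,
                                 1, 1, -1), 3, 3, byrow = TRUE))
  pat <- c(0.5, -1, 2)
  # oracle: explicit 3x3 inverse of W W' via cofactors
  A <- W$W %*% t(W$W)
  cof <- matrix(NA, 3, 3)
  for (i in 1:3) for (j in 1:3)
    cof[i, j] <- (-1)^(i + j) * det(A[-i, -j, drop = FALSE])
  A_inv <- t(cof) / det(A)
  oracle <- as.numeric(pat %*% t(W$W) %*% A_inv)
  dec <- decode_latent(W, pat)
  expect_equal(c(dec$bias, dec$Z), oracle, tolerance = 1e-10)
  expect_error(decode_latent(W, c(1, 2)), "does not match")
})

test_that("decoding warns when W W' is singular", {
  W <- as_weight_matrix(rbind(c(1, 1, 1), c(2, 2, 2), c(0, 0, 1)))
  expect_warning(decode_latent(W, c(1, 0, 0)), "singular")
})

test_that("scaling behaves as the linear model predicts", {
  qs <- quick_sim(seed = 54, d = 4, n_voxels = 30, n_train = 60, n_test = 0,
                  reps = 0, noise = noise_spec(sd = 0, drift_amplitude = 0),
                  region_scales = c(1, 1, 1))
  wm <- fit_weights(qs$sim$design, qs$sim$Y)
  wm_scaled <- fit_weights(qs$sim$design, 3 * qs$sim$Y)
  expect_equal(wm_scaled$W, 3 * wm$W, tolerance = 1e-8)
  x <- c(1, rnorm(4))
  dec1 <- decode_latent(wm, as.numeric(x %*% wm$W))
  dec2 <- decode_latent(wm, 3 * as.numeric(x %*% wm$W))
  expect_equal(as.numeric(dec2$Z), 3 * as.numeric(dec1$Z), tolerance = 1e-8)
})
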