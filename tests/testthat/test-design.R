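test_that("canonical HRF kernel has the expected shape", {
  k <- hrf_kernel(hrf_spec(), dt = 0.01)
  expect_equal(k[1], 0)                              # gamma density at 0
  peak_t <- (which.max(k) - 1) * 0.01
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)       # dense-grid evaluation
  expect_equal(max(k), 1)                            # unit peak
  expect_lt(min(k), 0)                               # undershoot exists
  expect_gt(which.min(k), which.max(k))              # ... after the peak
  # grid refinement: halving dt moves the peak by less than dt
  k2 <- hrf_kernel(hrf_spec(), dt = 0.005)
  expect_lt(abs((which.max(k2) - 1) * 0.005 - peak_t), 0.01 + 1e-12)
  expect_error(hrf_spec(length = 20), "24")
  expect_error(hrf_spec(ratio = -1), "positive")
})

test_that("a fixation-only event list yields zero stimulus columns", {
  ev <- event_table(c(5, 10), 1, "fixation")
  dm <- build_design(ev, NULL, n_scans = 20, tr = 2)
  expect_equal(dm$X[, "bias"], rep(0, 20))
  expect_equal(dm$d, 0L)
  expect_true("intercept" %in% dm$names)
})

test_that("a single event makes each parametric column z_j times the bias column", {
  Z <- matrix(c(1.5, -0.7, 0.2), 1, 3, dimnames = list("a", NULL))
  ev <- event_table(20, 1, "train_face", "a")
  dm <- build_design(ev, Z, n_scans = 40, tr = 2)
  for (j in 1:3)
    expect_equal(dm$X[, paste0("z", j)], Z[1, j] * dm$X[, "bias"])
})

test_that("two opposite-latent events match a direct convolution oracle", {
  Z <- matrix(c(2, -2), 2, 1, dimnames = list(c("a", "b"), NULL))
  ev <- event_table(c(10, 70), 1, "train_face", c("a", "b"))
  tr <- 2; dt <- tr / 16; n_scans <- 60
  dm <- build_design(ev, Z, n_scans = n_scans, tr = tr)
  # oracle: independent discrete convolution of the stick grid
  kern <- hrf_kernel(hrf_spec(), dt)
  n_fine <- ceiling(n_scans * tr / dt) + 1
  t_fine <- (seq_len(n_fine) - 1) * dt
  x <- numeric(n_fine)
  for (i in 1:2) {
    idx <- which(t_fine >= ev$onset[i] & t_fine < ev$onset[i] + 1)
    x[idx] <- x[idx] + Z[i, 1]
  }
  conv <- numeric(n_fine)
  for (s in seq_len(n_fine)) {
    j <- seq_len(min(s, length(kern)))
    conv[s] <- sum(x[s - j + 1] * kern[j]) * dt
  }
  oracle <- conv[round((seq_len(n_scans) - 1) * tr / dt) + 1]
  expect_equal(dm$X[, "z1"], oracle, tolerance = 1e-10)
})

test_that("design construction is linear in the event list", {
  ids <- sprintf("s%02d", 1:8)
  Z <- rand_latents(ids, 2, seed = 31)
  ev_a <- event_table(seq(10, 31, by = 3), 1, "train_face", ids[1:8])
  ev_b <- event_table(seq(50, 62, by = 3) + 0.0, 1, "train_face",
                      sample(ids, 5))
  both <- validate_events(rbind(ev_a[names(ev_a) != ".index"],
                                ev_b[names(ev_b) != ".index"]))
  d_a <- build_design(ev_a, Z, 60, 2)
  d_b <- build_design(ev_b, Z, 60, 2)
  d_ab <- build_design(both, Z, 60, 2)
  stim <- c("bias", "z1", "z2")
  expect_equal(d_ab$X[, stim], d_a$X[, stim] + d_b$X[, stim],
               tolerance = 1e-10)
})

test_that("delaying all events by m TR shifts the stimulus columns by m rows", {
  ids <- c("a", "b", "c")
  Z <- rand_latents(ids, 2, seed = 32)
  ev <- event_table(c(10, 16, 25), 1, "train_face", ids)
  m <- 3; tr <- 2
  ev_shift <- ev
  ev_shift$onset <- ev$onset + m * tr
  d0 <- build_design(ev, Z, 50, tr)
  d1 <- build_design(ev_shift, Z, 50, tr)
  stim <- c("bias", "z1", "z2")
  rows <- 1:(50 - m)
  expect_equal(d1$X[rows + m, stim], d0$X[rows, stim], tolerance = 1e-10)
})

test_that("independent latents give a full-rank design", {
  ids <- sprintf("s%02d", 1:40)
  Z <- rand_latents(ids, 6, seed = 33)
  ev <- event_table(6 + 3 * (0:39), 1, "train_face", ids)
  dm <- build_design(ev, Z, 70, 2)
  expect_true(dm$full_rank)
  expect_equal(dm$rank, ncol(dm$X))
})

test_that("one-back repeats get a nuisance column and stay out of the parametric set", {
  ids <- c("a", "b")
  Z <- rand_latents(ids, 1, seed = 34)
  ev_plain <- event_table(c(10, 20), 1, "train_face", ids)
  ev_ob <- validate_events(data.frame(
    onset = c(10, 20, 23), duration = 1,
    trial_type = c("train_face", "train_face", "one_back"),
    stim_id = c("a", "b", "b")))
  d_plain <- build_design(ev_plain, Z, 40, 2)
  d_ob <- build_design(ev_ob, Z, 40, 2)
  expect_true("one_back" %in% d_ob$names)
  expect_equal(d_ob$role[d_ob$names == "one_back"], "nuisance")
  expect_equal(d_ob$X[, "z1"], d_plain$X[, "z1"])   # parametric unchanged
})

test_that("face types can be demoted to per-stimulus categorical columns", {
  ids <- c("tr1", "te1", "te2")
  Z <- rand_latents(ids, 2, seed = 35)
  ev <- event_table(c(10, 20, 30, 40), 1,
                    c("train_face", "test_face", "test_face", "test_face"),
                    c("tr1", "te1", "te2", "te1"))
  dm <- build_design(ev, Z, 40, 2, bias_types = "train_face",
                     parametric_types = "train_face")
  expect_true(all(c("stim_te1", "stim_te2") %in% dm$names))
  expect_equal(sum(dm$role == "latent"), 2)
  # bias counts only the training face
  one <- build_design(ev[ev$trial_type == "train_face", ], Z, 40, 2)
  expect_equal(dm$X[, "bias"], one$X[, "bias"])
  expect_error(build_design(ev, Z, 40, 2, bias_types = "train_face",
                            parametric_types = c("train_face", "test_face")),
               "subset")
})

test_that("event validation catches malformed tables", {
  expect_error(event_table(-1, 1, "train_face", "a"), "non-negative")
  expect_error(event_table(1, 0, "train_face", "a"), "positive")
  expect_error(event_table(1, 1, "banana", "a"), "trial_type")
  ev <- event_table(10, 1, "train_face", "a")
  expect_error(build_design(ev, NULL, 40, 2), "latent")
  Zb <- matrix(0.3, 1, 1, dimnames = list("b", NULL))
  expect_error(build_design(ev, Zb, 40, 2), "missing for stimulus")
  expect_error(build_design(ev, NULL, 4, 2), "beyond the run")
})

test_that("schedule onsets fall on the 3 s trial grid", {
  sch <- make_schedule(30, 5, 3, seed = 2)
  ev <- sch$runs[[1]]
  faces <- ev[ev$trial_type != "imagery", ]
  expect_true(all(diff(faces$onset) %% 3 == 0))
  expect_true(all(diff(faces$onset) > 0))
})
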