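test_that("perfect estimates give perfect recognition", {
  set.seed(71)
  truths <- matrix(rnorm(20 * 12), 20)
  r <- recognition(truths, truths, n_draws = 500, seed = 1)
  expect_equal(r$pairwise_accuracy, 1)
  expect_equal(r$full_accuracy, 1)
  expect_equal(r$n_comparisons, 20 * 19)
  expect_error(recognition(truths[1, , drop = FALSE],
                           truths[1, , drop = FALSE]), "at least 2")
  bad <- truths; bad[1, ] <- 5
  expect_error(recognition(bad, truths), "zero-variance")
})

test_that("pairwise accuracy equals brute-force pair enumeration", {
  set.seed(72)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    est <- matrix(rnorm(n * 6), n)
    tru <- matrix(rnorm(n * 6), n)
    r <- recognition(est, tru, n_draws = 100, seed = 1)
    # oracle: loop over every ordered (target, distractor) pair
    C <- cor(t(est), t(tru))
    wins <- 0; total <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      total <- total + 1
      if (C[i, i] > C[i, j]) wins <- wins + 1
    }
    expect_equal(r$pairwise_accuracy, wins / total, tolerance = 1e-12)
    expect_equal(r$full_accuracy,
                 mean(vapply(seq_len(n), function(i)
                   all(C[i, i] > C[i, -i]), logical(1))))
  }
})

test_that("the Monte-Carlo null is centred on chance", {
  nt <- pairwise_null_test(0.9, n_items = 10, n_candidates = 20,
                           n_draws = 100000, seed = 3)
  se <- nt$sd / sqrt(nt$n_draws)
  expect_lt(abs(nt$mean - 0.5), 3 * se)
})

test_that("small Monte-Carlo nulls agree with exhaustive enumeration", {
  # oracle: all 3^2 equally likely rank pairs for 2 items, 3 candidates
  ranks <- expand.grid(1:3, 1:3)
  acc <- rowMeans((3 - ranks) / 2)
  observed <- 0.75
  p_exact <- mean(acc >= observed)
  nt <- pairwise_null_test(observed, 2, 3, n_draws = 200000, seed = 4)
  se <- sqrt(p_exact * (1 - p_exact) / nt$n_draws)
  expect_lt(abs(nt$p - p_exact), 3 * se + 2 / nt$n_draws)
})

test_that("an unreachable observation gets the add-one floor", {
  nt <- pairwise_null_test(1.0, 20, 20, n_draws = 5000, seed = 5)
  expect_equal(nt$p, 1 / 5001)
})

test_that("the exhaustive group null enumerates every outcome", {
  g <- group_null_exhaustive(0.7, n_subjects = 4, n_candidates = 20)
  expect_true(g$exhaustive)
  expect_equal(g$n_draws, 20^4)
  expect_equal(group_null_exhaustive(0, 2, 3)$p, 1)   # lower bound
  # 2 subjects x 3 candidates against a 9-case hand enumeration
  hand <- expand.grid(r1 = 1:3, r2 = 1:3)
  hand_acc <- (((3 - hand$r1) / 2) + ((3 - hand$r2) / 2)) / 2
  for (obs in c(0.25, 0.5, 0.75, 1)) {
    expect_equal(group_null_exhaustive(obs, 2, 3)$p,
                 mean(hand_acc >= obs))
  }
  expect_error(group_null_exhaustive(0.5, 10, 20), "sampled")
})

test_that("sampled and exhaustive group nulls agree within 3 SE", {
  obs <- 0.7
  ex <- group_null_exhaustive(obs, 4, 20)
  sam <- group_null_sampled(obs, 4, 20, n_draws = 100000, seed = 6)
  se <- sqrt(ex$p * (1 - ex$p) / sam$n_draws)
  expect_lt(abs(sam$p - ex$p), 3 * se + 2 / sam$n_draws)
})

test_that("binomial full-recognition tail matches direct PMF summation", {
  expect_equal(binomial_full_test(0, 20, 20), 1)
  expect_equal(binomial_full_test(20, 20, 20), (1 / 20)^20)
  # oracle: explicit PMF sum
  p <- 1 / 20
  oracle <- sum(vapply(13:20, function(k)
    choose(20, k) * p^k * (1 - p)^(20 - k), numeric(1)))
  expect_equal(binomial_full_test(13, 20, 20), oracle, tolerance = 1e-12)
  expect_error(binomial_full_test(21, 20, 20), "<=")
})

test_that("perceptual rating designs count comparisons exactly", {
  pr <- perceptual_binomial(913, n_subjects = 4, n_images = 20,
                            n_ratings = 15)
  expect_equal(pr$n_comparisons, 1200)
  expect_equal(pr$proportion, 913 / 1200)
  expect_lt(pr$p, 1e-10)
})

test_that("Friedman statistic matches its rank-sum formula and stats::friedman.test", {
  # consistent ordering, 4 subjects x 2 conditions
  scores <- cbind(a = c(2, 3, 4, 5), b = c(1, 2, 3, 4))
  f <- friedman_test(scores)
  expect_equal(f$chisq, 4)
  expect_equal(f$df, 1)
  # all-identical table: midranks give chi-square 0
  expect_equal(friedman_test(matrix(1, 4, 3))$chisq, 0)
  # tie-free random table against the independent base-R implementation
  set.seed(73)
  tab <- matrix(rnorm(12), 4, 3)
  ref <- stats::friedman.test(tab)
  f2 <- friedman_test(tab)
  expect_equal(f2$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(f2$p, ref$p.value, tolerance = 1e-12)
  expect_error(friedman_test(matrix(1, 1, 3)), "at least 2")
})

test_that("SSIM matches an independent sliding-window oracle", {
  set.seed(74)
  a <- matrix(runif(16 * 16), 16)
  b <- a + matrix(rnorm(16 * 16, sd = 0.1), 16)
  w <- 5; C1 <- 0.01^2; C2 <- 0.03^2
  vals <- c()
  for (i in 1:(16 - w + 1)) for (j in 1:(16 - w + 1)) {
    pa <- a[i:(i + w - 1), j:(j + w - 1)]
    pb <- b[i:(i + w - 1), j:(j + w - 1)]
    vals <- c(vals, (2 * mean(pa) * mean(pb) + C1) *
                (2 * cov(as.numeric(pa), as.numeric(pb)) + C2) /
                ((mean(pa)^2 + mean(pb)^2 + C1) *
                   (var(as.numeric(pa)) + var(as.numeric(pb)) + C2)))
  }
  expect_equal(ssim(a, b, window = 5), mean(vals), tolerance = 1e-12)
  expect_equal(ssim(a, a), 1)
  # identical up to a constant shift, huge stabilisers: similarity ~ 1
  expect_gt(ssim(a, a + 0.1, k1 = 10, k2 = 10), 0.999)
  # structureless comparison: near zero
  set.seed(75)
  expect_lt(abs(ssim(matrix(0.5, 32, 32) + matrix(rnorm(1024, sd = 1e-6), 32),
                     matrix(runif(1024), 32))), 0.05)
  expect_error(ssim(a, a[1:8, 1:8]), "identical shape")
})

test_that("variance partitioning decomposes and sums exactly", {
  set.seed(76)
  truths <- matrix(rnorm(30 * 5), 30)
  noise1 <- matrix(rnorm(30 * 5), 30)
  # perfect single predictor
  vp <- variance_partition(truths, truths, noise1,
                           matrix(rnorm(150), 30))
  expect_equal(vp$r2_full, 1, tolerance = 1e-10)
  expect_gt(vp$unique_occipital, 0.9)
  # total redundancy: all shared
  same <- truths + noise1
  vp2 <- variance_partition(truths, same, same, same)
  expect_equal(vp2$shared_all, vp2$r2_full, tolerance = 1e-10)
  expect_lt(max(abs(unlist(vp2[c("unique_occipital", "unique_temporal",
                                 "unique_frontoparietal")]))), 1e-10)
  # components always sum to the full-model R2
  vp3 <- variance_partition(truths, truths + noise1,
                            matrix(rnorm(150), 30), noise1)
  expect_equal(sum(unlist(vp3[1:7])), vp3$r2_full, tolerance = 1e-10)
})

test_that("variance partition components match explicit nested regressions", {
  # 3 faces x 2 dims, pooled into 6 observations
  truths <- matrix(c(1, 2, 3, -1, 0, 2), 3)
  occ <- matrix(c(1.1, 1.8, 3.2, -0.8, 0.1, 1.9), 3)
  tmp <- matrix(c(0.5, 2.5, 2.0, -1.5, 0.6, 1.2), 3)
  fp <- matrix(c(0, 1, 0, 1, 0, 1), 3)
  vp <- variance_partition(truths, occ, tmp, fp)
  y <- as.numeric(truths)
  r2 <- function(...) summary(lm(y ~ cbind(...)))$r.squared
  R_o <- r2(as.numeric(occ)); R_t <- r2(as.numeric(tmp))
  R_f <- r2(as.numeric(fp))
  R_ot <- r2(as.numeric(occ), as.numeric(tmp))
  R_of <- r2(as.numeric(occ), as.numeric(fp))
  R_tf <- r2(as.numeric(tmp), as.numeric(fp))
  R_otf <- r2(as.numeric(occ), as.numeric(tmp), as.numeric(fp))
  expect_equal(vp$unique_occipital, R_otf - R_tf, tolerance = 1e-10)
  expect_equal(vp$unique_frontoparietal, R_otf - R_ot, tolerance = 1e-10)
  expect_equal(vp$shared_occ_temp, R_of + R_tf - R_f - R_otf,
               tolerance = 1e-10)
  expect_equal(vp$shared_all,
               R_o + R_t + R_f - R_ot - R_of - R_tf + R_otf,
               tolerance = 1e-10)
  expect_equal(vp$r2_full, R_otf, tolerance = 1e-10)
})
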