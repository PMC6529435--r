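#' @section Identification metrics and nulls:
#' Decoded latent vectors are scored by Pearson correlation with every
#' candidate ground-truth vector.  Pairwise recognition counts, for each
#' item, the fraction of distractors whose correlation falls below the
#' target's -- equivalently `(n - rank)/(n - 1)` where `rank` is the
#' target's position (1 = best).  Full recognition requires rank 1 (chance
#' `1/n`).  Because the pairwise comparisons for one item share the same
#' estimate, they are not independent, so significance uses rank-based
#' nulls: a Monte-Carlo surrogate distribution built from independent
#' uniform target ranks, or -- for small group designs -- the exhaustive
#' enumeration of every possible rank combination.  Empirical p-values use
#' the add-one rule and count ties against the observation (conservative).
#' @name evaluation
NULL

#' Score decoded latents against candidate ground-truth latents
#'
#' @param estimates matrix of decoded latent vectors (n_items x d), a
#'   `decoded_latents` object, or a list of vectors.
#' @param truths matrix of ground-truth latent vectors, same layout; row i
#'   is the true target of estimate i, all rows act as candidates.
#' @param n_draws Monte-Carlo draws for the pairwise p-value.
#' @param seed seed for the Monte-Carlo null.
#' @return object of class `recognition_result`: per-item target ranks and
#'   correlations, `pairwise_accuracy`, `full_accuracy`, `n_comparisons`
#'   (ordered target-distractor pairs), and p-values (`p_pairwise`
#'   Monte-Carlo, `p_full` binomial).
#' @export
recognition <- function(estimates, truths, n_draws = 10000, seed = 1) {
  if (inherits(estimates, "decoded_latents")) estimates <- estimates$Z
  if (is.list(estimates) && !is.matrix(estimates)) estimates <- do.call(rbind, estimates)
  if (is.list(truths) && !is.matrix(truths)) truths <- do.call(rbind, truths)
  estimates <- as.matrix(estimates); truths <- as.matrix(truths)
  if (!all(dim(estimates) == dim(truths)))
    stop("estimates and truths must have identical dimensions")
  n <- nrow(truths)
  if (n < 2) stop("need at least 2 items")
  if (any(apply(estimates, 1, sd) == 0) || any(apply(truths, 1, sd) == 0))
    stop("zero-variance latent vector: correlation undefined")
  C <- cor(t(estimates), t(truths))        # C[i, j] = cor(estimate i, truth j)
  ranks <- vapply(seq_len(n), function(i)
    1L + sum(C[i, -i] >= C[i, i]), integer(1))
  pairwise <- mean(rank_accuracy(ranks, n, "pairwise"))
  full <- mean(rank_accuracy(ranks, n, "full"))
  pw <- pairwise_null_test(pairwise, n_items = n, n_candidates = n,
                           n_draws = n_draws, seed = seed)
  structure(list(ranks = ranks, correlations = C,
                 pairwise_accuracy = pairwise, full_accuracy = full,
                 n_comparisons = n * (n - 1L),
                 p_pairwise = pw$p,
                 p_full = binomial_full_test(sum(ranks == 1), n, n)),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  cat(sprintf("recognition_result: %d items, %d ordered pairwise comparisons\n",
              length(x$ranks), x$n_comparisons))
  cat(sprintf("pairwise accuracy %.1f%% (Monte-Carlo p = %.3g), full recognition %.1f%% (binomial p = %.3g)\n",
              100 * x$pairwise_accuracy, x$p_pairwise,
              100 * x$full_accuracy, x$p_full))
  invisible(x)
}

#' Monte-Carlo rank null for pairwise decoding accuracy
#'
#' Under the null the target's rank among the candidates is uniform on
#' `1..n_candidates` for every item.  Each draw samples `n_items`
#' independent uniform ranks and converts them to a surrogate accuracy
#' `mean((n_candidates - rank)/(n_candidates - 1))`; the p-value is
#' `(1 + #{surrogate >= observed}) / (n_draws + 1)`.
#'
#' @param observed observed pairwise accuracy in \[0, 1\].
#' @param n_items number of test items.
#' @param n_candidates number of candidate latent vectors.
#' @param n_draws Monte-Carlo draws (>= 1).
#' @param seed RNG seed.
#' @param keep_null return the surrogate values?
#' @return list of class `null_distribution` with `p`, `mean`, `sd`,
#'   `n_draws`, `seed`, `exhaustive = FALSE` and (optionally) `values`.
#' @export
pairwise_null_test <- function(observed, n_items, n_candidates, n_draws,
                               seed = 1, keep_null = FALSE) {
  n_items <- assert_scalar_count(n_items, "n_items")
  n_candidates <- assert_scalar_count(n_candidates, "n_candidates", min = 2)
  n_draws <- assert_scalar_count(n_draws, "n_draws")
  set.seed(seed)
  exceed <- 0
  total <- 0
  s1 <- 0; s2 <- 0
  values <- if (keep_null) numeric(n_draws) else NULL
  chunk <- 100000L
  done <- 0L
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    ranks <- matrix(sample.int(n_candidates, m * n_items, replace = TRUE),
                    m, n_items)
    acc <- rowMeans((n_candidates - ranks) / (n_candidates - 1))
    exceed <- exceed + sum(acc >= observed)
    s1 <- s1 + sum(acc); s2 <- s2 + sum(acc^2)
    if (keep_null) values[done + seq_len(m)] <- acc
    done <- done + m
  }
  mu <- s1 / n_draws
  sdv <- sqrt(max(0, s2 / n_draws - mu^2) * n_draws / max(1, n_draws - 1))
  structure(list(p = (1 + exceed) / (n_draws + 1), mean = mu, sd = sdv,
                 n_draws = n_draws, seed = seed, exhaustive = FALSE,
                 values = values),
            class = "null_distribution")
}

#' Exhaustive group-level rank null
#'
#' Enumerates every possible combination of per-subject target ranks
#' (`n_candidates ^ n_subjects` outcomes), converts each to a group-mean
#' pairwise accuracy, and returns the exact upper-tail probability of the
#' observed group mean.
#'
#' @param observed observed group-mean pairwise accuracy in \[0, 1\].
#' @param n_subjects number of subjects.
#' @param n_candidates number of candidates per subject.
#' @param max_outcomes refuse to enumerate beyond this many outcomes.
#' @return list of class `null_distribution` with exact `p`, `n_draws`
#'   (= number of enumerated outcomes) and `exhaustive = TRUE`.
#' @export
group_null_exhaustive <- function(observed, n_subjects, n_candidates,
                                  max_outcomes = 1e7) {
  n_subjects <- assert_scalar_count(n_subjects, "n_subjects")
  n_candidates <- assert_scalar_count(n_candidates, "n_candidates", min = 2)
  n_out <- n_candidates^n_subjects
  if (n_out > max_outcomes)
    stop(sprintf("%g outcomes exceed max_outcomes = %g; use group_null_sampled()",
                 n_out, max_outcomes))
  acc <- (n_candidates - seq_len(n_candidates)) / (n_candidates - 1)
  group <- acc
  for (s in seq_len(n_subjects - 1))
    group <- as.numeric(outer(group, acc, `+`))
  group <- group / n_subjects
  structure(list(p = sum(group >= observed) / n_out,
                 mean = mean(group), sd = sd(group),
                 n_draws = n_out, seed = NA, exhaustive = TRUE,
                 values = NULL),
            class = "null_distribution")
}

#' Sampled group-level rank null
#'
#' Monte-Carlo version of [group_null_exhaustive()] for designs too large
#' to enumerate; add-one p-value rule.
#'
#' @inheritParams group_null_exhaustive
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @return a `null_distribution` (sampled).
#' @export
group_null_sampled <- function(observed, n_subjects, n_candidates, n_draws,
                               seed = 1) {
  n_subjects <- assert_scalar_count(n_subjects, "n_subjects")
  pairwise_null_test(observed, n_items = n_subjects,
                     n_candidates = n_candidates, n_draws = n_draws,
                     seed = seed)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %s, %g draws, mean %.4f, sd %.4f, p = %.4g\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_draws, x$mean, x$sd, x$p))
  invisible(x)
}

#' Upper-tail binomial test for full recognition
#'
#' `P(K >= k)` for `K ~ Binomial(n_items, 1/n_candidates)`.
#'
#' @param k_correct number of items identified exactly (rank 1).
#' @param n_items number of test items.
#' @param n_candidates number of candidates (success probability
#'   `1/n_candidates`).
#' @return the p-value.
#' @export
binomial_full_test <- function(k_correct, n_items, n_candidates) {
  if (k_correct < 0 || k_correct > n_items) stop("need 0 <= k <= n")
  pbinom(k_correct - 1, n_items, 1 / n_candidates, lower.tail = FALSE)
}

#' Two-sided preference count and binomial test for perceptual ratings
#'
#' Utility for rating designs in which every reconstruction pair is judged
#' a fixed number of times: `n_subjects x n_images x n_ratings`
#' comparisons, tested against indifference (probability 1/2).
#'
#' @param k_preferred comparisons won by the first option.
#' @param n_subjects,n_images,n_ratings design counts.
#' @return list with `n_comparisons`, `proportion`, and upper-tail `p`.
#' @export
perceptual_binomial <- function(k_preferred, n_subjects, n_images, n_ratings) {
  n <- as.integer(n_subjects * n_images * n_ratings)
  if (k_preferred < 0 || k_preferred > n) stop("need 0 <= k <= n comparisons")
  list(n_comparisons = n, proportion = k_preferred / n,
       p = pbinom(k_preferred - 1, n, 0.5, lower.tail = FALSE))
}

#' Friedman rank test for repeated measures
#'
#' Classic chi-square approximation from within-subject midranks:
#' `chi2 = 12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)` with `R_j` the rank sum
#' of condition `j`, `df = k - 1`.  Midranks make constant rows legal
#' (an all-constant table gives chi-square 0).
#'
#' @param scores numeric matrix, subjects in rows, conditions in columns.
#' @return list of class `friedman_result` with `chisq`, `df`, `p`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  R <- t(apply(scores, 1, rank))           # midranks within subject
  Rj <- colSums(R)
  chisq <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  df <- k - 1
  structure(list(chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE)),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-square(%d) = %.4g, p = %.4g\n", x$df, x$chisq, x$p))
  invisible(x)
}

#' Structural similarity (SSIM) between two images
#'
#' Mean over all sliding windows of the standard
#' luminance-contrast-structure product
#' `(2 mu_a mu_b + C1)(2 cov_ab + C2) / ((mu_a^2 + mu_b^2 + C1)(var_a + var_b + C2))`
#' with `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.  Window statistics use the
#' unbiased (n-1) normalisation.
#'
#' @param a,b numeric matrices of identical shape.
#' @param window square window side in pixels (default 8).
#' @param k1,k2 stabilising constants (defaults 0.01, 0.03).
#' @param dynamic_range data range `L` (default 1 for \[0,1\] images).
#' @return similarity in \[-1, 1\].
#' @export
ssim <- function(a, b, window = 8, k1 = 0.01, k2 = 0.03, dynamic_range = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("images must have identical shape")
  w <- assert_scalar_count(window, "window", min = 2)
  if (any(dim(a) < w)) stop("window larger than the image")
  C1 <- (k1 * dynamic_range)^2
  C2 <- (k2 * dynamic_range)^2
  # box sums over all w x w windows via integral images
  int <- function(m) {
    s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative sums
    s <- t(s)
    S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
    S[-1, -1] <- s
    nr <- nrow(m) - w + 1; nc <- ncol(m) - w + 1
    S[(w + 1):(nrow(m) + 1), (w + 1):(ncol(m) + 1)] -
      S[1:nr, (w + 1):(ncol(m) + 1)] -
      S[(w + 1):(nrow(m) + 1), 1:nc] + S[1:nr, 1:nc]
  }
  n <- w * w
  mu_a <- int(a) / n; mu_b <- int(b) / n
  var_a <- (int(a * a) - n * mu_a^2) / (n - 1)
  var_b <- (int(b * b) - n * mu_b^2) / (n - 1)
  cov_ab <- (int(a * b) - n * mu_a * mu_b) / (n - 1)
  s_map <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s_map)
}

#' Variance partitioning of region-wise latent predictions
#'
#' Commonality analysis: the ground-truth latent values (all items and
#' dimensions pooled) are regressed on every non-empty subset of the three
#' region-wise predictions, and the seven nested R-squared values are
#' decomposed into unique and shared components, which sum exactly to the
#' full-model R-squared.
#'
#' @param truths ground-truth latent matrix (n_items x d).
#' @param est_occ,est_temp,est_fp region-wise predicted latent matrices of
#'   the same shape.
#' @return list of class `variance_partition` with components
#'   `unique_occipital`, `unique_temporal`, `unique_frontoparietal`,
#'   `shared_occ_temp`, `shared_occ_fp`, `shared_temp_fp`, `shared_all`,
#'   plus `r2_full` and the seven subset `r2` values.
#' @export
variance_partition <- function(truths, est_occ, est_temp, est_fp) {
  mats <- list(truths, est_occ, est_temp, est_fp)
  dims <- lapply(mats, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all four latent sets must share one shape")
  y <- as.numeric(as.matrix(truths))
  P <- cbind(o = as.numeric(as.matrix(est_occ)),
             t = as.numeric(as.matrix(est_temp)),
             f = as.numeric(as.matrix(est_fp)))
  r2 <- function(cols) {
    X <- cbind(1, P[, cols, drop = FALSE])
    beta <- pinv_solve(crossprod(X), crossprod(X, y), warn = FALSE)
    res <- y - X %*% beta
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  R <- list(o = r2("o"), t = r2("t"), f = r2("f"),
            ot = r2(c("o", "t")), of = r2(c("o", "f")), tf = r2(c("t", "f")),
            otf = r2(c("o", "t", "f")))
  out <- list(
    unique_occipital = R$otf - R$tf,
    unique_temporal = R$otf - R$of,
    unique_frontoparietal = R$otf - R$ot,
    shared_occ_temp = R$of + R$tf - R$f - R$otf,
    shared_occ_fp = R$ot + R$tf - R$t - R$otf,
    shared_temp_fp = R$ot + R$of - R$o - R$otf,
    shared_all = R$o + R$t + R$f - R$ot - R$of - R$tf + R$otf,
    r2_full = R$otf, r2 = R)
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  comp <- unlist(x[1:7])
  cat("variance_partition (components sum to full-model R2):\n")
  for (nm in names(comp)) cat(sprintf("  %-22s %+.4f\n", nm, comp[nm]))
  cat(sprintf("  full-model R2          %.4f\n", x$r2_full))
  invisible(x)
}
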