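#' @section Voxel selection:
#' Decoding operates on a region of interest chosen by two criteria, both
#' computed from training-run responses only: (i) the voxel responds to
#' faces (t statistic of the face-vs-fixation bias regressor in a baseline
#' model with only a binary face regressor), and (ii) adding the latent
#' face features as regressors improves the voxel's explained variance
#' (delta R-squared between the full and baseline models).  The selection
#' is then split geometrically into three equal subsets: the most posterior
#' third ("occipital"); the remainder halved along a second anatomical axis
#' into "temporal" and "frontoparietal".
#' @name voxel_selection
NULL

#' Per-voxel selection statistics
#'
#' @param design_full design with bias + latent columns ([build_design()]).
#' @param design_baseline nested design with the bias column but no latent
#'   columns (binary face regressor only).
#' @param Y voxel time series shared by both designs.
#' @param coords optional n_voxels x 3 coordinate matrix carried through.
#' @return object of class `voxel_stats`: data frame with one row per
#'   voxel: `t` (face-vs-baseline), `dr2` (R2_full - R2_baseline), and
#'   coordinates when given.
#' @export
compute_voxel_stats <- function(design_full, design_baseline, Y,
                                coords = NULL) {
  stopifnot(inherits(design_full, "design_matrix"),
            inherits(design_baseline, "design_matrix"))
  Y <- as.matrix(Y)
  Xf <- design_full$X
  Xb <- design_baseline$X
  if (nrow(Xf) != nrow(Y) || nrow(Xb) != nrow(Y))
    stop("designs and data must share rows")
  # nesting: every baseline column must appear in the full design
  in_full <- vapply(seq_len(ncol(Xb)), function(j) {
    any(vapply(seq_len(ncol(Xf)),
               function(k) isTRUE(all.equal(Xb[, j], Xf[, k], tolerance = 1e-10)),
               logical(1)))
  }, logical(1))
  if (!all(in_full))
    stop("baseline design is not nested in the full design")

  fit_r2 <- function(X) {
    beta <- tryCatch(solve(crossprod(X), crossprod(X, Y)),
                     error = function(e) pinv_solve(crossprod(X), crossprod(X, Y)))
    resid <- Y - X %*% beta
    tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
    list(beta = beta, resid = resid,
         r2 = 1 - colSums(resid^2) / pmax(tss, .Machine$double.eps))
  }
  fb <- fit_r2(Xb)
  ff <- fit_r2(Xf)

  # t statistic of the bias (face) coefficient in the baseline model
  bias_col <- which(design_baseline$role == "bias")
  if (length(bias_col) != 1) stop("baseline design must have one bias column")
  df <- nrow(Y) - qr(Xb)$rank
  XtXinv <- tryCatch(solve(crossprod(Xb)),
                     error = function(e) pseudo_inverse(crossprod(Xb), warn = FALSE))
  sigma2 <- colSums(fb$resid^2) / df
  se <- sqrt(XtXinv[bias_col, bias_col] * sigma2)
  tstat <- fb$beta[bias_col, ] / pmax(se, .Machine$double.xmin)

  out <- data.frame(voxel = seq_len(ncol(Y)), t = tstat, dr2 = ff$r2 - fb$r2)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == ncol(Y))
    out <- cbind(out, a1 = coords[, 1], a2 = coords[, 2],
                 a3 = if (ncol(coords) >= 3) coords[, 3] else 0)
  }
  class(out) <- c("voxel_stats", "data.frame")
  out
}

#' Voxel selection policies
#'
#' `conjunction` keeps voxels with `t > t_min` and `dr2 > dr2_min`;
#' `top_fraction` ranks voxels by the sum of their within-criterion ranks
#' (larger t and larger delta-R2 rank higher) and keeps the top fraction.
#' Raising either conjunction threshold never adds voxels; ties in the
#' rank-sum are broken by voxel index for determinism.
#'
#' @param type `"conjunction"` or `"top_fraction"`.
#' @param t_min,dr2_min thresholds for `conjunction`.
#' @param fraction fraction in (0, 1\] for `top_fraction`.
#' @return list of class `selection_policy`.
#' @export
selection_policy <- function(type = c("top_fraction", "conjunction"),
                             fraction = 0.3, t_min = 0, dr2_min = 0) {
  type <- match.arg(type)
  if (type == "top_fraction" && (fraction <= 0 || fraction > 1))
    stop("fraction must be in (0, 1]")
  structure(list(type = type, fraction = fraction, t_min = t_min,
                 dr2_min = dr2_min), class = "selection_policy")
}

#' Select voxels for decoding
#'
#' @param stats a [compute_voxel_stats()] result (training runs only; test
#'   data never enter the selection).
#' @param policy a [selection_policy()].
#' @return sorted integer vector of selected voxel indices.
#' @export
select_voxels <- function(stats, policy = selection_policy()) {
  stopifnot(inherits(stats, "voxel_stats"), inherits(policy, "selection_policy"))
  idx <- if (policy$type == "conjunction") {
    which(stats$t > policy$t_min & stats$dr2 > policy$dr2_min)
  } else {
    score <- rank(stats$t, ties.method = "average") +
      rank(stats$dr2, ties.method = "average")
    k <- max(1L, floor(policy$fraction * nrow(stats)))
    ord <- order(-score, stats$voxel)
    sort(stats$voxel[ord[seq_len(k)]])
  }
  if (!length(idx))
    stop("selection is empty; lower t_min/dr2_min or raise the fraction")
  as.integer(idx)
}

#' Split a voxel selection into three equal anatomical subsets
#'
#' The third of voxels with the smallest posterior-anterior coordinate
#' (axis 1) is labelled `occipital`.  The remaining voxels are halved at
#' the median of a second axis: the lower half is `temporal`, the upper
#' half `frontoparietal`.  Subset sizes differ pairwise by at most one;
#' ties at either cut are broken by voxel index.
#'
#' @param selection integer voxel indices.
#' @param coords coordinate matrix for *all* voxels (rows indexed by the
#'   selection), axis 1 = posterior to anterior.
#' @param split_axis which coordinate column separates temporal from
#'   frontoparietal (default 2; the anatomical sense of that axis is a
#'   dataset convention, hence configurable).
#' @return object of class `region_partition`: list with `occipital`,
#'   `temporal`, `frontoparietal` (voxel index vectors) and `labels`
#'   (factor aligned with `selection`).
#' @export
split_regions <- function(selection, coords, split_axis = 2) {
  coords <- as.matrix(coords)
  selection <- as.integer(selection)
  if (any(selection < 1 | selection > nrow(coords)))
    stop("selection indices outside the coordinate table")
  sub <- coords[selection, , drop = FALSE]
  if (nrow(unique(sub)) == 1)
    stop("degenerate geometry: all selected voxels share one coordinate")
  n <- length(selection)
  sizes <- c(n %/% 3 + (n %% 3 >= 1), n %/% 3 + (n %% 3 >= 2), n %/% 3)
  ord1 <- order(sub[, 1], selection)
  occ <- selection[ord1[seq_len(sizes[1])]]
  rest <- selection[ord1[-seq_len(sizes[1])]]
  rest_c <- coords[rest, split_axis]
  ord2 <- order(rest_c, rest)
  temporal <- rest[ord2[seq_len(sizes[2])]]
  fronto <- rest[ord2[-seq_len(sizes[2])]]
  labels <- factor(rep(NA_character_, n), levels = .REGIONS)
  labels[match(occ, selection)] <- "occipital"
  labels[match(temporal, selection)] <- "temporal"
  labels[match(fronto, selection)] <- "frontoparietal"
  structure(list(occipital = sort(occ), temporal = sort(temporal),
                 frontoparietal = sort(fronto), labels = labels,
                 selection = selection, split_axis = split_axis),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: occipital %d, temporal %d, frontoparietal %d voxels (split axis %d)\n",
              length(x$occipital), length(x$temporal),
              length(x$frontoparietal), x$split_axis))
  invisible(x)
}
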