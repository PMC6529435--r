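#' @section The linear brain decoder:
#' The encoding model assumes every voxel's activation is a weighted sum of
#' the latent face features plus a constant bias, `Y = X W` with `X` the
#' (n_samples x d+1) latent-plus-bias matrix and `W` the (d+1 x n_voxels)
#' weight matrix.  Training solves the normal equations
#' `W = (X'X)^-1 X'Y`; decoding inverts the system for a new activation
#' pattern `y`: `x = y W' (W W')^-1`, whose first coefficient is the bias
#' estimate (retained but unused downstream) and the rest the decoded
#' latent vector.
#' @name brain_decoder
NULL

#' Fit the voxel weight matrix by closed-form least squares
#'
#' Estimates all regression coefficients of the design, then extracts the
#' bias and latent rows into the `(d+1) x n_voxels` weight-matrix layout
#' (row 1 = bias); nuisance coefficients are discarded.  If `X'X` is
#' numerically rank-deficient the pseudo-inverse (relative cutoff `1e-10`)
#' is used and a warning logged.
#'
#' @param design a [build_design()] object containing bias and latent
#'   columns.
#' @param Y voxel time-series matrix (`n_scans` x `n_voxels`), rows aligned
#'   with the design.
#' @return object of class `weight_matrix`: list with `W`
#'   (`(d+1) x n_voxels`), `d`, `voxel_index`, and `diagnostics`
#'   (condition number of `X'X`, per-voxel R-squared).
#' @export
fit_weights <- function(design, Y) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(Y)
  X <- design$X
  if (nrow(X) != nrow(Y))
    stop(sprintf("design has %d rows but Y has %d", nrow(X), nrow(Y)))
  if (design$d < 1) stop("design contains no latent columns; nothing to fit")
  XtX <- crossprod(X)
  sv <- svd(XtX, nu = 0, nv = 0)$d
  condition <- max(sv) / max(min(sv), .Machine$double.xmin)
  beta <- tryCatch(solve(XtX, crossprod(X, Y)),
                   error = function(e) pinv_solve(XtX, crossprod(X, Y)))
  resid <- Y - X %*% beta
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- 1 - colSums(resid^2) / pmax(tss, .Machine$double.eps)
  keep <- design$role %in% c("bias", "latent")
  W <- beta[keep, , drop = FALSE]
  rownames(W) <- c("bias", paste0("z", seq_len(design$d)))
  structure(list(W = W, d = design$d,
                 voxel_index = seq_len(ncol(Y)),
                 diagnostics = list(condition_XtX = condition, r2 = r2)),
            class = "weight_matrix")
}

#' Wrap a raw matrix as a weight matrix
#'
#' Used by the simulator-facing analyses when the ground-truth weights are
#' taken as given rather than estimated.
#'
#' @param W numeric matrix with `d + 1` rows (row 1 = bias).
#' @param voxel_index optional index of the columns into a source dataset.
#' @return a `weight_matrix`.
#' @export
as_weight_matrix <- function(W, voxel_index = seq_len(ncol(W))) {
  W <- as.matrix(W)
  if (nrow(W) < 2) stop("weight matrix needs a bias row plus latent rows")
  if (any(!is.finite(W))) stop("weight matrix entries must be finite")
  structure(list(W = W, d = nrow(W) - 1L, voxel_index = voxel_index,
                 diagnostics = list()), class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: %d latent dims (+bias) x %d voxels\n",
              x$d, ncol(x$W)))
  if (length(x$diagnostics))
    cat(sprintf("cond(X'X) = %.3g, median voxel R2 = %.3f\n",
                x$diagnostics$condition_XtX, median(x$diagnostics$r2)))
  invisible(x)
}

#' Subset a weight matrix to a voxel selection
#'
#' @param wm a `weight_matrix`.
#' @param voxels integer indices into the weight matrix's columns.
#' @return a `weight_matrix` over the selected voxels.
#' @export
subset_weights <- function(wm, voxels) {
  stopifnot(inherits(wm, "weight_matrix"))
  out <- wm
  out$W <- wm$W[, voxels, drop = FALSE]
  out$voxel_index <- wm$voxel_index[voxels]
  if (length(wm$diagnostics))
    out$diagnostics$r2 <- wm$diagnostics$r2[voxels]
  out
}

#' Estimate per-stimulus activation patterns
#'
#' Two estimators are provided.  `"glm"` (default) models each distinct
#' test stimulus (or the imagery condition) as its own HRF-convolved
#' categorical regressor in a GLM that also contains a combined regressor
#' for all other face trials, one-back and intercept nuisance columns; the
#' pattern is the stimulus's beta row.  `"average"` averages the raw BOLD
#' samples in a window following each presentation (block averaging, the
#' natural choice for 12 s imagery trials), after removing the voxel mean.
#'
#' @param events the run's `event_table` (must contain `test_face` or
#'   `imagery` rows).
#' @param Y voxel time series (`n_scans` x n_voxels).
#' @param tr repetition time (seconds).
#' @param hrf an [hrf_spec()].
#' @param condition `"test_face"` or `"imagery"`: which rows to estimate.
#' @param method `"glm"` or `"average"`.
#' @param nuisance optional matrix of additional regressors for the GLM
#'   (e.g. the training-phase bias and parametric columns, so that
#'   responses to interleaved training faces are modelled properly).  When
#'   given, the automatic combined other-faces column is omitted.
#' @param window for `method = "average"`: seconds after onset over which
#'   to average (default: 4 s haemodynamic delay to onset + duration + 4 s).
#' @param dt fine-grid resolution for the GLM designs.
#' @return object of class `activation_patterns`: list with `patterns`
#'   (n_stimuli x n_voxels, rownames = stimulus ids), `n_trials` per
#'   stimulus, `method`, `condition`.
#' @export
estimate_test_patterns <- function(events, Y, tr, hrf = hrf_spec(),
                                   condition = c("test_face", "imagery"),
                                   method = c("glm", "average"),
                                   nuisance = NULL, window = NULL,
                                   dt = tr / 16) {
  events <- validate_events(events)
  condition <- match.arg(condition)
  method <- match.arg(method)
  Y <- as.matrix(Y)
  n_scans <- nrow(Y)
  rows <- events$trial_type == condition
  if (!any(rows)) stop(sprintf("no '%s' events in the table", condition))
  ids <- if (condition == "imagery") rep("imagery", sum(rows)) else events$stim_id[rows]
  uniq <- unique(ids)
  n_trials <- vapply(uniq, function(id) sum(ids == id), integer(1))

  if (method == "glm") {
    kernel <- hrf_kernel(hrf, dt)
    cols <- lapply(uniq, function(id) {
      sub <- which(rows)[ids == id]
      convolved_regressor(events$onset[sub], events$duration[sub],
                          rep(1, length(sub)), n_scans, tr, dt, kernel)
    })
    X <- do.call(cbind, cols)
    if (is.null(nuisance)) {
      other <- events$trial_type %in% c("train_face", "test_face",
                                        "one_back", "imagery") & !rows
      if (any(other)) {
        X <- cbind(X, convolved_regressor(events$onset[other],
                                          events$duration[other],
                                          rep(1, sum(other)),
                                          n_scans, tr, dt, kernel))
      }
    } else {
      nuisance <- as.matrix(nuisance)
      if (nrow(nuisance) != n_scans) stop("nuisance matrix must have n_scans rows")
      X <- cbind(X, nuisance)
    }
    X <- cbind(X, 1)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, Y)),
                     error = function(e) pinv_solve(crossprod(X), crossprod(X, Y)))
    patterns <- beta[seq_along(uniq), , drop = FALSE]
  } else {
    Yc <- sweep(Y, 2, colMeans(Y))
    delay <- 4
    patterns <- t(vapply(uniq, function(id) {
      sub <- which(rows)[ids == id]
      scans <- unique(unlist(lapply(sub, function(i) {
        w_end <- if (is.null(window)) events$duration[i] + 2 * delay else window
        lo <- floor((events$onset[i] + delay) / tr) + 1
        hi <- min(n_scans, ceiling((events$onset[i] + w_end) / tr))
        seq(lo, max(lo, hi))
      })))
      colMeans(Yc[scans, , drop = FALSE])
    }, numeric(ncol(Y))))
  }
  rownames(patterns) <- uniq
  structure(list(patterns = patterns, n_trials = n_trials, method = method,
                 condition = condition), class = "activation_patterns")
}

#' Decode latent vectors from activation patterns
#'
#' Inverts the linear system: `x = y W' (W W')^-1` for each pattern row
#' `y`.  All `d + 1` coefficients are returned; the first (bias) is flagged
#' unused.  `W W'` is inverted with the shared pseudo-inverse policy
#' (relative cutoff `1e-10`, warning when activated).
#'
#' @param wm a `weight_matrix`.
#' @param patterns a numeric vector (one pattern), a matrix with one
#'   pattern per row, or an `activation_patterns` object.
#' @return object of class `decoded_latents`: list with `Z` (n_patterns x
#'   d latent estimates), `bias` (per-pattern bias estimates, unused
#'   downstream), and `source` ids when available.
#' @export
decode_latent <- function(wm, patterns) {
  stopifnot(inherits(wm, "weight_matrix"))
  source_ids <- NULL
  if (inherits(patterns, "activation_patterns")) {
    source_ids <- rownames(patterns$patterns)
    patterns <- patterns$patterns
  }
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1)
  if (ncol(patterns) != ncol(wm$W))
    stop(sprintf("pattern length %d does not match the %d weight-matrix voxels",
                 ncol(patterns), ncol(wm$W)))
  WWt <- tcrossprod(wm$W)
  sv <- svd(WWt, nu = 0, nv = 0)$d
  Xhat <- if (min(sv) > 1e-10 * max(sv)) {
    patterns %*% t(wm$W) %*% solve(WWt)
  } else {
    warning("W W' numerically singular; decoding via pseudo-inverse")
    patterns %*% t(wm$W) %*% pseudo_inverse(WWt, warn = FALSE)
  }
  Z <- Xhat[, -1, drop = FALSE]
  colnames(Z) <- paste0("z", seq_len(wm$d))
  if (!is.null(source_ids)) rownames(Z) <- source_ids
  structure(list(Z = Z, bias = Xhat[, 1], source = source_ids,
                 bias_used = FALSE), class = "decoded_latents")
}

#' @export
print.decoded_latents <- function(x, ...) {
  cat(sprintf("decoded_latents: %d pattern(s) x %d latent dims (bias retained, unused)\n",
              nrow(x$Z), ncol(x$Z)))
  invisible(x)
}
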