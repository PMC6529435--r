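#' @section GLM design construction:
#' Stimulus schedules are turned into design matrices the way event-related
#' fMRI GLMs are built: every event becomes a boxcar of its stated duration
#' on a fine time grid, boxcars are convolved with a canonical double-gamma
#' haemodynamic response function, and the result is sampled at scan times.
#' The encoding model's regressors are a constant "bias" column (unit stick
#' at every face onset -- the face-vs-fixation contrast) plus one parametric
#' column per latent dimension whose stick heights are that dimension's
#' value for each stimulus.  One-back repeats and imagery blocks get their
#' own nuisance columns; fixation trials are the implicit baseline.
#' @name glm_design
NULL

.TRIAL_TYPES <- c("train_face", "test_face", "one_back", "imagery", "fixation")

#' Construct a validated event table
#'
#' @param onset event onsets in seconds from the first scan (scan 0 at t=0).
#' @param duration event durations in seconds (> 0).
#' @param trial_type one of `train_face`, `test_face`, `one_back`,
#'   `imagery`, `fixation`.
#' @param stim_id stimulus identifier (used to join latent vectors); may be
#'   `NA` for fixation/imagery rows.
#' @return data frame of class `event_table`, stably sorted by onset.
#' @export
event_table <- function(onset, duration, trial_type, stim_id = NA_character_) {
  ev <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   stim_id = as.character(stim_id),
                   stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(ev) {
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("event table lacks required column(s): ", paste(missing, collapse = ", "))
  if (!"stim_id" %in% names(ev)) ev$stim_id <- NA_character_
  if (any(!is.finite(ev$onset)) || any(ev$onset < 0))
    stop("onsets must be finite and non-negative")
  if (any(!is.finite(ev$duration)) || any(ev$duration <= 0))
    stop("durations must be positive")
  bad <- setdiff(unique(ev$trial_type), .TRIAL_TYPES)
  if (length(bad))
    stop("unknown trial_type(s): ", paste(bad, collapse = ", "))
  ord <- order(ev$onset)            # stable sort, original order kept as index
  ev$.index <- seq_len(nrow(ev))
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical haemodynamic response: a gamma-density peak
#' minus a scaled gamma-density undershoot.  Defaults are the canonical set
#' (peak 6 s, undershoot 16 s, unit dispersions, peak:undershoot ratio 6,
#' 32 s kernel).
#'
#' @param peak_delay,under_delay delays of peak/undershoot in seconds.
#' @param peak_disp,under_disp dispersions in seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length kernel length in seconds (>= 24).
#' @return list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, under_delay = 16, peak_disp = 1,
                     under_disp = 1, ratio = 6, length = 32) {
  if (length < 24) stop("HRF kernel length must be at least 24 s")
  if (any(c(peak_delay, under_delay, peak_disp, under_disp, ratio) <= 0))
    stop("all HRF parameters must be positive")
  structure(list(peak_delay = peak_delay, under_delay = under_delay,
                 peak_disp = peak_disp, under_disp = under_disp,
                 ratio = ratio, length = length),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel
#'
#' The kernel is zero at t = 0, rises to a single positive peak (near 5 s
#' with default parameters), undershoots, and is normalised to unit peak.
#'
#' @param spec an [hrf_spec()].
#' @param dt sampling step in seconds (> 0).
#' @return numeric vector sampled at `t = 0, dt, 2 dt, ..., length`.
#' @export
hrf_kernel <- function(spec = hrf_spec(), dt) {
  stopifnot(inherits(spec, "hrf_spec"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  t <- seq(0, spec$length, by = dt)
  h <- dgamma(t, shape = spec$peak_delay / spec$peak_disp, scale = spec$peak_disp) -
    dgamma(t, shape = spec$under_delay / spec$under_disp, scale = spec$under_disp) / spec$ratio
  if (sum(h) * dt <= 0) stop("HRF kernel must integrate to a positive value")
  h / max(h)
}

# Per-event HRF responses sampled at scan times.  Every event of duration L
# produces the same unit boxcar-times-kernel response, shifted to its onset,
# so one convolution per distinct duration suffices; column i of the result
# is event i's sampled response.  All regressors are linear combinations of
# these columns.
event_response_matrix <- function(onsets, durations, n_scans, tr, dt,
                                  kernel) {
  t_scan <- (seq_len(n_scans) - 1L) * tr
  S <- matrix(0, n_scans, length(onsets))
  for (L in unique(durations)) {
    n_box <- max(1L, ceiling(L / dt - 1e-9))
    x <- c(rep(1, n_box), numeric(length(kernel)))
    unit <- convolve(x, rev(kernel), type = "open")[seq_along(x)] * dt
    for (i in which(durations == L)) {
      idx <- round((t_scan - onsets[i]) / dt) + 1L
      ok <- idx >= 1L & idx <= length(unit)
      S[ok, i] <- unit[idx[ok]]
    }
  }
  S
}

# Boxcar-on-fine-grid convolved with the HRF kernel and sampled at scans.
convolved_regressor <- function(onsets, durations, heights, n_scans, tr, dt,
                                kernel) {
  S <- event_response_matrix(onsets, durations, n_scans, tr, dt, kernel)
  as.numeric(S %*% heights)
}

#' Build an HRF-convolved design matrix with latent parametric regressors
#'
#' Columns are, in order: the constant `bias` regressor (unit-height stick
#' at every face onset, train and test), `d` parametric columns (stick
#' heights equal to each stimulus's latent components), then nuisance
#' columns (one-back repeats, imagery blocks, an intercept, and any
#' user-supplied nuisance matrix).  Everything is built on a fine grid
#' (`dt = tr/16` by default), convolved, then sampled at scan times.
#'
#' @param events an `event_table`.
#' @param latents numeric matrix of latent vectors with rownames = stim_id.
#'   Required whenever the events contain `train_face`/`test_face` rows;
#'   pass `NULL` for a latent-free (baseline) design.
#' @param n_scans number of volumes; events must fit within `n_scans * tr`.
#' @param tr repetition time in seconds.
#' @param hrf an [hrf_spec()].
#' @param nuisance optional numeric matrix (`n_scans` rows) of additional
#'   nuisance regressors (e.g. motion), entered as given.
#' @param dt fine-grid resolution in seconds (must be `<= tr/16`).
#' @param mean_center mean-center the latent stick heights per column before
#'   convolution?  Off by default: latent coordinates are already
#'   approximately centred.
#' @param orthogonalize orthogonalise each parametric column against the
#'   bias column after sampling?  Off by default.
#' @param bias_types face trial types entering the bias regressor.
#' @param parametric_types face trial types entering the parametric latent
#'   columns (must be a subset of `bias_types`).  Face rows of types in
#'   neither set are modeled by one categorical nuisance column per
#'   distinct stimulus, so their evoked responses stay out of the encoding
#'   fit without contaminating the residuals.
#' @return object of class `design_matrix`: list with `X`
#'   (n_scans x n_regressors), `names`, `role` (`bias`/`latent`/`nuisance`
#'   per column), `tr`, `dt`, `rank`, `full_rank`.
#' @export
build_design <- function(events, latents = NULL, n_scans, tr,
                         hrf = hrf_spec(), nuisance = NULL, dt = tr / 16,
                         mean_center = FALSE, orthogonalize = FALSE,
                         bias_types = c("train_face", "test_face"),
                         parametric_types = bias_types) {
  events <- validate_events(events)
  n_scans <- assert_scalar_count(n_scans, "n_scans")
  if (dt > tr / 16 + 1e-12) stop("dt must be at most tr/16")
  if (nrow(events) && max(events$onset + events$duration) > n_scans * tr)
    stop("events extend beyond the run (n_scans * tr)")
  if (!all(parametric_types %in% bias_types))
    stop("parametric_types must be a subset of bias_types")
  kernel <- hrf_kernel(hrf, dt)

  face <- events$trial_type %in% bias_types
  par <- events$trial_type %in% parametric_types
  cols <- list()
  role <- character(0)

  mk <- function(sub, heights) {
    convolved_regressor(events$onset[sub], events$duration[sub],
                        heights, n_scans, tr, dt, kernel)
  }

  cols$bias <- if (any(face)) mk(face, rep(1, sum(face))) else numeric(n_scans)
  role <- "bias"

  d <- 0L
  if (any(par)) {
    if (is.null(latents))
      stop("events contain parametric face rows but no latent table was given")
    ids <- events$stim_id[par]
    missing <- setdiff(ids, rownames(latents))
    if (length(missing))
      stop("latent vector missing for stimulus id(s): ",
           paste(head(missing, 5), collapse = ", "))
    Z <- latents[ids, , drop = FALSE]
    if (mean_center) Z <- sweep(Z, 2, colMeans(Z))
    d <- ncol(Z)
    S_par <- event_response_matrix(events$onset[par], events$duration[par],
                                   n_scans, tr, dt, kernel)
    Zcols <- S_par %*% Z
    for (j in seq_len(d)) {
      cols[[paste0("z", j)]] <- Zcols[, j]
      role <- c(role, "latent")
    }
  }

  # face rows excluded from the encoding model: one categorical column per
  # distinct stimulus (captures each stimulus's full evoked response)
  other <- events$trial_type %in% c("train_face", "test_face") & !face & !par
  if (any(other)) {
    for (id in unique(events$stim_id[other])) {
      sub <- other & events$stim_id == id
      cols[[paste0("stim_", id)]] <- mk(sub, rep(1, sum(sub)))
      role <- c(role, "nuisance")
    }
  }

  for (type in c("one_back", "imagery")) {
    sub <- events$trial_type == type
    if (any(sub)) {
      cols[[type]] <- mk(sub, rep(1, sum(sub)))
      role <- c(role, "nuisance")
    }
  }
  cols$intercept <- rep(1, n_scans)
  role <- c(role, "nuisance")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance matrix must have n_scans rows")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    role <- c(role, rep("nuisance", ncol(nuisance)))
  }

  if (orthogonalize && d > 0) {
    b <- X[, 1]
    bb <- sum(b^2)
    if (bb > 0) {
      for (j in which(role == "latent"))
        X[, j] <- X[, j] - b * sum(b * X[, j]) / bb
    }
  }

  rank <- qr(X)$rank
  structure(list(X = X, names = colnames(X), role = role, tr = tr, dt = dt,
                 d = d, rank = rank, full_rank = rank == ncol(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d scans x %d regressors (TR %.3g s, %d latent dims)\n",
              nrow(x$X), ncol(x$X), x$tr, x$d))
  cat(sprintf("rank %d/%d (%sfull rank)\n", x$rank, ncol(x$X),
              if (x$full_rank) "" else "NOT "))
  invisible(x)
}
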