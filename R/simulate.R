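#' @section Forward BOLD simulation:
#' The simulator supplies the test bed that scanner data would otherwise
#' provide.  A ground-truth brain holds a known weight matrix `W_true`
#' ((d+1) x n_voxels) mapping latent-plus-bias regressors to voxel
#' responses, voxel coordinates arranged in three equal-sized blocks
#' (occipital / temporal / frontoparietal) along the posterior-anterior and
#' second anatomical axes, and per-region signal scales.  A run is simulated
#' as `Y = X W_true + drift + AR(1) noise`, with `X` the HRF-convolved
#' design of the run's event schedule.
#' @name bold_sim
NULL

.REGIONS <- c("occipital", "temporal", "frontoparietal")

#' Noise specification for simulated runs
#'
#' @param sd stationary standard deviation of the AR(1) Gaussian noise.
#' @param ar lag-1 autocorrelation coefficient (|ar| < 1).
#' @param drift_amplitude amplitude of the sinusoidal low-frequency drift.
#' @param drift_period drift period in seconds.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 4, ar = 0.3, drift_amplitude = 0.5,
                       drift_period = 128) {
  if (sd < 0 || abs(ar) >= 1 || drift_amplitude < 0 || drift_period <= 0)
    stop("invalid noise specification")
  structure(list(sd = sd, ar = ar, drift_amplitude = drift_amplitude,
                 drift_period = drift_period), class = "noise_spec")
}

#' Create a ground-truth brain for forward simulation
#'
#' Voxels are split into three equal regions.  Coordinates use axis 1 as
#' posterior-to-anterior: occipital voxels occupy the most posterior block
#' (axis1 in \[0,1\]); the remaining voxels sit anterior (axis1 in \[1,3\])
#' and are separated along axis 2, temporal below 1 and frontoparietal
#' above, so that [split_regions()] recovers the generative labels exactly.
#' Latent rows of `W_true` are i.i.d. standard normal on a sparse (10% by
#' default) per-column support; the bias row is dense and positive
#' (half-normal), so every in-scale voxel shows a face-evoked response
#' while feature tuning is sparse.  Each column is multiplied by its
#' region's scale.
#'
#' @param n_voxels total voxel count, divisible by 3.
#' @param d latent dimension (rows of `W_true` are `d + 1`; row 1 is bias).
#' @param region_scales numeric length-3 signal scale for
#'   (occipital, temporal, frontoparietal); default `c(1, 0.5, 0.05)`.
#' @param seed RNG seed.
#' @param density fraction of nonzero entries per `W_true` column.
#' @param noise a [noise_spec()] used by default in [simulate_run()].
#' @return object of class `ground_truth_brain`.
#' @export
make_brain <- function(n_voxels, d, region_scales = c(1, 0.5, 0.05), seed,
                       density = 0.1, noise = noise_spec()) {
  n_voxels <- assert_scalar_count(n_voxels, "n_voxels", min = 3)
  d <- assert_scalar_count(d, "d")
  if (n_voxels %% 3 != 0) stop("n_voxels must be divisible by 3 (equal regions)")
  if (length(region_scales) != 3 || any(region_scales < 0))
    stop("region_scales must be 3 non-negative numbers")
  set.seed(seed)
  m <- n_voxels / 3
  region <- factor(rep(.REGIONS, each = m), levels = .REGIONS)
  coords <- cbind(
    a1 = c(runif(m, 0, 1), runif(2 * m, 1, 3)),
    a2 = c(runif(m, 0, 2), runif(m, 0, 1), runif(m, 1, 2)),
    a3 = runif(n_voxels, 0, 1))
  nr <- d + 1L
  # sparse-ish latent tuning; the floor of 3 tuned dimensions per voxel
  # keeps W W' well-conditioned when d is small
  nnz <- min(d, max(3L, round(density * d)))
  W <- matrix(0, nr, n_voxels)
  for (v in seq_len(n_voxels)) {
    rows <- 1L + sample.int(d, nnz)
    W[rows, v] <- rnorm(nnz)
  }
  # every in-scale voxel carries a positive face-evoked mean response (the
  # bias row is dense and positive); latent tuning stays sparse and signed
  W[1, ] <- abs(rnorm(n_voxels))
  W <- sweep(W, 2, region_scales[as.integer(region)], `*`)
  structure(list(W_true = W, coords = coords, region = region,
                 region_scales = region_scales, noise = noise, d = d,
                 seed = seed, fingerprint = sum(W) + sum(coords)),
            class = "ground_truth_brain")
}

#' @export
print.ground_truth_brain <- function(x, ...) {
  cat(sprintf("ground_truth_brain: %d voxels, d = %d, scales (%s), seed %s\n",
              ncol(x$W_true), x$d,
              paste(x$region_scales, collapse = ", "), x$seed))
  invisible(x)
}

#' Forward-simulate a voxel time-series run
#'
#' `Y = X W_true + drift + AR(1) Gaussian noise`, where `X` is the
#' bias-plus-latent part of the run's HRF-convolved design.  With noise SD
#' and drift amplitude zero the product is reproduced exactly.
#'
#' @param brain a [make_brain()] object.
#' @param events the run's `event_table`.
#' @param latents latent matrix (rownames = stim_id) with `d` columns.
#' @param n_scans,tr run length in volumes and repetition time (seconds).
#' @param hrf an [hrf_spec()].
#' @param seed RNG seed for the noise.
#' @param noise override of the brain's [noise_spec()].
#' @param imagery_latent optional latent vector of the imagined face.  When
#'   given and the events contain imagery blocks, a latent-weighted
#'   response (`gain * [1, z] W_true`) is added during those blocks, but
#'   only in `imagery_regions` -- emulating the top-down reinstatement that
#'   makes imagery decodable from higher-order regions only.
#' @param imagery_gain amplitude of the imagery signal relative to
#'   perception (default 0.5).
#' @param imagery_regions regions carrying the imagery signal.
#' @return object of class `simulated_run`: list with `Y`
#'   (n_scans x n_voxels), `events`, `design`, `tr`, `seed`,
#'   `brain_fingerprint`.
#' @export
simulate_run <- function(brain, events, latents, n_scans, tr,
                         hrf = hrf_spec(), seed, noise = brain$noise,
                         imagery_latent = NULL, imagery_gain = 0.5,
                         imagery_regions = "temporal") {
  stopifnot(inherits(brain, "ground_truth_brain"))
  design <- build_design(events, latents, n_scans, tr, hrf = hrf)
  if (design$d != brain$d && design$d != 0L)
    stop(sprintf("latent dimension mismatch: design has %d, brain expects %d",
                 design$d, brain$d))
  Xs <- design$X[, design$role %in% c("bias", "latent"), drop = FALSE]
  W_used <- if (design$d == 0L) brain$W_true[1, , drop = FALSE] else brain$W_true
  Y <- Xs %*% W_used
  if (!is.null(imagery_latent) && "imagery" %in% design$names) {
    if (length(imagery_latent) != brain$d)
      stop("imagery_latent must have the brain's latent dimension")
    vox <- brain$region %in% imagery_regions
    Y[, vox] <- Y[, vox] + imagery_gain *
      design$X[, "imagery", drop = FALSE] %*%
      (matrix(c(1, imagery_latent), 1) %*% brain$W_true[, vox, drop = FALSE])
  }
  set.seed(seed)
  n_vox <- ncol(brain$W_true)
  if (noise$drift_amplitude > 0) {
    t <- (seq_len(n_scans) - 1) * tr
    phase <- runif(n_vox, 0, 2 * pi)
    Y <- Y + noise$drift_amplitude *
      sin(outer(t, phase, function(ti, ph) 2 * pi * ti / noise$drift_period + ph))
  }
  if (noise$sd > 0) {
    innov_sd <- noise$sd * sqrt(1 - noise$ar^2)
    E <- matrix(rnorm(n_scans * n_vox, sd = innov_sd), n_scans, n_vox)
    if (noise$ar != 0)
      E <- apply(E, 2, function(e) as.numeric(stats::filter(e, noise$ar, method = "recursive")))
    Y <- Y + E
  }
  structure(list(Y = Y, events = validate_events(events),
                 design = design, tr = tr, seed = seed,
                 brain_fingerprint = brain$fingerprint),
            class = "simulated_run")
}

#' Generate a rapid event-related stimulus schedule
#'
#' Emulates the scanning design the decoder is meant for: runs of 1 s face
#' stimuli at a 3 s inter-trial interval, test faces randomly interleaved
#' among training faces, 1-back repeat trials (nuisance), 30 null fixation
#' trials per run, 6 s blanks at run boundaries, and optionally a unique
#' 12 s imagery trial at the start of odd runs and the end of even runs
#' (each followed by a 6 s blank).
#'
#' @param n_train number of distinct training faces (one presentation each).
#' @param n_test number of distinct test faces.
#' @param reps_per_test presentations of each test face (interleaved).
#' @param imagery include one 12 s imagery trial per run?
#' @param seed RNG seed.
#' @param faces_per_run face presentations per run (default 88).
#' @param oneback_per_run 1-back repeat trials per run (default 8).
#' @param fixation_per_run null fixation trials per run (default 30).
#' @param iti inter-trial interval in seconds (default 3: 1 s stimulus +
#'   2 s gap).
#' @param stim_duration face stimulus duration in seconds.
#' @return object of class `schedule`: list with `runs` (list of
#'   `event_table`), `run_duration` (seconds, one per run), `train_ids`,
#'   `test_ids`, `imagery_id` (or `NULL`), `seed`.
#' @export
make_schedule <- function(n_train, n_test, reps_per_test, imagery = FALSE,
                          seed, faces_per_run = 88, oneback_per_run = 8,
                          fixation_per_run = 30, iti = 3, stim_duration = 1) {
  if (n_train < 0 || n_test < 0 || reps_per_test < 0)
    stop("counts must be non-negative")
  if (n_test > 0 && reps_per_test == 0)
    stop("test faces requested with zero repetitions")
  set.seed(seed)
  train_ids <- if (n_train > 0) sprintf("train%05d", seq_len(n_train)) else character(0)
  test_ids <- if (n_test > 0) sprintf("test%03d", seq_len(n_test)) else character(0)
  pres <- c(train_ids, rep(test_ids, each = reps_per_test))
  if (!length(pres)) stop("schedule would contain no face presentations")
  pres <- sample(pres)                      # global random interleaving
  n_runs <- ceiling(length(pres) / faces_per_run)
  runs <- vector("list", n_runs)
  run_duration <- numeric(n_runs)
  imagery_id <- if (imagery) "imagined01" else NULL
  for (r in seq_len(n_runs)) {
    ids <- pres[((r - 1) * faces_per_run + 1):min(r * faces_per_run, length(pres))]
    type <- ifelse(ids %in% test_ids, "test_face", "train_face")
    trials <- data.frame(trial_type = type, stim_id = ids,
                         stringsAsFactors = FALSE)
    # null fixation trials interleaved anywhere
    nfix <- fixation_per_run
    if (nfix > 0) {
      fix <- data.frame(trial_type = "fixation", stim_id = NA_character_)
      trials <- rbind(trials, fix[rep(1, nfix), ])
      trials <- trials[sample.int(nrow(trials)), ]
    }
    # 1-back repeats: duplicate a face trial immediately after itself
    nob <- min(oneback_per_run, sum(trials$trial_type != "fixation"))
    if (nob > 0) {
      face_pos <- which(trials$trial_type %in% c("train_face", "test_face"))
      at <- sort(sample(face_pos, nob))
      for (k in rev(seq_along(at))) {
        i <- at[k]
        rep_row <- data.frame(trial_type = "one_back",
                              stim_id = trials$stim_id[i],
                              stringsAsFactors = FALSE)
        trials <- rbind(trials[seq_len(i), ], rep_row,
                        trials[setdiff(seq_len(nrow(trials)), seq_len(i)), ])
      }
    }
    n_tr <- nrow(trials)
    t0 <- 6
    img_row <- NULL
    if (imagery && r %% 2 == 1) {           # odd run: imagery first
      img_row <- data.frame(onset = 6, duration = 12, trial_type = "imagery",
                            stim_id = imagery_id, stringsAsFactors = FALSE)
      t0 <- 6 + 12 + 6
    }
    ev <- data.frame(onset = t0 + iti * (seq_len(n_tr) - 1),
                     duration = ifelse(trials$trial_type == "imagery", 12,
                                       stim_duration),
                     trial_type = trials$trial_type, stim_id = trials$stim_id,
                     stringsAsFactors = FALSE)
    t_end <- max(ev$onset) + iti
    if (imagery && r %% 2 == 0) {           # even run: imagery last
      img_row <- data.frame(onset = t_end, duration = 12,
                            trial_type = "imagery", stim_id = imagery_id,
                            stringsAsFactors = FALSE)
      t_end <- t_end + 12 + 6
    }
    if (!is.null(img_row)) ev <- rbind(img_row, ev)
    runs[[r]] <- validate_events(ev)
    run_duration[r] <- t_end + 6            # closing blank
  }
  structure(list(runs = runs, run_duration = run_duration,
                 train_ids = train_ids, test_ids = test_ids,
                 imagery_id = imagery_id, seed = seed),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  n_ev <- vapply(x$runs, nrow, integer(1))
  cat(sprintf("schedule: %d run(s), %d events total (%d train, %d test faces%s), seed %s\n",
              length(x$runs), sum(n_ev), length(x$train_ids),
              length(x$test_ids),
              if (!is.null(x$imagery_id)) ", imagery" else "", x$seed))
  invisible(x)
}

#' Concatenate the runs of a schedule into one event table
#'
#' Onsets are shifted so runs follow each other back to back, each run's
#' duration padded to a whole number of scans.
#'
#' @param schedule a [make_schedule()] object.
#' @param tr repetition time in seconds.
#' @return list with `events` (single `event_table`), `n_scans` (total),
#'   and `run_scans` (per run).
#' @export
concat_schedule <- function(schedule, tr) {
  stopifnot(inherits(schedule, "schedule"))
  run_scans <- ceiling(schedule$run_duration / tr)
  offsets <- c(0, cumsum(run_scans[-length(run_scans)])) * tr
  evs <- mapply(function(ev, off) {
    ev$onset <- ev$onset + off
    ev
  }, schedule$runs, offsets, SIMPLIFY = FALSE)
  ev <- do.call(rbind, evs)
  list(events = validate_events(ev), n_scans = sum(run_scans),
       run_scans = run_scans)
}
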