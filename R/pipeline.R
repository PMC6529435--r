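#' @section The pipeline:
#' [run_pipeline()] wires every stage together on simulated data: sample
#' faces, fit the PCA latent space, encode stimuli, build a ground-truth
#' brain whose voxels are tuned to those latents, schedule and simulate
#' runs, fit the weight matrix on training trials, select voxels, estimate
#' test patterns, decode, and score recognition, gender classification and
#' (optionally) imagery decoding, per region.  Every random stage draws a
#' named sub-seed derived from the single config seed, so a rerun with the
#' same config reproduces all outputs.
#' @name pipeline
NULL

.CONFIG_DEFAULTS <- function() list(
  seed = 1L,
  d = 32L,
  image_size = 64L,
  n_voxels = 3000L,
  n_train = 500L,
  n_test = 10L,
  reps_per_test = 15L,
  tr = 2,
  imagery = FALSE,
  imagery_gain = 0.5,
  region_scales = c(1, 0.5, 0.05),
  density = 0.1,
  noise = list(sd = 20, ar = 0.3, drift_amplitude = 0.5, drift_period = 128),
  selection = list(type = "top_fraction", fraction = 0.3, t_min = 0,
                   dr2_min = 0),
  pattern_method = "glm",
  evaluation = list(n_draws = 10000L)
)

#' Build a validated pipeline configuration
#'
#' Unknown keys (including nested ones) are rejected; omitted keys take
#' the documented defaults.
#'
#' @param ... configuration entries overriding the defaults: `seed`, `d`,
#'   `image_size`, `n_voxels`, `n_train`, `n_test`, `reps_per_test`, `tr`,
#'   `imagery`, `imagery_gain`, `region_scales`, `density`, `noise`
#'   (`sd`, `ar`, `drift_amplitude`, `drift_period`), `selection`
#'   (`type`, `fraction`, `t_min`, `dr2_min`), `pattern_method`,
#'   `evaluation` (`n_draws`).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- .CONFIG_DEFAULTS()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      sub <- user[[nm]]
      bad <- setdiff(names(sub), names(defaults[[nm]]))
      if (length(bad))
        stop(sprintf("unknown config key(s) under '%s': %s", nm,
                     paste(bad, collapse = ", ")))
      cfg[[nm]][names(sub)] <- sub
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_config` returns a validated `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# deterministic per-stage sub-seeds from the one config seed
stage_seed <- function(seed, stage) {
  offsets <- c(faces = 11L, brain = 23L, schedule = 37L, run = 53L,
               evaluation = 71L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Run the full simulate-fit-decode-evaluate pipeline
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, events, latents,
#'   selection, metrics and a manifest are written there.
#' @param verbose print stage progress?
#' @return list of class `pipeline_result`: `config`, `pca`, `brain`,
#'   `schedule`, `weights` (fitted, full brain), `stats`, `selection`,
#'   `partition`, `decoded` (test latents over the selection),
#'   `recognition`, `region_recognition` (per region), `gender` (axis,
#'   ceiling and decoded accuracy, sensitivity map), `imagery` (when
#'   enabled), and a tidy `metrics` data frame.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- Sys.time()

  # --- stimuli and latent space ------------------------------------------
  n_faces <- config$n_train + config$n_test + as.integer(config$imagery)
  say("sampling %d faces", n_faces)
  faces <- sample_faces(n_faces, seed = stage_seed(config$seed, "faces"),
                        size = config$image_size)
  train_idx <- seq_len(config$n_train)
  test_idx <- config$n_train + seq_len(config$n_test)
  ids <- c(sprintf("train%05d", seq_len(config$n_train)),
           sprintf("test%03d", seq_len(config$n_test)),
           if (config$imagery) "imagined01")
  say("fitting PCA latent space (d = %d)", config$d)
  pca <- fit_pca(faces$images[train_idx], d = config$d)
  latents <- encode_all(pca, faces$images)
  rownames(latents) <- ids

  # --- brain, schedule, simulation ---------------------------------------
  noise <- do.call(noise_spec, config$noise)
  brain <- make_brain(config$n_voxels, config$d,
                      region_scales = config$region_scales,
                      seed = stage_seed(config$seed, "brain"),
                      density = config$density, noise = noise)
  sched <- make_schedule(config$n_train, config$n_test,
                         config$reps_per_test, imagery = config$imagery,
                         seed = stage_seed(config$seed, "schedule"))
  cat_run <- concat_schedule(sched, config$tr)
  say("simulating %d scans x %d voxels", cat_run$n_scans, config$n_voxels)
  sim <- simulate_run(brain, cat_run$events, latents, cat_run$n_scans,
                      config$tr, seed = stage_seed(config$seed, "run"),
                      imagery_latent = if (config$imagery) latents["imagined01", ],
                      imagery_gain = config$imagery_gain)

  # --- encoding fit and voxel selection (training trials only) ------------
  say("fitting weight matrix")
  design_train <- build_design(cat_run$events, latents, cat_run$n_scans,
                               config$tr, bias_types = "train_face",
                               parametric_types = "train_face")
  weights <- fit_weights(design_train, sim$Y)
  design_base <- build_design(cat_run$events, latents = NULL,
                              cat_run$n_scans, config$tr,
                              bias_types = "train_face",
                              parametric_types = character(0))
  stats <- compute_voxel_stats(design_train, design_base, sim$Y,
                               coords = brain$coords)
  policy <- do.call(selection_policy, config$selection)
  selection <- select_voxels(stats, policy)
  partition <- split_regions(selection, brain$coords)
  say("selected %d voxels", length(selection))

  # --- test patterns, decoding, recognition ------------------------------
  train_cols <- design_train$X[, !grepl("^stim_", colnames(design_train$X)),
                               drop = FALSE]
  train_cols <- train_cols[, colnames(train_cols) != "intercept", drop = FALSE]
  patterns <- estimate_test_patterns(cat_run$events, sim$Y, config$tr,
                                     condition = "test_face",
                                     method = config$pattern_method,
                                     nuisance = if (config$pattern_method == "glm") train_cols)
  test_ids <- rownames(patterns$patterns)
  truths <- latents[test_ids, , drop = FALSE]
  eval_seed <- stage_seed(config$seed, "evaluation")
  decode_region <- function(vox) {
    dec <- decode_latent(subset_weights(weights, vox),
                         patterns$patterns[, vox, drop = FALSE])
    rownames(dec$Z) <- test_ids
    dec
  }
  decoded <- decode_region(selection)
  recog <- recognition(decoded$Z, truths,
                       n_draws = config$evaluation$n_draws, seed = eval_seed)
  region_recog <- lapply(partition[.REGIONS], function(vox)
    recognition(decode_region(vox)$Z, truths,
                n_draws = config$evaluation$n_draws, seed = eval_seed))

  # --- gender decoding ----------------------------------------------------
  male <- faces$labels$male[train_idx]
  gender_axis <- compute_axis(latents[train_idx, , drop = FALSE][male, , drop = FALSE],
                              latents[train_idx, , drop = FALSE][!male, , drop = FALSE],
                              name = "male")
  truth_male <- faces$labels$male[test_idx][match(test_ids,
                  sprintf("test%03d", seq_len(config$n_test)))]
  ceiling_acc <- mean(classify(gender_axis, truths) == truth_male)
  decoded_acc <- mean(classify(gender_axis, decoded$Z) == truth_male)
  gender <- list(axis = gender_axis, ceiling = ceiling_acc,
                 decoded = decoded_acc,
                 p = pbinom(round(decoded_acc * config$n_test) - 1,
                            config$n_test, 0.5, lower.tail = FALSE),
                 sensitivity = sensitivity_map(subset_weights(weights, selection),
                                               gender_axis))

  # --- imagery decoding ---------------------------------------------------
  imagery <- NULL
  if (config$imagery) {
    img_pat <- estimate_test_patterns(cat_run$events, sim$Y, config$tr,
                                      condition = "imagery",
                                      method = "average")
    cands <- latents[c("imagined01", test_ids), , drop = FALSE]
    imagery <- lapply(c(list(full = selection), partition[.REGIONS]),
                      function(vox) {
      dec <- decode_latent(subset_weights(weights, vox),
                           img_pat$patterns[, vox, drop = FALSE])
      r <- cor(as.numeric(dec$Z[1, ]), t(cands))
      rank <- 1 + sum(r[-1] >= r[1])
      list(rank = rank,
           pairwise = rank_accuracy(rank, nrow(cands), "pairwise"))
    })
  }

  metrics <- data.frame(
    region = c("full", .REGIONS),
    pairwise = c(recog$pairwise_accuracy,
                 vapply(region_recog, `[[`, numeric(1), "pairwise_accuracy")),
    full_recognition = c(recog$full_accuracy,
                         vapply(region_recog, `[[`, numeric(1), "full_accuracy")),
    p_pairwise = c(recog$p_pairwise,
                   vapply(region_recog, `[[`, numeric(1), "p_pairwise")))

  result <- structure(list(config = config, pca = pca, brain = brain,
                           schedule = sched, weights = weights,
                           stats = stats, selection = selection,
                           partition = partition, patterns = patterns,
                           decoded = decoded, truths = truths,
                           recognition = recog,
                           region_recognition = region_recog,
                           gender = gender, imagery = imagery,
                           metrics = metrics,
                           elapsed = as.numeric(difftime(Sys.time(), tic,
                                                         units = "secs"))),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(result, cat_run, latents, out_dir)
  result
}

write_pipeline <- function(result, cat_run, latents, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(result$config, file.path(out_dir, "config.yaml"))
  write_events(cat_run$events, file.path(out_dir, "events.tsv"))
  write_latents(latents, file.path(out_dir, "latents.tsv"))
  writeLines(as.character(result$selection),
             file.path(out_dir, "selection_index.txt"))
  write.table(result$metrics, file.path(out_dir, "metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("facedec")),
    seed = result$config$seed,
    n_voxels_total = result$config$n_voxels,
    n_voxels_selected = length(result$selection),
    pairwise_accuracy = result$recognition$pairwise_accuracy,
    full_accuracy = result$recognition$full_accuracy,
    gender_decoded = result$gender$decoded,
    gender_ceiling = result$gender$ceiling)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (seed %d, d = %d, %d voxels, %.1f s)\n",
              x$config$seed, x$config$d, x$config$n_voxels, x$elapsed))
  cat(sprintf("selection: %d voxels\n", length(x$selection)))
  print(x$metrics, row.names = FALSE)
  cat(sprintf("gender: decoded %.1f%% (ceiling %.1f%%)\n",
              100 * x$gender$decoded, 100 * x$gender$ceiling))
  if (!is.null(x$imagery))
    cat(sprintf("imagery pairwise: %s\n",
                paste(sprintf("%s %.2f", names(x$imagery),
                              vapply(x$imagery, `[[`, numeric(1), "pairwise")),
                      collapse = ", ")))
  invisible(x)
}
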