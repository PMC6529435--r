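# Shared fixtures, all generated in code.

# latent matrix with stimulus-id rownames
rand_latents <- function(ids, d, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(length(ids) * d, sd = sd), length(ids), d,
         dimnames = list(ids, NULL))
}

# small end-to-end simulation: schedule + unit-scale latents + one run
quick_sim <- function(seed, d = 6, n_voxels = 90, n_train = 70, n_test = 8,
                      reps = 4, tr = 2, region_scales = c(1, 0.5, 0.05),
                      noise = noise_spec(), imagery = FALSE, ...) {
  brain <- make_brain(n_voxels, d, region_scales = region_scales,
                      seed = seed, noise = noise)
  sched <- make_schedule(n_train, n_test, reps, imagery = imagery,
                         seed = seed + 1000L)
  cr <- concat_schedule(sched, tr)
  ids <- rownames_for_schedule(sched)
  Z <- rand_latents(ids, d, seed = seed + 2000L)
  sim <- simulate_run(brain, cr$events, Z, cr$n_scans, tr,
                      seed = seed + 3000L, ...)
  list(brain = brain, sched = sched, cr = cr, Z = Z, sim = sim, tr = tr,
       d = d)
}

rownames_for_schedule <- function(sched) {
  c(sched$train_ids, sched$test_ids, sched$imagery_id)
}

# fit weights on training trials only (test faces as per-stimulus nuisance)
fit_training_weights <- function(qs) {
  dtr <- build_design(qs$cr$events, qs$Z, qs$cr$n_scans, qs$tr,
                      bias_types = "train_face",
                      parametric_types = "train_face")
  fit_weights(dtr, qs$sim$Y)
}

# decode the test faces of a quick_sim over a voxel subset
decode_test_faces <- function(qs, wm, voxels = seq_len(ncol(wm$W))) {
  pat <- estimate_test_patterns(qs$cr$events, qs$sim$Y, qs$tr)
  dec <- decode_latent(subset_weights(wm, voxels),
                       pat$patterns[, voxels, drop = FALSE])
  list(Z = dec$Z, truths = qs$Z[rownames(pat$patterns), , drop = FALSE])
}

# hand-rolled design_matrix wrapper for raw X matrices
raw_design <- function(X, role, tr = 2) {
  structure(list(X = X, names = colnames(X), role = role, tr = tr,
                 dt = tr / 16, d = sum(role == "latent"),
                 rank = qr(X)$rank, full_rank = qr(X)$rank == ncol(X)),
            class = "design_matrix")
}
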