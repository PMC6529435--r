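#' @section File formats:
#' Event schedules travel as BIDS-style tab-delimited files (`onset`,
#' `duration`, `trial_type`, optional `stim_id`); voxel time series as 4-D
#' NIfTI volumes or plain delimited matrices; latent vectors as
#' tab-delimited tables keyed by `stim_id` (columns `z0..z{d-1}`); run
#' configurations as a single YAML file with strict key checking.
#' @name io
NULL

#' Write / read a BIDS-style events file
#'
#' Tab-delimited with header `onset`, `duration`, `trial_type`, `stim_id`;
#' missing stimulus ids are written as `n/a`.  Reading validates and
#' stably sorts by onset (the original row order is kept in the `.index`
#' column).
#'
#' @param events an `event_table`.
#' @param path file path (conventionally `*_events.tsv`).
#' @return `read_events` returns an `event_table`.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- events[, c("onset", "duration", "trial_type", "stim_id")]
  out$stim_id[is.na(out$stim_id)] <- "n/a"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  for (col in c("onset", "duration")) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(vals) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at line %d ('%s')", path, col,
                   bad[1] + 1L, tab[[col]][bad[1]]))
    tab[[col]] <- vals
  }
  if (!"stim_id" %in% names(tab)) tab$stim_id <- NA_character_
  tab$stim_id[tab$stim_id %in% c("n/a", "NA", "")] <- NA_character_
  validate_events(tab[, c("onset", "duration", "trial_type", "stim_id")])
}

#' Write / read a latent-vector table
#'
#' One row per stimulus: `stim_id` then `z0..z{d-1}`, tab-delimited.
#'
#' @param latents numeric matrix with rownames = stimulus ids.
#' @param path file path.
#' @return `read_latents` returns the matrix (rownames = stim_id).
#' @export
write_latents <- function(latents, path) {
  latents <- as.matrix(latents)
  if (is.null(rownames(latents))) stop("latent matrix needs stim_id rownames")
  tab <- data.frame(stim_id = rownames(latents), latents, check.names = FALSE)
  colnames(tab) <- c("stim_id", paste0("z", seq_len(ncol(latents)) - 1L))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_latents
#' @export
read_latents <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"stim_id" %in% names(tab)) stop(path, ": missing stim_id column")
  Z <- as.matrix(tab[, grep("^z[0-9]+$", names(tab)), drop = FALSE])
  rownames(Z) <- tab$stim_id
  Z
}

#' Write a voxel time-series matrix as a 4-D NIfTI volume
#'
#' Voxels (columns of `Y`) are laid out on a 3-D grid in column-major
#' order; the grid shape defaults to a flat `n_voxels x 1 x 1` line when
#' not given.  The TR is stored in the time pixdim.
#'
#' @param Y numeric matrix, scans in rows, voxels in columns.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr repetition time in seconds.
#' @param grid_dim integer length-3 grid with `prod(grid_dim) == ncol(Y)`.
#' @return `read_bold` returns a list of class `voxel_dataset` with `Y`
#'   (scans x voxels), `coords` (0-based grid indices), `tr`, `grid_dim`.
#' @export
write_bold <- function(Y, path, tr, grid_dim = c(ncol(Y), 1L, 1L)) {
  Y <- as.matrix(Y)
  grid_dim <- as.integer(grid_dim)
  if (prod(grid_dim) != ncol(Y))
    stop("prod(grid_dim) must equal the number of voxels")
  arr <- array(t(Y), dim = c(grid_dim, nrow(Y)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @param mask optional logical/0-1 array (grid shape) or integer voxel
#'   indices restricting the columns returned.
#' @export
read_bold <- function(path, mask = NULL, tr = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    dims <- dim(img)
    if (length(dims) != 4) stop(path, ": expected a 4-D volume")
    hdr_tr <- RNifti::pixdim(img)[4]
    if (is.null(tr)) tr <- hdr_tr
    if (is.null(tr) || !is.finite(tr) || tr <= 0)
      stop("TR not present in the header; pass tr explicitly")
    n_vox <- prod(dims[1:3])
    Y <- t(matrix(img, n_vox, dims[4]))
    grid <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                                  j = seq_len(dims[2]) - 1L,
                                  k = seq_len(dims[3]) - 1L))
    grid_dim <- dims[1:3]
  } else {
    Y <- as.matrix(read.delim(path, header = FALSE))
    if (is.null(tr) || tr <= 0)
      stop("matrix files carry no TR; pass tr explicitly")
    grid <- as.matrix(expand.grid(i = seq_len(ncol(Y)) - 1L, j = 0L, k = 0L))
    grid_dim <- c(ncol(Y), 1L, 1L)
  }
  if (!is.null(mask)) {
    idx <- if (is.array(mask) || is.matrix(mask)) which(as.logical(mask)) else as.integer(mask)
    Y <- Y[, idx, drop = FALSE]
    grid <- grid[idx, , drop = FALSE]
  }
  structure(list(Y = Y, coords = grid, tr = as.numeric(tr),
                 grid_dim = grid_dim),
            class = "voxel_dataset")
}

#' Write a voxel selection as a NIfTI mask plus a plain index list
#'
#' @param selection integer voxel indices (into the grid's column-major
#'   order).
#' @param grid_dim integer length-3 grid shape.
#' @param path base path; writes `<path>.nii.gz` and `<path>_index.txt`.
#' @return invisibly, the two paths written.
#' @export
write_mask <- function(selection, grid_dim, path) {
  m <- array(0L, dim = as.integer(grid_dim))
  m[as.integer(selection)] <- 1L
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(m), nii)
  txt <- paste0(path, "_index.txt")
  writeLines(as.character(sort(as.integer(selection))), txt)
  invisible(c(nii, txt))
}
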