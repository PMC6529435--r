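#' @section Latent face spaces:
#' The decoder only needs an embedding: `encode()` maps an image to a latent
#' vector of length `d`, `decode()` maps a latent vector back to an image.
#' Any generative face model can plug into that seam; the implementation
#' shipped here is PCA on pixels, the fully linear baseline: latent
#' coordinates are projections onto the top-`d` eigenvectors of the pixel
#' covariance, and decoding is the inverse transform `mean + U z`.
#' @name latent_space
NULL

#' Fit a PCA latent face space on a set of images
#'
#' Computes the top-`d` principal components of the pixel covariance via a
#' singular-value decomposition of the centred data matrix (stable when
#' `n_pixels >> n_images`).  Component signs are fixed so the
#' largest-magnitude pixel loading of each component is positive, making the
#' model deterministic across platforms.
#'
#' @param images list of >= 2 numeric matrices with identical dimensions.
#' @param d number of components to retain; at most
#'   `min(n_images - 1, n_pixels)`.  Default: that maximum, capped at 1024.
#' @return object of class `pca_model` with fields `mean` (pixel vector),
#'   `U` (n_pixels x d orthonormal loadings), `variance` (per-component
#'   variance, non-increasing), `shape` (image dimensions), `d`, and
#'   `training` metadata (n_images and a data checksum).
#' @export
fit_pca <- function(images, d = NULL) {
  if (!is.list(images) || length(images) < 2)
    stop("need a list of at least 2 images")
  shape <- dim(images[[1]])
  if (any(!vapply(images, function(x) identical(dim(x), shape), logical(1))))
    stop("all images must share the same dimensions")
  X <- t(vapply(images, as.numeric, numeric(prod(shape))))  # n x p
  n <- nrow(X); p <- ncol(X)
  dmax <- min(n - 1L, p)
  if (is.null(d)) d <- min(1024L, dmax)
  d <- assert_scalar_count(d, "d")
  if (d > dmax)
    stop(sprintf("d = %d exceeds the achievable maximum %d (= min(n_images - 1, n_pixels))",
                 d, dmax))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0, nv = d)
  if (max(s$d) == 0)
    stop("all images are identical: pixel covariance is zero, PCA undefined")
  U <- s$v
  # deterministic sign: largest-|loading| pixel of each component positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  variance <- (s$d[seq_len(d)]^2) / (n - 1)
  structure(list(mean = mu, U = U, variance = variance, shape = shape,
                 d = d,
                 training = list(n_images = n, checksum = sum(X))),
            class = c("pca_model", "embedding_model"))
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components on %s images (fit on %d images)\n",
              x$d, paste(x$shape, collapse = "x"), x$training$n_images))
  cat(sprintf("variance retained: %.1f%% of training pixel variance\n",
              100 * sum(x$variance) / max(sum(x$variance), .Machine$double.eps)))
  invisible(x)
}

#' Encode an image into a latent vector
#'
#' @param model an embedding model (e.g. from [fit_pca()]).
#' @param image numeric matrix matching the model's image shape.
#' @param ... passed to methods.
#' @return numeric latent vector of length `model$d`.
#' @export
encode <- function(model, image, ...) UseMethod("encode")

#' @export
encode.pca_model <- function(model, image, ...) {
  if (!identical(dim(image), model$shape))
    stop(sprintf("image shape %s does not match model shape %s",
                 paste(dim(image), collapse = "x"),
                 paste(model$shape, collapse = "x")))
  as.numeric(crossprod(model$U, as.numeric(image) - model$mean))
}

#' Decode a latent vector into an image
#'
#' For PCA, `mean + U z`.  Raw values are returned (no clipping); clipping
#' to `[0, 1]` happens only when writing images to disk.
#'
#' @param model an embedding model.
#' @param z latent vector of length `model$d`.
#' @param ... passed to methods.
#' @return numeric matrix with the model's image shape.
#' @export
decode <- function(model, z, ...) UseMethod("decode")

#' @export
decode.pca_model <- function(model, z, ...) {
  if (length(z) != model$d)
    stop(sprintf("latent vector has length %d, model expects %d", length(z), model$d))
  matrix(model$mean + as.numeric(model$U %*% z), model$shape[1], model$shape[2])
}

#' Encode a list of images into a latent matrix
#'
#' @param model an embedding model.
#' @param images list of images.
#' @return matrix (n_images x d).
#' @export
encode_all <- function(model, images) {
  t(vapply(images, function(im) encode(model, im), numeric(model$d)))
}

#' Persist / restore a fitted latent model
#'
#' @param model a `pca_model`.
#' @param path file path for the model archive.
#' @return `read_pca_model` returns the model.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pca_model"))
  model
}
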