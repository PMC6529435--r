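#' @section Parametric faces:
#' The synthetic stimulus generator draws schematic grayscale faces from a
#' low-dimensional generative parameter vector, standing in for a labelled
#' photographic face database.  Each of the 12 parameters controls one
#' interpretable geometric or photometric axis, every parameter lives in
#' `[-1, 1]`, and binary attribute labels ("male", "smile", "long_hair")
#' are deterministic threshold functions of designated parameters, so the
#' ground-truth attribute direction in image (or latent) space is known.
#' @name faces
NULL

.FACE_K <- 12L

#' Names of the generative face parameters
#'
#' @return character vector of length 12, in the order expected by
#'   [render_face()].
#' @export
face_param_names <- function() {
  c("oval_width", "oval_height", "eye_spacing", "eye_size",
    "mouth_curve", "mouth_width", "brow_thickness", "jaw_width",
    "hair_extent", "nose_length", "skin_tone", "v_offset")
}

validate_face_params <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) != .FACE_K)
    stop(sprintf("face parameter vector must have length %d", .FACE_K))
  if (any(!is.finite(theta)))
    stop("face parameters must be finite")
  if (any(theta < -1 | theta > 1))
    stop("face parameters must lie in [-1, 1]")
  names(theta) <- face_param_names()
  theta
}

# Signed-coverage anti-aliasing: alpha in [0,1] from an approximate signed
# distance to the shape boundary, measured in canvas units; px is one pixel.
.aa <- function(dist, px) pmin(1, pmax(0, 0.5 + dist / px))

# Ellipse "inside" coverage on grids U, V (canvas coords in [-1,1]).
.ellipse_alpha <- function(U, V, cx, cy, rx, ry, px) {
  e <- sqrt(((U - cx) / rx)^2 + ((V - cy) / ry)^2)
  .aa((1 - e) * min(rx, ry), px)
}

.face_geometry <- function(theta) {
  th <- validate_face_params(theta)
  cy <- 0.10 * th["v_offset"]
  list(
    cy = cy,
    rx = 0.55 + 0.08 * th["oval_width"],
    ry = 0.72 + 0.12 * th["oval_height"],
    jaw = 0.45 * th["jaw_width"],
    hairline = cy - 0.45 + 0.18 * th["hair_extent"],
    eye_x = 0.22 + 0.08 * th["eye_spacing"],
    eye_y = cy - 0.12,
    eye_r = 0.055 + 0.025 * th["eye_size"],
    brow_half = 0.035 + 0.020 * th["brow_thickness"],
    nose_len = 0.18 + 0.06 * th["nose_length"],
    mouth_y = cy + 0.38,
    mouth_w = 0.16 + 0.06 * th["mouth_width"],
    mouth_amp = -0.12 * th["mouth_curve"],
    skin = 0.62 + 0.18 * th["skin_tone"]
  )
}

#' Render a schematic face image
#'
#' Deterministically rasterises a face from its generative parameter vector.
#' The same `(theta, size)` always yields a bit-identical image; all shapes
#' are anti-aliased so every parameter perturbation moves at least one pixel
#' value at the default 64 x 64 resolution.
#'
#' @param theta numeric vector of length 12 in `[-1, 1]`, ordered as
#'   [face_param_names()].
#' @param size image side in pixels (>= 32; default 64, 128 also supported).
#' @return `size` x `size` numeric matrix with values in `[0, 1]`
#'   (row = image row, top to bottom).
#' @export
render_face <- function(theta, size = 64L) {
  size <- assert_scalar_count(size, "size", min = 32)
  g <- .face_geometry(theta)
  px <- 2 / size
  ax <- (seq_len(size) - (size + 1) / 2) * px   # canvas coords in (-1, 1)
  U <- matrix(ax, size, size, byrow = TRUE)     # horizontal
  V <- matrix(ax, size, size, byrow = FALSE)    # vertical, down = positive

  img <- matrix(0.20, size, size)               # background

  # head: ellipse whose lower half widens/narrows with jaw width
  ramp <- pmin(1, pmax(0, (V - g$cy) / g$ry))
  rx_eff <- g$rx * (1 + g$jaw * ramp)
  e <- sqrt(((U) / rx_eff)^2 + ((V - g$cy) / g$ry)^2)
  head_a <- .aa((1 - e) * min(g$rx * (1 - abs(g$jaw)), g$ry), px)
  img <- img * (1 - head_a) + g$skin * head_a

  # hair: the part of a slightly enlarged head ellipse above the hairline
  eh <- sqrt((U / (rx_eff * 1.06))^2 + ((V - g$cy) / (g$ry * 1.06))^2)
  hair_a <- .aa((1 - eh) * min(g$rx, g$ry), px) * .aa(g$hairline - V, px)
  img <- img * (1 - hair_a) + 0.15 * hair_a

  # brows: horizontal bands above the eyes (painted over the hair)
  brow_y <- g$eye_y - 0.19
  for (s in c(-1, 1)) {
    band <- .aa(g$brow_half - abs(V - brow_y), px) *
      .aa(g$eye_r * 1.6 - abs(U - s * g$eye_x), px)
    img <- img * (1 - band) + 0.15 * band
  }

  # eyes
  for (s in c(-1, 1)) {
    a <- .ellipse_alpha(U, V, s * g$eye_x, g$eye_y, g$eye_r * 1.3,
                        g$eye_r * 0.8, px)
    img <- img * (1 - a) + 0.08 * a
  }

  # nose: a short vertical bar, slightly darker than skin
  nose_a <- .aa(0.02 - abs(U), px) *
    .aa(g$nose_len / 2 - abs(V - (g$eye_y + 0.05 + g$nose_len / 2)), px)
  img <- img * (1 - nose_a) + (g$skin - 0.15) * nose_a

  # mouth: a curved band; positive mouth_curve lifts the corners (smile)
  vc <- g$mouth_y + g$mouth_amp * ((U / g$mouth_w)^2 - 0.5)
  mouth_a <- .aa(0.025 - abs(V - vc), px) * .aa(g$mouth_w - abs(U), px)
  img <- img * (1 - mouth_a) + 0.20 * mouth_a

  img[] <- pmin(1, pmax(0, img))
  img
}

#' Pixel bounding box of the mouth region
#'
#' Conservative box containing every pixel the mouth band can touch for the
#' given parameter vector, whatever the mouth curvature/width components are.
#' Used to verify that mouth parameters act locally.
#'
#' @param theta face parameter vector (only `v_offset` affects the box).
#' @param size image side in pixels.
#' @return list with integer vectors `rows` and `cols`.
#' @export
mouth_box <- function(theta, size = 64L) {
  size <- assert_scalar_count(size, "size", min = 32)
  g <- .face_geometry(theta)
  px <- 2 / size
  to_idx <- function(x) pmin(size, pmax(1, round((x + 1) / px + 0.5)))
  pad <- 0.12 + 2 * px
  list(rows = to_idx(g$mouth_y - pad):to_idx(g$mouth_y + pad),
       cols = to_idx(-(0.23 + 2 * px)):to_idx(0.23 + 2 * px))
}

#' Attribute labels implied by a face parameter vector
#'
#' Labels are deterministic threshold rules on designated generative axes:
#' `male` is jaw width > 0, `smile` is mouth curvature > 0, `long_hair` is
#' hair extent > 0.
#'
#' @param theta face parameter vector.
#' @return named logical vector.
#' @export
face_labels <- function(theta) {
  th <- validate_face_params(theta)
  c(male = unname(th["jaw_width"] > 0),
    smile = unname(th["mouth_curve"] > 0),
    long_hair = unname(th["hair_extent"] > 0))
}

#' Sample a reproducible set of synthetic faces
#'
#' Draws generative parameters i.i.d. uniform on `[-1, 1]` (so each binary
#' attribute has prevalence 0.5), renders the images and computes labels.
#'
#' @param n number of faces (>= 1).
#' @param seed RNG seed; the same seed reproduces the sample exactly.
#' @param size image side in pixels.
#' @param render render images?  Set `FALSE` to sample only parameters and
#'   labels (e.g. for large prevalence checks).
#' @return object of class `face_sample`: list with `params` (n x 12 matrix),
#'   `labels` (data frame with `id` and one logical column per attribute),
#'   `images` (list of rasters, or `NULL`), `size`, `seed`.
#' @export
sample_faces <- function(n, seed, size = 64L, render = TRUE) {
  n <- assert_scalar_count(n, "n")
  withr_seed <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    old
  })
  on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, globalenv()))
  params <- matrix(runif(n * .FACE_K, -1, 1), nrow = n,
                   dimnames = list(NULL, face_param_names()))
  labels <- as.data.frame(t(apply(params, 1, face_labels)))
  labels <- cbind(id = sprintf("face%05d", seq_len(n)), labels)
  images <- if (render) lapply(seq_len(n), function(i) render_face(params[i, ], size)) else NULL
  structure(list(params = params, labels = labels, images = images,
                 size = size, seed = seed),
            class = "face_sample")
}

#' @export
print.face_sample <- function(x, ...) {
  cat(sprintf("face_sample: %d faces, %dx%d%s, seed %s\n",
              nrow(x$params), x$size, x$size,
              if (is.null(x$images)) " (not rendered)" else "", x$seed))
  prev <- colMeans(x$labels[-1])
  cat("attribute prevalence:",
      paste(sprintf("%s=%.2f", names(prev), prev), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a face image as PNG
#'
#' Values are clipped to `[0, 1]` at this I/O boundary only.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @return `read_face_png` returns the image matrix.
#' @export
write_face_png <- function(image, path) {
  image[] <- pmin(1, pmax(0, image))
  png::writePNG(image, target = path)
  invisible(path)
}

#' @rdname write_face_png
#' @export
read_face_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write / read the parameter + label table of a face sample
#'
#' One row per face: `id`, the 12 theta components, then the binary labels,
#' tab-delimited.
#'
#' @param sample a `face_sample`.
#' @param path file path.
#' @return `read_face_table` returns a data frame.
#' @export
write_face_table <- function(sample, path) {
  stopifnot(inherits(sample, "face_sample"))
  tab <- cbind(sample$labels["id"], as.data.frame(sample$params),
               sample$labels[-1])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_face_table
#' @export
read_face_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
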