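#' @section Attribute axes:
#' A binary facial attribute (gender, smile, ...) defines a direction in
#' latent space: the mean latent vector of faces carrying the label minus
#' the mean of faces without it.  Sign of the projection onto that axis
#' classifies any latent vector; correlating the axis with each column of
#' the trained weight matrix maps which voxels are sensitive to the
#' attribute (strongly positive and strongly negative correlations both
#' count -- they mark opposite preferences).
#' @name attributes
NULL

#' Compute an attribute axis from labelled latent vectors
#'
#' `axis = mean(positive latents) - mean(negative latents)`.  The axis is
#' deliberately not normalised: its magnitude carries the class-mean
#' separation, and sign-based classification is scale-invariant anyway.
#'
#' @param pos matrix of latent vectors with the attribute (n_pos x d).
#' @param neg matrix of latent vectors without it (n_neg x d).
#' @param name attribute name.
#' @return object of class `attribute_axis`: `name`, `axis` (length d),
#'   `n_positive`, `n_negative`.
#' @export
compute_axis <- function(pos, neg, name = "attribute") {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) < 1 || nrow(neg) < 1) stop("both label classes must be non-empty")
  if (ncol(pos) != ncol(neg)) stop("latent dimensions differ between classes")
  axis <- colMeans(pos) - colMeans(neg)
  if (sqrt(sum(axis^2)) == 0)
    stop("degenerate labels: class means coincide, axis has zero norm")
  structure(list(name = name, axis = axis,
                 n_positive = nrow(pos), n_negative = nrow(neg)),
            class = "attribute_axis")
}

#' @export
print.attribute_axis <- function(x, ...) {
  cat(sprintf("attribute_axis '%s': d = %d, |axis| = %.4g (%d positive, %d negative examples)\n",
              x$name, length(x$axis), sqrt(sum(x$axis^2)),
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Sign-projection attribute classifier
#'
#' Projects each latent vector onto the axis; positive projections are
#' classified as carrying the attribute.  An exact zero projection (a
#' measure-zero tie) is classified negative and flagged.
#'
#' @param axis an [compute_axis()] result.
#' @param z a latent vector or a matrix with one vector per row.
#' @return logical vector (`TRUE` = positive class) with attribute
#'   `projection` (the raw projections) and, when ties occurred, attribute
#'   `tie` marking them.
#' @export
classify <- function(axis, z) {
  stopifnot(inherits(axis, "attribute_axis"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != length(axis$axis))
    stop("latent dimension does not match the axis")
  proj <- as.numeric(z %*% axis$axis)
  out <- proj > 0
  attr(out, "projection") <- proj
  if (any(proj == 0)) {
    attr(out, "tie") <- which(proj == 0)
    message(sprintf("%d zero projection(s) classified negative (tie rule)",
                    sum(proj == 0)))
  }
  out
}

#' Voxel sensitivity map for an attribute
#'
#' Pearson correlation of each weight-matrix column (over the d latent
#' rows; the bias row is excluded) with the attribute axis.  Zero-variance
#' columns get correlation 0 and are flagged.
#'
#' @param wm a `weight_matrix`.
#' @param axis an `attribute_axis` of matching dimension.
#' @return numeric vector in \[-1, 1\], one value per voxel, with attribute
#'   `undefined` listing zero-variance columns (if any).
#' @export
sensitivity_map <- function(wm, axis) {
  stopifnot(inherits(wm, "weight_matrix"), inherits(axis, "attribute_axis"))
  Wl <- wm$W[-1, , drop = FALSE]
  if (nrow(Wl) != length(axis$axis))
    stop("weight-matrix latent rows do not match the axis dimension")
  sds <- apply(Wl, 2, sd)
  out <- numeric(ncol(Wl))
  ok <- sds > 0
  if (any(ok)) out[ok] <- as.numeric(cor(Wl[, ok, drop = FALSE], axis$axis))
  if (any(!ok)) attr(out, "undefined") <- unname(which(!ok))
  out
}

#' Write / read attribute axes as a delimited latent table
#'
#' Axes are stored as named rows (`name`, then `z1..zd`), tab-delimited.
#'
#' @param axes list of `attribute_axis` objects.
#' @param path file path.
#' @return `read_axes` returns a named list of `attribute_axis` objects.
#' @export
write_axes <- function(axes, path) {
  stopifnot(all(vapply(axes, inherits, logical(1), "attribute_axis")))
  Z <- t(vapply(axes, function(a) a$axis, numeric(length(axes[[1]]$axis))))
  tab <- data.frame(name = vapply(axes, `[[`, character(1), "name"),
                    n_positive = vapply(axes, `[[`, numeric(1), "n_positive"),
                    n_negative = vapply(axes, `[[`, numeric(1), "n_negative"))
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  write.table(cbind(tab, Z), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_axes
#' @export
read_axes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  zcols <- grep("^z[0-9]+$", names(tab))
  axes <- lapply(seq_len(nrow(tab)), function(i) {
    structure(list(name = tab$name[i],
                   axis = as.numeric(tab[i, zcols]),
                   n_positive = tab$n_positive[i],
                   n_negative = tab$n_negative[i]),
              class = "attribute_axis")
  })
  names(axes) <- tab$name
  axes
}
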