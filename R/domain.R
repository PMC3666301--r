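#' Spatial domain of an image
#'
#' An `image_domain` describes the grid on which images live: the array
#' extents and, optionally, a mask restricting analysis to a subset of grid
#' points (e.g. voxels inside the brain). Retained points are stored as
#' 0-based integer coordinates in R's native array order (first axis varies
#' fastest); every vectorised image in the package uses this same order, so
#' point `l` of a coefficient vector always corresponds to `points[l, ]`.
#'
#' @param shape Integer vector of extents, one per spatial axis (2 or 3 axes).
#' @param mask Optional logical array (or vector) with `prod(shape)` entries;
#'   `TRUE` marks points kept for analysis. Default keeps every point.
#' @return An object of class `image_domain` with elements `shape`, `mask`
#'   (always a logical vector of length `prod(shape)`), `points` (N x d
#'   integer matrix of 0-based coordinates) and `n_points`.
#' @examples
#' dom <- image_domain(c(4, 4))
#' dom$n_points
#' @export
image_domain <- function(shape, mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L || any(shape < 1L))
    stop("`shape` must give 2 or 3 positive extents")
  npix <- prod(shape)
  if (is.null(mask)) {
    mask <- rep(TRUE, npix)
  } else {
    mask <- as.logical(mask)
    if (length(mask) != npix)
      stop("`mask` has ", length(mask), " entries but the domain has ", npix)
    if (anyNA(mask)) stop("`mask` contains NA")
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask retains no points")
  points <- arrayInd(idx, .dim = shape) - 1L
  structure(
    list(shape = shape, mask = mask, points = points,
         n_points = length(idx)),
    class = "image_domain"
  )
}

#' @export
print.image_domain <- function(x, ...) {
  cat("<image_domain> ", paste(x$shape, collapse = " x "),
      "; ", x$n_points, " of ", prod(x$shape), " points retained\n", sep = "")
  invisible(x)
}

#' Regular lattice of basis knots
#'
#' Places knots on a regular lattice covering the bounding box of the domain,
#' anchored at coordinate 0 with step `spacing` along every axis (the last
#' knot does not exceed the maximal extent). The kernel bandwidth defaults to
#' `sqrt(3) * spacing`, so that neighbouring basis bumps overlap
#' substantially; for 4-unit spacing this gives a bandwidth of about 6.93.
#'
#' @param domain An [image_domain()].
#' @param spacing Distance between adjacent knots along each axis (>= 1).
#' @param bandwidth Kernel bandwidth `h`; default `sqrt(3) * spacing`.
#' @return An object of class `knot_grid`: `knots` (q x d matrix of 0-based
#'   coordinates), `spacing`, `bandwidth`, `n_knots` and the per-axis knot
#'   positions `axes`.
#' @examples
#' grid <- knot_grid(image_domain(c(100, 100)), spacing = 2)
#' grid$n_knots  # 50 x 50 = 2500
#' @export
knot_grid <- function(domain, spacing, bandwidth = sqrt(3) * spacing) {
  stopifnot(inherits(domain, "image_domain"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing < 1)
    stop("`spacing` must be a single value >= 1")
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("`bandwidth` must be a single positive value")
  axes <- lapply(domain$shape, function(ext) seq(0, ext - 1L, by = spacing))
  if (any(vapply(axes, length, 1L) == 0L))
    stop("knot spacing leaves no knots inside the domain")
  knots <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(knots) <- NULL
  structure(
    list(knots = knots, spacing = spacing, bandwidth = bandwidth,
         n_knots = nrow(knots), axes = axes),
    class = "knot_grid"
  )
}

#' @export
print.knot_grid <- function(x, ...) {
  cat("<knot_grid> ", x$n_knots, " knots, spacing ", x$spacing,
      ", bandwidth ", signif(x$bandwidth, 4), "\n", sep = "")
  invisible(x)
}

#' Embed a per-point vector into the domain's array geometry
#'
#' Inverse of the mask extraction: places the N retained values back at their
#' grid positions, filling unmasked points with `fill`.
#'
#' @param values Numeric vector of length `domain$n_points`.
#' @param domain An [image_domain()].
#' @param fill Value used outside the mask (default `NA`).
#' @return An array with dimensions `domain$shape`.
#' @export
as_image <- function(values, domain, fill = NA_real_) {
  stopifnot(inherits(domain, "image_domain"))
  if (length(values) != domain$n_points)
    stop("`values` has length ", length(values),
         " but the domain retains ", domain$n_points, " points")
  out <- rep(fill, prod(domain$shape))
  out[which(domain$mask)] <- values
  array(out, dim = domain$shape)
}
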