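#' Radial B-spline kernel
#'
#' Compactly supported piecewise-cubic kernel of distance used for the basis
#' expansion. For bandwidth `h` it equals
#' \deqn{\phi(u) = \frac{1}{4h^2}\left\{h^3 + 3h^2(h-u) + 3h(h-u)^2
#'   - 3(h-u)^3\right\}, \quad u \le h,}
#' \deqn{\phi(u) = \frac{(2h-u)^3}{4h^2}, \quad h < u \le 2h,}
#' and 0 beyond `2h`. The kernel is continuous, nonincreasing on its support,
#' takes the value `h` at the origin and `h/4` at `u = h`.
#'
#' @param u Nonnegative distance(s); vectorised.
#' @param h Positive bandwidth.
#' @return Kernel values, same shape as `u`.
#' @examples
#' radial_bspline(0, h = 2)   # 2
#' radial_bspline(2, h = 2)   # 0.5
#' @export
radial_bspline <- function(u, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("`h` must be a single positive value")
  if (!is.numeric(u) || any(u < 0))
    stop("`u` must be nonnegative")
  out <- numeric(length(u))
  near <- u <= h
  mid <- u > h & u <= 2 * h
  if (any(near)) {
    d <- h - u[near]
    out[near] <- (h^3 + 3 * h^2 * d + 3 * h * d^2 - 3 * d^3) / (4 * h^2)
  }
  if (any(mid)) out[mid] <- (2 * h - u[mid])^3 / (4 * h^2)
  attributes(out) <- attributes(u)
  out
}

#' Basis matrix mapping grid points to knot coefficients
#'
#' Builds the N x q matrix `B` with entry `B[l, m] = phi(||w_l - k_m||)`,
#' where `w_l` ranges over the retained points of the domain and `k_m` over
#' the knots, and `phi` is [radial_bspline()] with the grid's bandwidth.
#' Entries vanish beyond distance `2h` from a knot, so the matrix is stored
#' sparse; the contract is the dense definition.
#'
#' @param domain An [image_domain()].
#' @param grid A [knot_grid()] on the same lattice.
#' @return An object of class `basis_matrix`: `values` (sparse N x q
#'   [Matrix::dgCMatrix-class]), `domain`, `grid`.
#' @export
build_basis_matrix <- function(domain, grid) {
  stopifnot(inherits(domain, "image_domain"), inherits(grid, "knot_grid"))
  pts <- domain$points
  knots <- grid$knots
  if (ncol(pts) != ncol(knots))
    stop("domain and knot grid have different numbers of axes")
  h <- grid$bandwidth
  N <- nrow(pts); q <- nrow(knots)
  support2 <- (2 * h)^2
  # chunk over knots to keep the dense distance block small
  chunk <- max(1L, floor(5e6 / N))
  ii <- vector("list", 0L); jj <- vector("list", 0L); xx <- vector("list", 0L)
  start <- 1L
  while (start <= q) {
    end <- min(q, start + chunk - 1L)
    kb <- knots[start:end, , drop = FALSE]
    d2 <- matrix(0, N, nrow(kb))
    for (ax in seq_len(ncol(pts)))
      d2 <- d2 + outer(pts[, ax], kb[, ax], "-")^2
    nz <- which(d2 <= support2)
    if (length(nz)) {
      rows <- ((nz - 1L) %% N) + 1L
      cols <- ((nz - 1L) %/% N) + start
      ii[[length(ii) + 1L]] <- rows
      jj[[length(jj) + 1L]] <- cols
      xx[[length(xx) + 1L]] <- radial_bspline(sqrt(d2[nz]), h)
    }
    start <- end + 1L
  }
  values <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(N, q)
  )
  structure(list(values = values, domain = domain, grid = grid),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat("<basis_matrix> ", nrow(x$values), " points x ", ncol(x$values),
      " knots; ", length(x$values@x), " nonzero entries\n", sep = "")
  invisible(x)
}

#' Reduce an image block to basis coefficients
#'
#' Computes `Y = S B`: each subject's image (a row of `S` over the retained
#' points) is projected onto the knot basis, giving the low-dimensional
#' response block used by the sparse PLS fit.
#'
#' @param S Numeric n x N matrix, one row per subject over the domain's
#'   retained points.
#' @param basis A [build_basis_matrix()] result.
#' @return Dense numeric n x q matrix.
#' @export
reduce_images <- function(S, basis) {
  stopifnot(inherits(basis, "basis_matrix"))
  S <- as.matrix(S)
  if (ncol(S) != nrow(basis$values))
    stop("`S` has ", ncol(S), " columns but the basis has ",
         nrow(basis$values), " points")
  as.matrix(S %*% basis$values)
}

#' Back-project basis-space loadings to the image grid
#'
#' Maps a q-vector of knot loadings to the N retained grid points via `B v`,
#' e.g. to render a component's selected knots as a coefficient image.
#'
#' @param v Numeric vector of length q (number of knots).
#' @param basis A [build_basis_matrix()] result.
#' @param as_array If `TRUE`, reshape to the domain's array geometry
#'   (unmasked points become `NA`).
#' @return Numeric vector of length N, or an array if `as_array = TRUE`.
#' @export
back_project <- function(v, basis, as_array = FALSE) {
  stopifnot(inherits(basis, "basis_matrix"))
  if (length(v) != ncol(basis$values))
    stop("`v` has length ", length(v), " but the basis has ",
         ncol(basis$values), " knots")
  out <- as.numeric(basis$values %*% v)
  if (as_array) as_image(out, basis$domain) else out
}
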