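#' Soft-thresholding operator
#'
#' `sign(y) * pmax(|y| - lambda, 0)`, the proximal operator of the L1
#' penalty; applied elementwise inside the NIPALS inner loop. Entries whose
#' magnitude equals `lambda` exactly are set to zero.
#'
#' @param y Numeric scalar, vector or matrix.
#' @param lambda Nonnegative penalty.
#' @return Same shape as `y`.
#' @examples
#' soft_threshold(c(5, -5, 1), 2)  # 3 -3 0
#' @export
soft_threshold <- function(y, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a single nonnegative value")
  sign(y) * pmax(abs(y) - lambda, 0)
}

# Internal engine: sequential extraction of k sparse PLS-SVD components from
# column-centred blocks. The cross-product M = X'Y is maintained across
# deflation by the rank-1 identity M_{next} = M - (t't) p q', and Y is never
# copied: q-loadings are recovered from the undeflated block via
# q = (Y't - Q T't) / t't. Returns weights, scores and loadings column-wise.
spls_engine <- function(X, Y, lamX, lamY, k, tol = 1e-6, max_iter = 500L,
                        partial = FALSE) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  M <- crossprod(X, Y)
  Xd <- X
  U <- matrix(0, p, k); V <- matrix(0, q, k)
  Tm <- matrix(0, n, k); P <- matrix(0, p, k); Q <- matrix(0, q, k)
  iters <- integer(k); conv <- logical(k)
  k_done <- 0L
  fail <- function(comp, ...) {
    # with partial = TRUE, a later component that degenerates truncates the
    # model instead of failing the whole fit
    if (partial && comp > 1L) rlang::abort("truncate", class = "spls_truncate")
    stop("component ", comp, ": ", ...)
  }
  for (comp in seq_len(k)) {
    trunc <- tryCatch({
    maxM <- max(abs(M))
    if (maxM == 0)
      fail(comp, "X'Y is zero; no signal to initialize from")
    # initialisation: leading singular pair of M via the small-side eigenproblem
    if (p <= q) {
      eg <- eigen(tcrossprod(M), symmetric = TRUE)
      u <- eg$vectors[, 1L]
      v <- drop(crossprod(M, u))
    } else {
      eg <- eigen(crossprod(M), symmetric = TRUE)
      v <- eg$vectors[, 1L]
      u <- drop(M %*% v)
      nu <- sqrt(sum(u^2))
      if (nu == 0) fail(comp, "degenerate initialization")
      u <- u / nu
      v <- drop(crossprod(M, u))
    }
    nv <- sqrt(sum(v^2))
    if (nv == 0) fail(comp, "degenerate initialization")
    v <- v / nv
    it <- 0L; converged <- FALSE
    repeat {
      it <- it + 1L
      u_new <- soft_threshold(drop(M %*% v), lamX)
      nu <- sqrt(sum(u_new^2))
      if (nu == 0)
        fail(comp, "penalty too large for the X block (lambda_X = ", lamX,
             " annihilates the weight vector)")
      u_new <- u_new / nu
      v_new <- soft_threshold(drop(crossprod(M, u_new)), lamY)
      nv <- sqrt(sum(v_new^2))
      if (nv == 0)
        fail(comp, "penalty too large for the Y block (lambda_Y = ", lamY,
             " annihilates the weight vector)")
      v_new <- v_new / nv
      delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
      u <- u_new; v <- v_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    if (!converged)
      warning("component ", comp, ": NIPALS did not converge in ",
              max_iter, " iterations")
    tvec <- drop(Xd %*% u)
    tt <- sum(tvec^2)
    if (tt == 0) fail(comp, "zero score vector")
    pl <- drop(crossprod(Xd, tvec)) / tt
    prev <- seq_len(comp - 1L)
    ql <- drop(crossprod(Y, tvec))
    if (comp > 1L)
      ql <- ql - drop(Q[, prev, drop = FALSE] %*%
                        crossprod(Tm[, prev, drop = FALSE], tvec))
    ql <- ql / tt
    # deterministic sign: largest-|.| entry of u positive, flipped jointly
    jmax <- which.max(abs(u))
    if (u[jmax] < 0) {
      u <- -u; v <- -v; tvec <- -tvec; pl <- -pl; ql <- -ql
    }
    U[, comp] <- u; V[, comp] <- v
    Tm[, comp] <- tvec; P[, comp] <- pl; Q[, comp] <- ql
    iters[comp] <- it; conv[comp] <- converged
    if (comp < k) {
      Xd <- Xd - tcrossprod(tvec, pl)
      M <- M - tt * tcrossprod(pl, ql)
    }
    FALSE
    }, spls_truncate = function(e) TRUE)
    if (trunc) break
    k_done <- comp
  }
  keep <- seq_len(k_done)
  list(U = U[, keep, drop = FALSE], V = V[, keep, drop = FALSE],
       T = Tm[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Q = Q[, keep, drop = FALSE],
       iterations = iters[keep], converged = conv[keep], k = k_done)
}

#' Extract a single sparse PLS component
#'
#' One round of the soft-thresholded NIPALS iteration: the weight pair is
#' initialised from the leading singular pair of `X'Y`, then alternated as
#' `u <- g_lamX(X'Y v)` and `v <- g_lamY(Y'X u)` (each renormalised to unit
#' L2 norm) until convergence. The score and loadings are `t = X u`,
#' `p = X't / t't`, `q = Y't / t't`.
#'
#' Both blocks are assumed column-centred by the caller (as [fit_spls()]
#' does); the deflation state of the inputs is the state the factor belongs
#' to.
#'
#' @param X Column-centred n x p explanatory block.
#' @param Y Column-centred n x q response block.
#' @param lamX,lamY Nonnegative L1 penalties on `u` and `v`.
#' @param tol Convergence tolerance on the max absolute change of `u`, `v`.
#' @param max_iter Iteration cap; non-convergence warns and flags the factor.
#' @return An object of class `spls_factor`: `u`, `v`, `t`, `p_load`,
#'   `q_load`, `iterations`, `converged`.
#' @export
spls_component <- function(X, Y, lamX = 0, lamY = 0,
                           tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  check_blocks(X, Y)
  check_penalties(lamX, lamY)
  fit <- spls_engine(X, Y, lamX, lamY, k = 1L, tol = tol,
                     max_iter = max_iter)
  structure(
    list(u = fit$U[, 1L], v = fit$V[, 1L], t = fit$T[, 1L],
         p_load = fit$P[, 1L], q_load = fit$Q[, 1L],
         iterations = fit$iterations[1L], converged = fit$converged[1L]),
    class = "spls_factor"
  )
}

#' Deflate the data blocks by an extracted factor
#'
#' Removes a factor's rank-1 contribution before the next component is
#' extracted: `X <- X - t p'` and `Y <- Y - t q'`. Because `p = X't/t't` and
#' `q = Y't/t't`, both deflated blocks are orthogonal to the score `t`.
#'
#' @param X,Y The blocks the factor was extracted from.
#' @param factor An `spls_factor` from [spls_component()].
#' @return List with deflated `X` and `Y`.
#' @export
deflate <- function(X, Y, factor) {
  stopifnot(inherits(factor, "spls_factor"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != length(factor$t) || nrow(Y) != length(factor$t))
    stop("row count of the blocks does not match the factor's score length")
  if (ncol(X) != length(factor$p_load) || ncol(Y) != length(factor$q_load))
    stop("column counts do not match the factor's loadings")
  if (all(factor$t == 0)) stop("factor has a zero score vector")
  list(X = X - tcrossprod(factor$t, factor$p_load),
       Y = Y - tcrossprod(factor$t, factor$q_load))
}

#' Fit a sparse PLS regression model
#'
#' Sequentially extracts `k` soft-thresholded PLS-SVD components with
#' deflation (see [spls_component()]), assembles the weight, score and
#' loading matrices, and forms the regression coefficient matrix
#' `C = U (P'U)^{-1} Q'` so that predictions are `Y_hat = X C` on the
#' centred scale.
#'
#' Columns of both blocks are centred by default (stored for prediction);
#' `scale_x = TRUE` additionally scales X columns to unit variance, useful
#' for covariates on mixed units.
#'
#' @param X n x p explanatory matrix.
#' @param Y n x q response matrix (e.g. the basis-reduced image block).
#' @param lamX,lamY Nonnegative L1 penalties.
#' @param k Number of components (`1 <= k <= min(n - 1, p, q)`).
#' @param center Centre columns of X and Y (default `TRUE`).
#' @param scale_x Scale X columns to unit standard deviation.
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `spls` with elements `U`, `V`, `T`, `P`, `Q`
#'   (matrices with `k` columns), `C` (p x q coefficients on the centred
#'   scale), `penalties`, `k`, `preprocess` (centres/scales), `iterations`,
#'   `converged`, `dims`.
#' @seealso [predict.spls()], [tidy.spls()], [glance.spls()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' Y <- X %*% matrix(rnorm(12), 4, 3) + 0.1 * matrix(rnorm(30), 10, 3)
#' fit <- fit_spls(X, Y, k = 2)
#' glance(fit)
#' @export
fit_spls <- function(X, Y, lamX = 0, lamY = 0, k = 1L,
                     center = TRUE, scale_x = FALSE,
                     tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  check_blocks(X, Y)
  check_penalties(lamX, lamY)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1")
  if (k > min(n - 1L, p, q))
    stop("`k` = ", k, " exceeds min(n - 1, p, q) = ", min(n - 1L, p, q))
  x_center <- if (center) colMeans(X) else numeric(p)
  y_center <- if (center) colMeans(Y) else numeric(q)
  Xc <- sweep(X, 2L, x_center, "-")
  Yc <- sweep(Y, 2L, y_center, "-")
  x_scale <- rep(1, p)
  if (scale_x) {
    x_scale <- apply(Xc, 2L, stats::sd)
    if (any(x_scale == 0)) stop("constant X column cannot be scaled")
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  fit <- spls_engine(Xc, Yc, lamX, lamY, k, tol = tol, max_iter = max_iter)
  PtU <- crossprod(fit$P, fit$U)
  kap <- tryCatch(kappa(PtU, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e12)
    stop("P'U is singular or numerically singular (condition number ",
         format(kap, digits = 3), "); try a smaller k")
  if (kap > 1e10)
    warning("P'U is ill-conditioned (condition number ",
            format(kap, digits = 3), ")")
  C <- fit$U %*% solve(PtU, t(fit$Q))
  structure(
    list(U = fit$U, V = fit$V, T = fit$T, P = fit$P, Q = fit$Q, C = C,
         penalties = c(lamX = lamX, lamY = lamY), k = k,
         preprocess = list(x_center = x_center, y_center = y_center,
                           x_scale = x_scale, center = center,
                           scale_x = scale_x),
         iterations = fit$iterations, converged = fit$converged,
         dims = c(n = n, p = p, q = q)),
    class = "spls"
  )
}

#' Predict responses from a fitted sparse PLS model
#'
#' Applies the training preprocessing (centring, optional X scaling) to new
#' covariates, multiplies by the coefficient matrix and maps back to the
#' original response scale.
#'
#' @param object An [fit_spls()] model.
#' @param newdata Matrix (or vector) with `p` columns.
#' @param ... Unused.
#' @return Matrix of predicted responses, one row per row of `newdata`.
#' @export
predict.spls <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dims[["p"]])
    stop("`newdata` has ", ncol(newdata), " columns; expected ",
         object$dims[["p"]])
  pp <- object$preprocess
  Xc <- sweep(newdata, 2L, pp$x_center, "-")
  if (pp$scale_x) Xc <- sweep(Xc, 2L, pp$x_scale, "/")
  sweep(Xc %*% object$C, 2L, pp$y_center, "+")
}

#' @export
print.spls <- function(x, ...) {
  d <- x$dims
  cat("Sparse PLS model (PLS-SVD, regression mode)\n")
  cat("  n = ", d[["n"]], ", p = ", d[["p"]], ", q = ", d[["q"]],
      ", k = ", x$k, "\n", sep = "")
  cat("  penalties: lambda_X = ", signif(x$penalties[["lamX"]], 4),
      ", lambda_Y = ", signif(x$penalties[["lamY"]], 4), "\n", sep = "")
  cat("  nonzero weights per component: X ",
      paste(colSums(x$U != 0), collapse = "/"), "; Y ",
      paste(colSums(x$V != 0), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Tidy the weight vectors of a sparse PLS model
#'
#' One row per (block, component, variable) with a nonzero weight, in the
#' broom convention.
#'
#' @param x An [fit_spls()] model.
#' @param all Include zero weights too (default drops them).
#' @param ... Unused.
#' @return A tibble with columns `block` ("X" or "Y"), `component`, `term`
#'   (column index) and `weight`.
#' @method tidy spls
#' @export
tidy.spls <- function(x, all = FALSE, ...) {
  one <- function(W, block) {
    dplyr::bind_rows(lapply(seq_len(ncol(W)), function(j) {
      idx <- if (all) seq_len(nrow(W)) else which(W[, j] != 0)
      tibble::tibble(block = block, component = j, term = idx,
                     weight = W[idx, j])
    }))
  }
  dplyr::bind_rows(one(x$U, "X"), one(x$V, "Y"))
}

#' One-row summary of a sparse PLS model
#'
#' @param x An [fit_spls()] model.
#' @param ... Unused.
#' @return A tibble with dimensions, penalties, per-component nonzero counts
#'   and convergence status.
#' @method glance spls
#' @export
glance.spls <- function(x, ...) {
  tibble::tibble(
    n = x$dims[["n"]], p = x$dims[["p"]], q = x$dims[["q"]], k = x$k,
    lamX = x$penalties[["lamX"]], lamY = x$penalties[["lamY"]],
    nonzero_x = paste(colSums(x$U != 0), collapse = "/"),
    nonzero_y = paste(colSums(x$V != 0), collapse = "/"),
    converged = all(x$converged)
  )
}

# shared argument checks
check_blocks <- function(X, Y) {
  if (!is.numeric(X) || !is.numeric(Y))
    stop("X and Y must be numeric matrices")
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows (subjects)")
  if (nrow(X) < 2L) stop("at least 2 subjects are required")
  invisible(TRUE)
}

check_penalties <- function(lamX, lamY) {
  for (lam in list(lamX, lamY))
    if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || !is.finite(lam))
      stop("penalties must be single nonnegative finite values")
  invisible(TRUE)
}
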