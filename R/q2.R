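#' Random balanced fold assignment
#'
#' Assigns each of `n` subjects to one of `K` cross-validation folds so that
#' fold sizes differ by at most one. With `seed` given, the draw is
#' reproducible and the global RNG state is left untouched.
#'
#' @param n Number of subjects (`n >= K`).
#' @param K Number of folds (default 10).
#' @param seed Optional integer seed for the fold draw.
#' @return An object of class `fold_assignment`: `kappa` (integer vector
#'   mapping subject to fold), `K`, `seed`.
#' @examples
#' table(make_folds(102, K = 10, seed = 1)$kappa)  # eight 10s, two 11s
#' @export
make_folds <- function(n, K = 10L, seed = NULL) {
  n <- as.integer(n); K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2")
  if (n < K) stop("cannot split n = ", n, " subjects into K = ", K, " folds")
  kappa <- with_preserved_seed(seed, sample(rep(seq_len(K), length.out = n)))
  structure(list(kappa = kappa, K = K, seed = seed),
            class = "fold_assignment")
}

# evaluate `expr` under `seed` (if non-NULL) without disturbing the caller's
# RNG stream
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Cross-validated and in-sample error sums for one penalty pair.
#
# For every fold: centre (and optionally scale) on the training subjects,
# fit k_max components, and record squared prediction errors on the held-out
# subjects for each k = 1..k_max. On the full data: fit once and record
# in-sample residual sums for k = 0..k_max (k = 0 is the column-mean model).
# Returns press (k_max x q) and rss ((k_max + 1) x q, row 1 = 0 components).
cv_error_sums <- function(X, Y, lamX, lamY, k_max, folds,
                          center = TRUE, scale_x = FALSE,
                          tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(folds, "fold_assignment"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); q <- ncol(Y)
  if (length(folds$kappa) != n)
    stop("fold assignment is for ", length(folds$kappa),
         " subjects, data has ", n)
  k_max <- as.integer(k_max)
  prep <- function(idx) {
    Xs <- X[idx, , drop = FALSE]; Ys <- Y[idx, , drop = FALSE]
    xc <- if (center) colMeans(Xs) else numeric(ncol(X))
    yc <- if (center) colMeans(Ys) else numeric(q)
    Xs <- sweep(Xs, 2L, xc, "-"); Ys <- sweep(Ys, 2L, yc, "-")
    xs <- rep(1, ncol(X))
    if (scale_x) {
      xs <- apply(Xs, 2L, stats::sd)
      if (any(xs == 0)) stop("constant X column cannot be scaled")
      Xs <- sweep(Xs, 2L, xs, "/")
    }
    list(X = Xs, Y = Ys, xc = xc, yc = yc, xs = xs)
  }
  press <- matrix(0, k_max, q)
  for (f in seq_len(folds$K)) {
    test <- which(folds$kappa == f)
    train <- which(folds$kappa != f)
    tr <- prep(train)
    fit <- tryCatch(
      spls_engine(tr$X, tr$Y, lamX, lamY, k = k_max, tol = tol,
                  max_iter = max_iter, partial = TRUE),
      error = function(e)
        stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
    )
    Xt <- sweep(X[test, , drop = FALSE], 2L, tr$xc, "-")
    if (scale_x) Xt <- sweep(Xt, 2L, tr$xs, "/")
    Yt <- sweep(Y[test, , drop = FALSE], 2L, tr$yc, "-")
    Z <- Xt %*% fit$U
    PtU <- crossprod(fit$P, fit$U)
    for (k in seq_len(k_max)) {
      if (k > fit$k) { press[k, ] <- NA_real_; next }
      sel <- seq_len(k)
      pred <- tryCatch(
        Z[, sel, drop = FALSE] %*%
          solve(PtU[sel, sel, drop = FALSE],
                t(fit$Q[, sel, drop = FALSE])),
        error = function(e) NULL)
      if (is.null(pred)) press[k, ] <- NA_real_
      else press[k, ] <- press[k, ] + colSums((Yt - pred)^2)
    }
  }
  all_p <- prep(seq_len(n))
  full <- spls_engine(all_p$X, all_p$Y, lamX, lamY, k = k_max, tol = tol,
                      max_iter = max_iter, partial = TRUE)
  rss <- matrix(NA_real_, k_max + 1L, q)
  R <- all_p$Y
  rss[1L, ] <- colSums(R^2)
  for (k in seq_len(min(k_max, full$k))) {
    R <- R - tcrossprod(full$T[, k], full$Q[, k])
    rss[k + 1L, ] <- colSums(R^2)
  }
  list(press = press, rss = rss)
}

#' Per-response PRESS and RSS for a sparse PLS model
#'
#' `PRESS_jk` sums, over subjects, the squared error of predicting response
#' column `j` for subject `i` from the model fitted with subject `i`'s fold
#' held out; `RSS_jk` is the in-sample residual sum of squares of the
#' all-data model, both at `k` components and the given penalties.
#'
#' @param X,Y Data blocks (uncentred; centring is refit within each fold).
#' @param lamX,lamY L1 penalties.
#' @param k Number of components.
#' @param folds A [make_folds()] assignment.
#' @param ... Passed to [fit_spls()] (`center`, `scale_x`, `tol`,
#'   `max_iter`).
#' @return List with numeric q-vectors `press` and `rss`.
#' @export
press_rss <- function(X, Y, lamX, lamY, k, folds, ...) {
  sums <- cv_error_sums(X, Y, lamX, lamY, k_max = k, folds = folds, ...)
  list(press = sums$press[k, ], rss = sums$rss[k + 1L, ])
}

#' Cross-validated predictive relevance Q-squared
#'
#' \deqn{Q^2(\lambda_X, \lambda_Y, k) = 1 -
#'   \frac{\sum_j \mathrm{PRESS}_{jk}}{\sum_j \mathrm{RSS}_{j,k-1}},}
#' the proportional reduction in held-out prediction error achieved by the
#' k-th component over the in-sample fit with `k - 1` components. The
#' denominator at `k = 1` is the residual sum of squares around the column
#' means (the 0-component model). Values near 1 mean the component predicts
#' held-out data almost perfectly; values at or below 0 mean it adds nothing.
#'
#' @inheritParams press_rss
#' @return A single numeric value (always <= 1).
#' @export
q2 <- function(X, Y, lamX, lamY, k, folds, ...) {
  sums <- cv_error_sums(X, Y, lamX, lamY, k_max = k, folds = folds, ...)
  denom <- sum(sums$rss[k, ])
  if (denom == 0)
    stop("Q2 denominator is zero: the ", k - 1,
         "-component model already fits the data exactly")
  1 - sum(sums$press[k, ]) / denom
}

# leading singular pair of X'Y via the small-side eigenproblem (sign-free)
init_singular_pair <- function(Xc, Yc) {
  M <- crossprod(Xc, Yc)
  if (max(abs(M)) == 0) stop("X'Y is zero; no signal to initialize from")
  if (nrow(M) <= ncol(M)) {
    u <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1L]
    v <- drop(crossprod(M, u))
  } else {
    v <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1L]
    u <- drop(M %*% v)
    u <- u / sqrt(sum(u^2))
    v <- drop(crossprod(M, u))
  }
  v <- v / sqrt(sum(v^2))
  list(u = u, v = v, M = M)
}

#' Grid search for penalties and number of components by Q-squared
#'
#' Evaluates \eqn{Q^2} by K-fold cross-validation over every combination of
#' the two penalty grids and `k = 1..k_max`, and returns the maximiser. The
#' fold assignment is drawn once per search so all cells are comparable.
#' Ties are broken towards the sparser model: smallest `k`, then largest
#' `lamX`, then largest `lamY`.
#'
#' Default grids are the 0.1..0.9 quantiles of the magnitudes of the vectors
#' the penalties threshold at initialisation, `|X'Y v0|` for `lamX` and
#' `|Y'X u0|` for `lamY`, where `(u0, v0)` is the leading singular pair of
#' `X'Y`.
#'
#' Cells whose cross-validation fit fails (typically a penalty that
#' annihilates a weight vector on a training subset) get `Q2 = NA` and are
#' excluded from the argmax; if every cell fails, the error lists the
#' per-cell failures. As an alternative to plain maximisation,
#' `rule = "threshold"` retains the largest `k` whose \eqn{Q^2} exceeds the
#' classical 0.0975 cut-off.
#'
#' @param X,Y Data blocks.
#' @param lamX_grid,lamY_grid Numeric penalty grids (default as above).
#' @param k_max Largest number of components to consider (default 5).
#' @param k_grid Optional subset of `1:k_max` the selection is restricted
#'   to (all of `1:k_max` by default); the table always reports every k.
#' @param folds Optional [make_folds()] assignment; drawn internally
#'   (with `K`, `seed`) when absent.
#' @param K,seed Fold count and seed used when `folds` is absent.
#' @param rule `"max"` (default) or `"threshold"` (retain components with
#'   `Q2 >= q2_threshold`).
#' @param q2_threshold Threshold for `rule = "threshold"` (default 0.0975).
#' @param ... Passed to [fit_spls()].
#' @return An object of class `q2_grid`: `best` (list with `lamX`, `lamY`,
#'   `k`, `Q2`), `table` (tibble with columns `lamX`, `lamY`, `k`, `Q2`,
#'   `sum_PRESS`, `sum_RSS`, the latter being the Q2 denominator at
#'   `k - 1` components), `folds`, `failures`.
#' @export
grid_search <- function(X, Y, lamX_grid = NULL, lamY_grid = NULL,
                        k_max = 5L, k_grid = NULL, folds = NULL,
                        K = 10L, seed = NULL,
                        rule = c("max", "threshold"), q2_threshold = 0.0975,
                        ...) {
  rule <- match.arg(rule)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(folds)) folds <- make_folds(n, K = K, seed = seed)
  if (is.null(lamX_grid) || is.null(lamY_grid)) {
    Xc <- sweep(X, 2L, colMeans(X), "-")
    Yc <- sweep(Y, 2L, colMeans(Y), "-")
    init <- init_singular_pair(Xc, Yc)
    probs <- seq(0.1, 0.9, by = 0.1)
    if (is.null(lamX_grid))
      lamX_grid <- unname(stats::quantile(abs(drop(init$M %*% init$v)), probs))
    if (is.null(lamY_grid))
      lamY_grid <- unname(stats::quantile(abs(drop(crossprod(init$M, init$u))),
                                          probs))
  }
  if (length(lamX_grid) == 0L || length(lamY_grid) == 0L)
    stop("penalty grids must be nonempty")
  k_max <- as.integer(k_max)
  if (is.null(k_grid)) k_grid <- seq_len(k_max)
  cells <- expand.grid(lamX = lamX_grid, lamY = lamY_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  failures <- list()
  for (i in seq_len(nrow(cells))) {
    lx <- cells$lamX[i]; ly <- cells$lamY[i]
    sums <- tryCatch(
      cv_error_sums(X, Y, lx, ly, k_max = k_max, folds = folds, ...),
      error = function(e) e
    )
    if (inherits(sums, "error")) {
      failures[[paste0("lamX=", signif(lx, 4), ",lamY=", signif(ly, 4))]] <-
        conditionMessage(sums)
      rows[[i]] <- tibble::tibble(
        lamX = lx, lamY = ly, k = seq_len(k_max),
        Q2 = NA_real_, sum_PRESS = NA_real_, sum_RSS = NA_real_)
      next
    }
    sp <- rowSums(sums$press)
    sr <- rowSums(sums$rss)
    denom <- sr[seq_len(k_max)]       # RSS at k - 1 components
    rows[[i]] <- tibble::tibble(
      lamX = lx, lamY = ly, k = seq_len(k_max),
      Q2 = ifelse(denom > 0, 1 - sp / denom, NA_real_),
      sum_PRESS = sp, sum_RSS = denom)
  }
  tab <- dplyr::bind_rows(rows)
  cand <- tab[!is.na(tab$Q2) & tab$k %in% k_grid, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("every grid cell failed:\n",
         paste(names(failures), unlist(failures), sep = ": ",
               collapse = "\n"))
  if (rule == "threshold") {
    eligible <- cand[cand$Q2 >= q2_threshold, , drop = FALSE]
    if (nrow(eligible) == 0L) {
      warning("no cell reached Q2 >= ", q2_threshold,
              "; falling back to plain maximization")
    } else {
      keep <- dplyr::slice_max(
        dplyr::group_by(eligible, .data$lamX, .data$lamY),
        order_by = .data$k, n = 1L, with_ties = FALSE)
      cand <- dplyr::ungroup(keep)
    }
  }
  best <- cand[order(-cand$Q2, cand$k, -cand$lamX, -cand$lamY), ][1L, ]
  structure(
    list(best = list(lamX = best$lamX, lamY = best$lamY,
                     k = best$k, Q2 = best$Q2),
         table = tab, folds = folds, failures = failures, rule = rule),
    class = "q2_grid"
  )
}

#' @export
print.q2_grid <- function(x, ...) {
  cat("Q2 grid search over", length(unique(x$table$lamX)), "x",
      length(unique(x$table$lamY)), "penalty pairs, k up to",
      max(x$table$k), "\n")
  cat("  best: lambda_X =", signif(x$best$lamX, 4),
      ", lambda_Y =", signif(x$best$lamY, 4),
      ", k =", x$best$k, ", Q2 =", signif(x$best$Q2, 4), "\n")
  if (length(x$failures))
    cat("  failed cells:", length(x$failures), "\n")
  invisible(x)
}

#' @method tidy q2_grid
#' @export
tidy.q2_grid <- function(x, ...) x$table

#' @method glance q2_grid
#' @export
glance.q2_grid <- function(x, ...) {
  tibble::tibble(lamX = x$best$lamX, lamY = x$best$lamY, k = x$best$k,
                 Q2 = x$best$Q2, n_cells = nrow(x$table),
                 n_failed = length(x$failures))
}

#' Write a Q-squared table to delimited text
#'
#' @param x A [grid_search()] result.
#' @param path Output file; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
export_q2_table <- function(x, path) {
  stopifnot(inherits(x, "q2_grid"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
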