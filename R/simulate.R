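#' Kronecker-structured true X loadings
#'
#' Builds the p x 2 loading matrix whose columns are Kronecker products of
#' the signal vector `b` with disjoint 0/1 block patterns: component 1 loads
#' on the first `p/20` positions of each of the five `b`-blocks, component 2
#' on the next `p/20`. The two supports are disjoint by construction.
#'
#' @param p Number of covariates; must be divisible by 20.
#' @param b Signal vector, default `c(5, 2, 1, -2, -5)`.
#' @return List with `P` (p x 2 matrix) and `x_support` (list of the two
#'   components' nonzero index sets).
#' @examples
#' make_loading_P(40)$x_support[[1]]  # 1 2 9 10 17 18 25 26 33 34
#' @export
make_loading_P <- function(p, b = c(5, 2, 1, -2, -5)) {
  p <- as.integer(p)
  if (p %% 20L != 0L) stop("`p` must be divisible by 20, got ", p)
  blk <- p %/% 20L
  pat1 <- c(rep(1, blk), rep(0, 3L * blk))
  pat2 <- c(rep(0, blk), rep(1, blk), rep(0, 2L * blk))
  P <- cbind(kronecker(b, pat1), kronecker(b, pat2))
  list(P = P, x_support = list(which(P[, 1L] != 0), which(P[, 2L] != 0)))
}

#' Binary plus-sign (cross) image
#'
#' A cross is the union of a horizontal and a vertical bar of width `width`
#' (odd) and total length `2 * arm + width`, centred at `center` (1-based
#' pixel coordinates). Its pixel count is
#' `2 * width * (2 * arm + width) - width^2`.
#'
#' @param shape Image extents, e.g. `c(100, 100)`.
#' @param center Length-2 centre, 1-based.
#' @param arm Arm length beyond the central square.
#' @param width Bar width (odd positive integer).
#' @return A 0/1 matrix of dimension `shape`.
#' @export
cross_image <- function(shape, center, arm = 15L, width = 5L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, length(center) == 2L)
  width <- as.integer(width); arm <- as.integer(arm)
  if (width < 1L || width %% 2L == 0L) stop("`width` must be odd and >= 1")
  if (arm < 0L) stop("`arm` must be nonnegative")
  half <- (width - 1L) %/% 2L
  dx <- abs(seq_len(shape[1L]) - center[1L])
  dy <- abs(seq_len(shape[2L]) - center[2L])
  horiz <- outer(dx <= arm + half, dy <= half, "&")
  vert <- outer(dx <= half, dy <= arm + half, "&")
  img <- (horiz | vert) * 1
  if (sum(img) == 0) stop("cross lies outside the image")
  img
}

#' True binary component images for the simulation
#'
#' The default truth is two disjoint plus-sign crosses (arm 15, width 5,
#' 325 pixels each) centred in opposite quadrants of a 100 x 100 image; any
#' pair of binary images of the right shape can be substituted. Images are
#' vectorised in R's array order to length `q = prod(shape)`.
#'
#' @param shape Image extents (default `c(100, 100)`).
#' @param centers List of two 1-based centres (default opposite quadrant
#'   centres).
#' @param arm,width Cross geometry, see [cross_image()].
#' @param images Optional list of two custom binary matrices overriding the
#'   crosses.
#' @param require_disjoint Error if the two supports overlap (default TRUE).
#' @return List with `images` (list of two 0/1 matrices), `Q` (q x 2 matrix
#'   of vectorised images), `y_support` (list of the two pixel index sets)
#'   and `q`.
#' @export
make_true_images <- function(shape = c(100L, 100L), centers = NULL,
                             arm = 15L, width = 5L, images = NULL,
                             require_disjoint = TRUE) {
  shape <- as.integer(shape)
  if (is.null(images)) {
    if (is.null(centers))
      centers <- list(round(shape / 4), round(3 * shape / 4))
    images <- lapply(centers, function(ctr)
      cross_image(shape, ctr, arm = arm, width = width))
  }
  if (length(images) != 2L) stop("exactly two true images are required")
  images <- lapply(images, function(im) {
    im <- as.matrix(im)
    if (!all(dim(im) == shape)) stop("true image shape mismatch")
    if (!all(im %in% c(0, 1))) stop("true images must be binary 0/1")
    im
  })
  Q <- cbind(as.vector(images[[1L]]), as.vector(images[[2L]]))
  y_support <- list(which(Q[, 1L] == 1), which(Q[, 2L] == 1))
  if (any(lengths(y_support) == 0L))
    stop("true image supports must be nonempty")
  if (require_disjoint && length(intersect(y_support[[1L]], y_support[[2L]])))
    stop("true image supports overlap")
  list(images = images, Q = Q, y_support = y_support, q = prod(shape))
}

#' Configuration of the two-component simulation model
#'
#' Describes the generator: covariate rows drawn i.i.d. MVN(0, Sigma),
#' latent scores `T = X P` with the Kronecker-structured loadings of
#' [make_loading_P()], and image responses `Y = T Q' + F` where the columns
#' of `Q` are the vectorised binary true images and `F` has i.i.d. standard
#' normal entries.
#'
#' @param n Subjects per dataset.
#' @param p Covariates (divisible by 20).
#' @param image_shape Image extents (default `c(100, 100)`, so q = 10,000).
#' @param Sigma Covariance of the covariates: `NULL` for identity, a p x p
#'   matrix, or `list(family = "ar1", rho = ...)`.
#' @param b Signal vector for the loadings (default `c(5, 2, 1, -2, -5)`).
#' @param truth A [make_true_images()] result (default crosses).
#' @param n_datasets Number of replicate datasets (default 100).
#' @param seed Master seed for the study.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 50L, p = 40L, image_shape = c(100L, 100L),
                       Sigma = NULL, b = c(5, 2, 1, -2, -5),
                       truth = NULL, n_datasets = 100L, seed = 1L) {
  n <- as.integer(n); p <- as.integer(p)
  if (p %% 20L != 0L) stop("`p` must be divisible by 20")
  if (n < 2L) stop("`n` must be at least 2")
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 1L) stop("`n_datasets` must be at least 1")
  if (is.null(Sigma)) {
    Sigma_mat <- diag(p)
  } else if (is.matrix(Sigma)) {
    if (!all(dim(Sigma) == p)) stop("`Sigma` must be p x p")
    Sigma_mat <- Sigma
  } else if (is.list(Sigma) && identical(Sigma$family, "ar1")) {
    rho <- Sigma$rho
    if (abs(rho) >= 1) stop("AR(1) rho must lie in (-1, 1)")
    Sigma_mat <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  } else stop("unsupported `Sigma` specification")
  chol_upper <- tryCatch(chol(Sigma_mat), error = function(e)
    stop("`Sigma` is not positive definite"))
  if (is.null(truth)) truth <- make_true_images(shape = image_shape)
  loading <- make_loading_P(p, b)
  structure(
    list(n = n, p = p, image_shape = as.integer(image_shape),
         Sigma = Sigma_mat, chol_upper = chol_upper, b = b,
         P = loading$P, x_support = loading$x_support, truth = truth,
         n_datasets = n_datasets, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n, ", p =", x$p, ", image",
      paste(x$image_shape, collapse = " x "),
      "(q =", x$truth$q, "),", x$n_datasets, "datasets, seed", x$seed, "\n")
  invisible(x)
}

#' Draw one dataset from the simulation model
#'
#' @param config A [sim_config()].
#' @param seed Optional seed for this replicate (global RNG preserved).
#' @param noise Set `FALSE` to suppress the residual matrix `F` (noiseless
#'   rank-2 responses, useful for checks).
#' @return List with `X` (n x p), `Y` (n x q pixel responses), `scores`
#'   (n x 2 latent scores) and the `config`.
#' @export
simulate_dataset <- function(config, seed = NULL, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(seed, {
    n <- config$n; p <- config$p; q <- config$truth$q
    X <- matrix(stats::rnorm(n * p), n, p) %*% config$chol_upper
    scores <- X %*% config$P
    Y <- if (noise) matrix(stats::rnorm(n * q), n, q) else matrix(0, n, q)
    for (g in 1:2)
      Y[, config$truth$y_support[[g]]] <-
        Y[, config$truth$y_support[[g]]] + scores[, g]
    list(X = X, Y = Y, scores = scores, config = config)
  })
}

#' Pixels selected by a fitted component
#'
#' Without a basis, a pixel is selected iff its entry of the component's
#' sparse Y-weight vector is nonzero. With a basis, the knot weights are
#' back-projected to the pixel grid and a pixel is selected iff the absolute
#' back-projected field exceeds `eps` times its maximum (the field is
#' exactly zero outside the selected knots' support discs).
#'
#' @param model An [fit_spls()] model.
#' @param basis The [build_basis_matrix()] used in the fit, or `NULL` if the
#'   model was fitted on raw pixels.
#' @param component Component index.
#' @param eps Relative threshold for the basis variant (default 1e-8).
#' @return Logical vector over pixels.
#' @export
selected_pixels <- function(model, basis = NULL, component = 1L,
                            eps = 1e-8) {
  stopifnot(inherits(model, "spls"))
  component <- as.integer(component)
  if (component < 1L || component > model$k)
    stop("`component` must lie in 1..", model$k)
  v <- model$V[, component]
  if (is.null(basis)) return(v != 0)
  field <- back_project(v, basis)
  m <- max(abs(field))
  if (m == 0) return(rep(FALSE, length(field)))
  abs(field) > eps * m
}

#' Score a pixel selection against the truth
#'
#' Sensitivity is the fraction of true pixels selected; specificity the
#' fraction of non-true pixels not selected; the c-index (Youden's J) is
#' `sensitivity - (1 - specificity)`.
#'
#' @param selected Logical or 0/1 vector of selected pixels.
#' @param truth Logical or 0/1 vector of true pixels (nonempty support).
#' @return A one-row tibble with `sensitivity`, `specificity`, `c_index`.
#' @export
evaluate_selection <- function(selected, truth) {
  selected <- as.logical(selected); truth <- as.logical(truth)
  if (length(selected) != length(truth))
    stop("`selected` and `truth` have different lengths")
  if (!any(truth)) stop("`truth` has empty support")
  sens <- sum(selected & truth) / sum(truth)
  spec <- if (all(truth)) NA_real_ else sum(!selected & !truth) / sum(!truth)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 c_index = sens - (1 - spec))
}

#' Selection frequency across replicates and its thresholded image
#'
#' Averages binary per-replicate selections pixelwise into a probability
#' image, and binarises at the threshold: a pixel survives only if selected
#' in at least that fraction of replicates.
#'
#' @param selections A list of logical/0-1 vectors, or a replicates x pixels
#'   matrix.
#' @param threshold Survival threshold (default 0.95).
#' @return An object of class `probability_image`: `frequency`, `binary`,
#'   `threshold`, `n_replicates`.
#' @export
probability_image <- function(selections, threshold = 0.95) {
  if (is.list(selections)) {
    lens <- lengths(selections)
    if (length(unique(lens)) != 1L)
      stop("replicate selections have differing lengths")
    selections <- do.call(rbind, lapply(selections, as.numeric))
  }
  selections <- as.matrix(selections) * 1
  if (nrow(selections) < 1L) stop("at least one replicate is required")
  freq <- colMeans(selections)
  structure(
    list(frequency = freq, binary = freq >= threshold,
         threshold = threshold, n_replicates = nrow(selections)),
    class = "probability_image"
  )
}

#' @export
print.probability_image <- function(x, ...) {
  cat("<probability_image> ", length(x$frequency), " pixels over ",
      x$n_replicates, " replicates; max frequency ",
      signif(max(x$frequency), 3), "; ", sum(x$binary),
      " pixels survive threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Tuning policy for the simulation study
#'
#' `mode = "cv"` tunes the penalty pair per replicate by a small Q-squared
#' grid search: a 3 x 3 grid of penalties at fractions `lambda_fracs` of the
#' largest absolute entry of the vector each penalty thresholds at the SVD
#' initialisation (`X'Y v0` for `lambda_X`, `Y'X u0` for `lambda_Y`), with
#' `K`-fold cross-validation. `mode = "fixed"` skips cross-validation and
#' uses the fractions `fixed_fracs` directly — a fast mode for smoke runs.
#' When `k_grid` is given, the number of components is selected by Q-squared
#' too (recorded per replicate); the metrics fit always uses `k` components.
#'
#' @param mode `"cv"` or `"fixed"`.
#' @param lambda_fracs Fractions of the initialisation maximum forming each
#'   penalty grid (default `c(0.2, 0.4, 0.6)`; fractions near 1 tend to
#'   annihilate a weight vector once the other block has been sparsified,
#'   because thresholding `v` shrinks the scale of `X'Y v`).
#' @param k Number of components fitted for selection metrics (default 2).
#' @param k_grid Optional candidate numbers of components for Q-squared
#'   selection (e.g. `1:3`); `NULL` keeps `k` fixed.
#' @param K Folds for cross-validation (default 10).
#' @param fixed_fracs Length-2 fractions for `mode = "fixed"`.
#' @return An object of class `study_tuning`.
#' @export
study_tuning <- function(mode = c("cv", "fixed"),
                         lambda_fracs = c(0.2, 0.4, 0.6),
                         k = 2L, k_grid = NULL, K = 10L,
                         fixed_fracs = c(0.4, 0.4)) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, lambda_fracs = lambda_fracs, k = as.integer(k),
         k_grid = if (!is.null(k_grid)) as.integer(k_grid), K = as.integer(K),
         fixed_fracs = fixed_fracs),
    class = "study_tuning"
  )
}

# injective greedy matching of estimated components (rows) to truth
# components (cols) by Jaccard overlap of the pixel selections
match_components <- function(selections, y_support, q) {
  k <- length(selections); g <- length(y_support)
  O <- matrix(0, k, g)
  for (i in seq_len(k)) for (j in seq_len(g)) {
    inter <- sum(selections[[i]][y_support[[j]]])
    uni <- sum(selections[[i]]) + length(y_support[[j]]) - inter
    O[i, j] <- if (uni > 0) inter / uni else 0
  }
  assign <- rep(NA_integer_, g)
  Ow <- O
  for (step in seq_len(min(k, g))) {
    ij <- arrayInd(which.max(Ow), dim(Ow))
    assign[ij[2L]] <- ij[1L]
    Ow[ij[1L], ] <- -Inf
    Ow[, ij[2L]] <- -Inf
  }
  assign
}

#' Run the full variable-selection simulation study
#'
#' For each replicate dataset: simulate, optionally reduce the image block
#' with a radial B-spline basis at each requested knot spacing (spacing 0
#' means no basis — raw pixel responses), tune penalties per the tuning
#' policy, fit the sparse PLS model, derive per-component pixel selections,
#' match estimated components to the two truth components by overlap, and
#' score sensitivity, specificity and c-index for pixels (and for covariate
#' selection against the true X supports). Results are averaged over
#' replicates; per-pixel selection frequencies are accumulated so
#' probability images can be thresholded afterwards.
#'
#' Replicate-level failures (e.g. a penalty annihilating a weight vector in
#' every grid cell) are recorded and skipped, not fatal.
#'
#' @param config A [sim_config()].
#' @param knot_spacings Numeric vector of knot spacings; 0 = no basis
#'   (default `c(0, 2, 4, 8)`).
#' @param tuning A [study_tuning()] policy.
#' @param verbose Print a line per replicate.
#' @return An object of class `sim_study`: `metrics` (tibble of means per
#'   method and component), `replicates` (per-replicate metric rows),
#'   `frequency` (per method: pixels x 2 selection-frequency matrix),
#'   `k_selected` (per-replicate selected component counts, if tuned),
#'   `failures`, plus the inputs.
#' @export
run_simulation_study <- function(config, knot_spacings = c(0, 2, 4, 8),
                                 tuning = study_tuning(),
                                 verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(tuning, "study_tuning"))
  q <- config$truth$q
  domain <- image_domain(config$image_shape)
  bases <- list()
  for (s in knot_spacings)
    if (s > 0)
      bases[[as.character(s)]] <-
        build_basis_matrix(domain, knot_grid(domain, spacing = s))
  method_label <- function(s)
    if (s == 0) "sPLS (no basis)" else paste0("RBF-sPLS h0=", s)
  rep_seeds <- with_preserved_seed(config$seed,
                                   sample.int(2^31 - 2, config$n_datasets))
  counts <- lapply(knot_spacings, function(s) matrix(0, q, 2L))
  names(counts) <- as.character(knot_spacings)
  n_ok <- stats::setNames(integer(length(knot_spacings)),
                          as.character(knot_spacings))
  rep_rows <- list()
  k_rows <- list()
  failures <- list()
  for (r in seq_len(config$n_datasets)) {
    dat <- simulate_dataset(config, seed = rep_seeds[r])
    for (s in knot_spacings) {
      key <- as.character(s)
      res <- tryCatch({
        with_preserved_seed(rep_seeds[r] %% 2146483647L + 1000000L, {
          basis <- if (s > 0) bases[[key]] else NULL
          Yr <- if (s > 0) reduce_images(dat$Y, basis) else dat$Y
          fitinfo <- tune_and_fit(dat$X, Yr, tuning)
          sels <- lapply(seq_len(fitinfo$model$k), function(cc)
            selected_pixels(fitinfo$model, basis = basis, component = cc))
          assign <- match_components(sels, config$truth$y_support, q)
          rows <- lapply(1:2, function(g) {
            sel <- if (is.na(assign[g])) rep(FALSE, q) else sels[[assign[g]]]
            ym <- evaluate_selection(sel, config$truth$Q[, g] == 1)
            u_sel <- if (is.na(assign[g])) rep(FALSE, config$p) else
              fitinfo$model$U[, assign[g]] != 0
            x_truth <- rep(FALSE, config$p)
            x_truth[config$x_support[[g]]] <- TRUE
            xm <- evaluate_selection(u_sel, x_truth)
            tibble::tibble(
              replicate = r, method = method_label(s), knot_spacing = s,
              component = g,
              sensitivity = ym$sensitivity, specificity = ym$specificity,
              c_index = ym$c_index,
              x_sensitivity = xm$sensitivity, x_specificity = xm$specificity,
              x_c_index = xm$c_index,
              lamX = fitinfo$lamX, lamY = fitinfo$lamY)
          })
          list(rows = dplyr::bind_rows(rows),
               sel1 = if (is.na(assign[1L])) rep(FALSE, q) else
                 sels[[assign[1L]]],
               sel2 = if (is.na(assign[2L])) rep(FALSE, q) else
                 sels[[assign[2L]]],
               k_selected = fitinfo$k_selected)
        })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(replicate = r, method = method_label(s),
                         knot_spacing = s, message = conditionMessage(res))
        next
      }
      rep_rows[[length(rep_rows) + 1L]] <- res$rows
      counts[[key]][, 1L] <- counts[[key]][, 1L] + res$sel1
      counts[[key]][, 2L] <- counts[[key]][, 2L] + res$sel2
      n_ok[key] <- n_ok[key] + 1L
      if (!is.null(res$k_selected))
        k_rows[[length(k_rows) + 1L]] <-
          tibble::tibble(replicate = r, method = method_label(s),
                         knot_spacing = s, k_selected = res$k_selected)
    }
    if (verbose)
      message("replicate ", r, "/", config$n_datasets, " done")
  }
  replicates <- dplyr::bind_rows(rep_rows)
  if (nrow(replicates) == 0L)
    stop("every replicate-method run failed; first failure: ",
         if (length(failures)) failures[[1L]]$message else "unknown")
  metrics <- dplyr::summarise(
    dplyr::group_by(replicates, .data$method, .data$knot_spacing,
                    .data$component),
    dplyr::across(c("sensitivity", "specificity", "c_index",
                    "x_sensitivity", "x_specificity", "x_c_index"),
                  mean),
    n_replicates = dplyr::n(), .groups = "drop")
  metrics <- dplyr::arrange(metrics, .data$knot_spacing, .data$component)
  frequency <- lapply(stats::setNames(as.character(knot_spacings),
                                      as.character(knot_spacings)),
                      function(key) {
                        if (n_ok[key] > 0) counts[[key]] / n_ok[key]
                        else counts[[key]]
                      })
  structure(
    list(metrics = metrics, replicates = replicates, frequency = frequency,
         k_selected = dplyr::bind_rows(k_rows),
         failures = dplyr::bind_rows(failures),
         config = config, tuning = tuning, knot_spacings = knot_spacings),
    class = "sim_study"
  )
}

# tune penalties (and optionally k) per the study policy, then fit the
# metrics model with tuning$k components
tune_and_fit <- function(X, Y, tuning) {
  Xc <- sweep(X, 2L, colMeans(X), "-")
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  init <- init_singular_pair(Xc, Yc)
  mx <- max(abs(drop(init$M %*% init$v)))
  my <- max(abs(drop(crossprod(init$M, init$u))))
  k_selected <- NULL
  if (tuning$mode == "fixed") {
    lamX <- tuning$fixed_fracs[1L] * mx
    lamY <- tuning$fixed_fracs[2L] * my
  } else {
    k_grid <- if (is.null(tuning$k_grid)) tuning$k else tuning$k_grid
    gs <- grid_search(X, Y,
                      lamX_grid = tuning$lambda_fracs * mx,
                      lamY_grid = tuning$lambda_fracs * my,
                      k_max = max(k_grid), k_grid = k_grid,
                      K = tuning$K)
    lamX <- gs$best$lamX; lamY <- gs$best$lamY
    if (!is.null(tuning$k_grid)) k_selected <- gs$best$k
  }
  model <- fit_spls(X, Y, lamX = lamX, lamY = lamY, k = tuning$k)
  list(model = model, lamX = lamX, lamY = lamY, k_selected = k_selected)
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulation study: n =", x$config$n, ", p =", x$config$p, ",",
      x$config$n_datasets, "datasets\n")
  print(x$metrics, n = Inf)
  if (nrow(x$failures))
    cat("failures:", nrow(x$failures), "replicate-method runs\n")
  invisible(x)
}

#' Export a study metrics table as delimited text
#'
#' @param x A [run_simulation_study()] result.
#' @param path Output file; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
export_metrics_table <- function(x, path) {
  stopifnot(inherits(x, "sim_study"))
  utils::write.table(x$metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
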