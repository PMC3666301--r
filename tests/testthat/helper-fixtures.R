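# Shared fixtures and a cross-file cache for the expensive simulation runs.
# Helpers are sourced once per session, so results computed lazily here are
# reused by every test file that needs them.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache, inherits = FALSE))
    assign(key, force(expr), envir = .study_cache)
  get(key, envir = .study_cache, inherits = FALSE)
}

# small correlated two-block dataset with a planted rank-2 structure
make_toy_blocks <- function(n = 12, p = 5, q = 7, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  list(X = X, Y = Y,
       Xc = scale(X, scale = FALSE), Yc = scale(Y, scale = FALSE))
}

# tiny image-study configuration that runs in well under a second per
# replicate (20 x 20 image, thin crosses)
tiny_sim_config <- function(n = 30, p = 20, n_datasets = 2, seed = 5) {
  sim_config(
    n = n, p = p, image_shape = c(20L, 20L),
    truth = make_true_images(c(20L, 20L),
                             centers = list(c(5, 5), c(15, 15)),
                             arm = 3L, width = 1L),
    n_datasets = n_datasets, seed = seed)
}

# study-scale runs shared between acceptance tests (30 replicates at the
# generator's stated n, p and 100 x 100 images)
study_n50_p40 <- function() cached("study_n50_p40", {
  cfg <- sim_config(n = 50, p = 40, n_datasets = 30, seed = 20240915)
  run_simulation_study(cfg, knot_spacings = c(0, 2, 4, 8),
                       tuning = study_tuning())
})

study_n100_p40 <- function() cached("study_n100_p40", {
  cfg <- sim_config(n = 100, p = 40, n_datasets = 30, seed = 20240916)
  run_simulation_study(cfg, knot_spacings = c(2, 8),
                       tuning = study_tuning())
})
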