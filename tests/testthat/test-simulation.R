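test_that("Kronecker loadings place b-blocks at the documented positions", {
  out <- make_loading_P(40)
  expect_equal(out$x_support[[1]], c(1, 2, 9, 10, 17, 18, 25, 26, 33, 34))
  expect_equal(out$x_support[[2]], c(3, 4, 11, 12, 19, 20, 27, 28, 35, 36))
  expect_equal(out$P[out$x_support[[1]], 1],
               c(5, 5, 2, 2, 1, 1, -2, -2, -5, -5))
  expect_equal(out$P[out$x_support[[2]], 2],
               c(5, 5, 2, 2, 1, 1, -2, -2, -5, -5))
  # supports are disjoint
  expect_length(intersect(out$x_support[[1]], out$x_support[[2]]), 0)
  # p = 20: blocks of length 1, supports of size 5
  out20 <- make_loading_P(20)
  expect_length(out20$x_support[[1]], 5)
  expect_equal(out20$x_support[[1]], c(1, 5, 9, 13, 17))
  expect_error(make_loading_P(30), "divisible by 20")
})

test_that("cross pixel counts follow the inclusion-exclusion formula", {
  for (geom in list(c(3, 1), c(5, 3), c(15, 5))) {
    a <- geom[1]; w <- geom[2]
    img <- cross_image(c(50, 50), c(25, 25), arm = a, width = w)
    expect_equal(sum(img), 2 * w * (2 * a + w) - w^2)
  }
  # enumerate a tiny cross by hand: arm 1, width 1 -> 5 pixels in a plus
  img <- cross_image(c(7, 7), c(4, 4), arm = 1, width = 1)
  # pixels (4,3),(3,4),(4,4),(5,4),(4,5); flat index x + (y-1)*7
  expect_equal(which(img == 1), c(18L, 24L, 25L, 26L, 32L))
  expect_error(cross_image(c(10, 10), c(5, 5), arm = 1, width = 2), "odd")
})

test_that("default truth images are disjoint 325-pixel crosses at q = 10000", {
  tr <- make_true_images()
  expect_equal(tr$q, 10000)
  expect_equal(lengths(tr$y_support), c(325L, 325L))
  expect_length(intersect(tr$y_support[[1]], tr$y_support[[2]]), 0)
  expect_true(all(tr$Q %in% c(0, 1)))
  # custom images must be binary with nonempty support
  expect_error(make_true_images(c(10, 10),
                                images = list(matrix(0, 10, 10),
                                              matrix(1, 10, 10))),
               "nonempty")
  expect_error(make_true_images(c(10, 10),
                                images = list(matrix(0.5, 10, 10),
                                              matrix(1, 10, 10))),
               "binary")
  # overlapping crosses rejected when disjointness is requested
  expect_error(make_true_images(c(30, 30),
                                centers = list(c(15, 15), c(16, 16)),
                                arm = 3, width = 1),
               "overlap")
})

test_that("the generator honours its moment structure", {
  cfg <- tiny_sim_config(n = 2000, n_datasets = 1)
  dat <- simulate_dataset(cfg, seed = 1)
  expect_equal(dim(dat$X), c(2000, 20))
  expect_equal(dim(dat$Y), c(2000, 400))
  # column means shrink like 3 sigma / sqrt(n)
  expect_true(all(abs(colMeans(dat$X)) < 3 / sqrt(2000)))
  # noiseless responses are exactly X P Q' (rank <= 2)
  nd <- simulate_dataset(cfg, seed = 2, noise = FALSE)
  expect_equal(nd$Y, nd$X %*% cfg$P %*% t(cfg$truth$Q))
  expect_lte(qr(nd$Y)$rank, 2)
  # identical seeds give identical draws
  expect_identical(simulate_dataset(cfg, seed = 3)$Y,
                   simulate_dataset(cfg, seed = 3)$Y)
})

test_that("sample covariance approaches Sigma for the AR(1) option", {
  cfg <- sim_config(n = 5000, p = 20, image_shape = c(10, 10),
                    truth = make_true_images(c(10, 10),
                                             centers = list(c(3, 3),
                                                            c(8, 8)),
                                             arm = 1, width = 1),
                    Sigma = list(family = "ar1", rho = 0.5),
                    n_datasets = 1, seed = 1)
  dat <- simulate_dataset(cfg, seed = 4)
  emp <- cov(dat$X)
  expect_lt(max(abs(emp - cfg$Sigma)), 0.12)
})

test_that("pixel selection logic distinguishes raw and basis variants", {
  toy <- make_toy_blocks(n = 20, p = 4, q = 6, seed = 5)
  m <- fit_spls(toy$X, toy$Y, lamX = 0.1, lamY = 2, k = 1)
  sel <- selected_pixels(m, component = 1)
  expect_equal(sum(sel), sum(m$V[, 1] != 0))
  expect_error(selected_pixels(m, component = 2), "1..1")
  # basis variant: one selected knot selects exactly its support disc
  dom <- image_domain(c(20, 20))
  g <- knot_grid(dom, 4)
  B <- build_basis_matrix(dom, g)
  fake <- m
  fake$k <- 1L
  fake$V <- matrix(0, g$n_knots, 1)
  fake$V[10, 1] <- 1
  sel_b <- selected_pixels(fake, basis = B, component = 1)
  d <- sqrt(rowSums(sweep(dom$points, 2, g$knots[10, ])^2))
  expect_setequal(which(sel_b), which(d < 2 * g$bandwidth))
  # zero weights select nothing
  fake$V[10, 1] <- 0
  expect_equal(sum(selected_pixels(fake, basis = B, component = 1)), 0)
})

test_that("selection metrics satisfy their identities", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 30))
  perfect <- evaluate_selection(truth, truth)
  expect_equal(unlist(perfect),
               c(sensitivity = 1, specificity = 1, c_index = 1))
  everything <- evaluate_selection(rep(TRUE, 40), truth)
  expect_equal(unlist(everything),
               c(sensitivity = 1, specificity = 0, c_index = 0))
  nothing <- evaluate_selection(rep(FALSE, 40), truth)
  expect_equal(unlist(nothing),
               c(sensitivity = 0, specificity = 1, c_index = 0))
  # c-index identity on random selections
  set.seed(6)
  for (i in 1:20) {
    sel <- runif(40) > 0.5
    m <- evaluate_selection(sel, truth)
    expect_equal(m$c_index, m$sensitivity + m$specificity - 1)
    expect_true(m$sensitivity >= 0 && m$sensitivity <= 1)
    expect_true(m$specificity >= 0 && m$specificity <= 1)
  }
  expect_error(evaluate_selection(truth, rep(FALSE, 40)), "empty")
})

test_that("probability images average indicators and threshold at >=", {
  sels <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  pi1 <- probability_image(sels, threshold = 0.95)
  expect_equal(pi1$frequency, c(1, 0.5, 0))
  expect_equal(pi1$binary, c(TRUE, FALSE, FALSE))
  # identical selections: frequencies in {0, 1}, binarization recovers them
  same <- probability_image(list(sels[[1]], sels[[1]]), threshold = 0.95)
  expect_true(all(same$frequency %in% c(0, 1)))
  expect_equal(same$binary, sels[[1]])
  # 94 of 100 falls below the 0.95 threshold
  m <- matrix(rep(c(rep(1, 94), rep(0, 6)), 1), ncol = 1)
  expect_false(probability_image(m, 0.95)$binary[1])
  m95 <- matrix(rep(c(rep(1, 95), rep(0, 5)), 1), ncol = 1)
  expect_true(probability_image(m95, 0.95)$binary[1])
  # doubling replicates leaves frequencies unchanged
  expect_equal(probability_image(rbind(m, m))$frequency,
               probability_image(m)$frequency)
  expect_error(probability_image(list(c(TRUE), c(TRUE, FALSE))),
               "differing lengths")
})

test_that("a one-replicate study run emits a well-formed metrics table", {
  cfg <- tiny_sim_config(n_datasets = 1)
  st <- run_simulation_study(cfg, knot_spacings = c(0, 2),
                             tuning = study_tuning(mode = "cv", K = 5))
  expect_s3_class(st$metrics, "tbl_df")
  expect_equal(nrow(st$metrics), 4)   # 2 methods x 2 components
  expect_true(all(c("method", "knot_spacing", "component", "sensitivity",
                    "specificity", "c_index", "n_replicates")
                  %in% names(st$metrics)))
  expect_true(all(st$metrics$c_index >= -1 & st$metrics$c_index <= 1))
  # c-index identity holds row by row
  expect_equal(st$metrics$c_index,
               st$metrics$sensitivity + st$metrics$specificity - 1)
  # frequency matrices have one column per truth component
  expect_equal(dim(st$frequency[["0"]]), c(cfg$truth$q, 2))
  expect_true(all(unlist(st$frequency) >= 0 & unlist(st$frequency) <= 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_metrics_table(st, path)
  expect_true(file.exists(path))
  # reruns with the same master seed reproduce the metrics exactly
  st2 <- run_simulation_study(cfg, knot_spacings = c(0, 2),
                              tuning = study_tuning(mode = "cv", K = 5))
  expect_equal(st$metrics, st2$metrics)
})

test_that("component matching absorbs order swaps", {
  q <- 100
  y_support <- list(1:10, 51:60)
  sel_swapped <- list(replace(rep(FALSE, q), 51:60, TRUE),
                      replace(rep(FALSE, q), 1:10, TRUE))
  assign <- rbfspls:::match_components(sel_swapped, y_support, q)
  expect_equal(assign, c(2L, 1L))
  sel_id <- rev(sel_swapped)
  expect_equal(rbfspls:::match_components(sel_id, y_support, q), c(1L, 2L))
})
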