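test_that("subset R-squared matches worked and degenerate cases", {
  set.seed(401)
  a <- rnorm(60); b <- rnorm(60); c <- rnorm(60)
  # y exactly equal to one predictor
  r2 <- fit_subset_r2(a, a, b, c)
  expect_equal(r2[["a"]], 1, tolerance = 1e-12)
  expect_equal(r2[["abc"]], 1, tolerance = 1e-12)
  # y independent of all predictors at large n: all R2 small
  y_ind <- rnorm(2000)
  r2i <- fit_subset_r2(y_ind, rnorm(2000), rnorm(2000), rnorm(2000))
  expect_true(all(r2i < 0.02))
  # collinear design flagged, R2 still computed
  expect_warning(r2c <- fit_subset_r2(a, b, b, c), "collinear")
  expect_equal(r2c[["ab"]], r2c[["a"]], tolerance = 1e-12)
})

test_that("subset R-squared equals the normal-equations oracle", {
  for (case in 1:30) {
    set.seed(420 + case)
    n <- 50
    X <- matrix(rnorm(n * 3), n, 3)
    y <- X %*% rnorm(3) + rnorm(n)
    got <- fit_subset_r2(y, X[, 1], X[, 2], X[, 3])
    subsets <- list(a = 1, b = 2, c = 3, ab = c(1, 2), ac = c(1, 3),
                    bc = c(2, 3), abc = 1:3)
    for (s in names(subsets)) {
      expect_equal(got[[s]], oracle_subset_r2(y, X[, subsets[[s]],
                                                  drop = FALSE]),
                   tolerance = 1e-10)
    }
  }
})

test_that("adding a predictor never decreases R-squared", {
  for (case in 1:20) {
    set.seed(440 + case)
    X <- matrix(rnorm(120), 40, 3)
    y <- rnorm(40)
    r2 <- fit_subset_r2(y, X[, 1], X[, 2], X[, 3])
    expect_gte(r2[["ab"]], r2[["a"]] - 1e-12)
    expect_gte(r2[["ab"]], r2[["b"]] - 1e-12)
    expect_gte(r2[["abc"]], max(r2[c("ab", "ac", "bc")]) - 1e-12)
  }
})

test_that("variance partition reproduces exact population cases", {
  # orthogonal +-1 contrasts: y = a + b, c orthogonal to everything
  a <- rep(c(1, -1), 50)
  b <- rep(c(1, 1, -1, -1), 25)
  cc <- rep(c(1, -1, -1, 1), 25)
  y <- a + b
  part <- partition_variance(fit_subset_r2(y, a, b, cc))
  expect_equal(part$components[["U_a"]], 0.5, tolerance = 1e-10)
  expect_equal(part$components[["U_b"]], 0.5, tolerance = 1e-10)
  expect_equal(part$components[["U_c"]], 0, tolerance = 1e-10)
  expect_equal(part$components[["C_ab"]], 0, tolerance = 1e-10)
  expect_equal(part$components[["C_abc"]], 0, tolerance = 1e-10)
  expect_equal(part$r2_full, 1, tolerance = 1e-10)
  # duplicated predictor: all variance is common to the pair
  suppressWarnings(part2 <- partition_variance(fit_subset_r2(a, a, a, cc)))
  expect_equal(part2$components[["U_a"]], 0, tolerance = 1e-10)
  expect_equal(part2$components[["U_b"]], 0, tolerance = 1e-10)
  expect_equal(part2$components[["C_ab"]], 1, tolerance = 1e-10)
})

test_that("the seven components always sum to the full-model R-squared", {
  for (case in 1:200) {
    set.seed(500 + case)
    X <- matrix(rnorm(90), 30, 3)
    y <- X %*% rnorm(3) + rnorm(30, sd = runif(1, 0.1, 3))
    part <- partition_variance(fit_subset_r2(y, X[, 1], X[, 2], X[, 3]))
    expect_equal(sum(part$components), part$r2_full, tolerance = 1e-10)
  }
})

test_that("commonality on RDMs assigns unique variance to the generator", {
  cfg <- generator_config(seed = 31, n_participants = 8, n_voxels = 150,
                          pattern_noise_sd = 0.3)
  truth <- make_truth_rdm(cfg)
  rdms <- lapply(simulate_subject_patterns(truth, cfg),
                 correlation_distance_rdm)
  d <- cfg$design
  set.seed(32)
  noise_model <- rdm(random_rdm_matrix(48, d$stimulus_id), source = "model")
  res <- commonality_analysis(rdms, list(make_type_model_rdm(d),
                                         make_shape_model_rdm(d),
                                         noise_model))
  expect_gt(res$r2_full, 0.5)
  expect_equal(which.max(res$components[c("U_a", "U_b", "U_c")]),
               c(U_a = 1L))
  expect_equal(sum(res$components), res$r2_full, tolerance = 1e-10)
})

test_that("permutation test detects signal and respects conventions", {
  cfg <- generator_config(seed = 61, n_participants = 6, n_voxels = 120,
                          pattern_noise_sd = 0.3)
  truth <- make_truth_rdm(cfg)
  rdms <- lapply(simulate_subject_patterns(truth, cfg),
                 correlation_distance_rdm)
  d <- cfg$design
  set.seed(62)
  preds <- list(make_type_model_rdm(d), make_shape_model_rdm(d),
                rdm(random_rdm_matrix(48, d$stimulus_id), source = "model"))
  res <- permutation_test_full_model(rdms, preds, n_perm = 200, seed = 63)
  expect_equal(res$p, 0)
  expect_match(res$p_label, "^< ")
  expect_length(res$null_r2, 200)
  expect_error(permutation_test_full_model(rdms, preds, n_perm = 0),
               "at least 1")
  expect_warning(permutation_test_full_model(rdms, preds, n_perm = 50,
                                             seed = 1), "coarse")
})

test_that("permutation p is invariant to affine rescaling of the RDMs", {
  set.seed(71)
  rdms <- lapply(1:5, function(i) rdm(random_rdm_matrix(12)))
  preds <- lapply(1:3, function(i) rdm(random_rdm_matrix(12),
                                       source = "model"))
  p1 <- permutation_test_full_model(rdms, preds, n_perm = 100, seed = 5)
  scaled <- lapply(rdms, function(r) {
    m <- 3 * as.matrix(r) + 2
    diag(m) <- 0
    rdm(m)
  })
  p2 <- suppressWarnings(
    permutation_test_full_model(scaled, preds, n_perm = 100, seed = 5))
  expect_equal(p2$p, p1$p)
})

test_that("the row-shuffle scheme permutes within triangular rows only", {
  n <- 6
  m <- matrix(0, n, n)
  for (i in 2:n) for (j in seq_len(i - 1)) m[i, j] <- i + j / 10
  m <- m + t(m)
  v <- lower_triangle_vector(m)
  idx <- tripletrsa:::lower_tri_row_index(n)
  set.seed(9)
  shuffled <- tripletrsa:::shuffle_lower_rows(v, idx)
  # each row's multiset of values is preserved
  for (r in seq_along(idx$lengths)) {
    span <- idx$starts[r]:(idx$starts[r] + idx$lengths[r] - 1)
    expect_setequal(shuffled[span], v[span])
    expect_equal(floor(shuffled[span]), floor(v[span]))  # stays in its row
  }
})
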