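test_that("rdm constructor enforces symmetry, diagonal, and ids", {
  m <- random_rdm_matrix(4)
  r <- rdm(m, source = "model")
  expect_s3_class(r, "rdm")
  expect_equal(attr(r, "source"), "model")
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(rdm(bad), "symmetric")
  expect_error(rdm(m[, 1:3]), "square")
  expect_error(rdm(m, ids = c("a", "a", "b", "c")), "unique")
})

test_that("correlation-distance RDM matches a brute-force Pearson loop", {
  set.seed(3)
  pat <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  got <- as.matrix(correlation_distance_rdm(pat))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(got[i, j], 1 - cor(pat[i, ], pat[j, ]),
                 tolerance = 1e-12)
  }
  # identical rows at distance 0; sign-flipped centered rows at 2
  x <- rnorm(10); x <- x - mean(x)
  p2 <- rbind(a = x, b = x, c = -x)
  g2 <- as.matrix(correlation_distance_rdm(p2))
  expect_equal(g2["a", "b"], 0, tolerance = 1e-12)
  expect_equal(g2["a", "c"], 2, tolerance = 1e-12)
  # constant row flagged as NA
  expect_warning(g3 <- correlation_distance_rdm(rbind(a = x, k = rep(1, 10))),
                 "constant")
  expect_true(is.na(as.matrix(g3)["a", "k"]))
})

test_that("correlation distance is invariant to per-stimulus affine scaling", {
  set.seed(4)
  pat <- matrix(rnorm(60), 6, 10)
  scaled <- sweep(sweep(pat, 1, runif(6, 0.5, 3), `*`), 1,
                  rnorm(6), `+`)
  expect_equal(as.matrix(correlation_distance_rdm(pat)),
               unname(as.matrix(correlation_distance_rdm(scaled))),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("lower-triangle vectorization is row-major and invertible", {
  m <- matrix(0, 4, 4)
  for (i in 2:4) for (j in seq_len(i - 1)) m[i, j] <- 10 * i + j
  m <- m + t(m)
  expect_equal(lower_triangle_vector(m), c(21, 31, 32, 41, 42, 43))
  expect_length(lower_triangle_vector(random_rdm_matrix(48)), 1128)
  # transposed input gives the identical vector for symmetric matrices
  expect_equal(lower_triangle_vector(t(m)), lower_triangle_vector(m))
})

test_that("compare_rdms is a Spearman on lower triangles", {
  m <- random_rdm_matrix(6)
  r <- rdm(m)
  expect_equal(compare_rdms(r, r)$rho, 1)
  # rank-reversed copy
  v <- lower_triangle_vector(m)
  rev_m <- max(v) - m
  diag(rev_m) <- 0
  expect_equal(compare_rdms(r, rdm(rev_m))$rho, -1)
  # equals textbook Spearman on the two vectors
  m2 <- random_rdm_matrix(6)
  expect_equal(compare_rdms(r, rdm(m2))$rho,
               cor(rank(lower_triangle_vector(m)),
                   rank(lower_triangle_vector(m2))))
  # invariant under strictly increasing transforms
  expect_equal(compare_rdms(rdm(exp(m) - diag(diag(exp(m)))), rdm(m2))$rho,
               compare_rdms(r, rdm(m2))$rho)
  expect_error(compare_rdms(r, rdm(random_rdm_matrix(5))), "dimensions")
})

test_that("noise ceiling spans identical, noisy, and independent RDMs", {
  base <- random_rdm_matrix(8)
  idr <- lapply(1:5, function(i) rdm(base))
  expect_equal(noise_ceiling(idr)$ceiling, 1)
  set.seed(6)
  noisy <- lapply(1:8, function(i) {
    nz <- random_rdm_matrix(8) * 0.05
    rdm(base + nz)
  })
  expect_gt(noise_ceiling(noisy)$ceiling, 0.95)
  indep <- lapply(1:20, function(i) rdm(random_rdm_matrix(8)))
  expect_lt(abs(noise_ceiling(indep)$ceiling), 0.25)
  expect_error(noise_ceiling(idr[1]), ">= 2")
})

test_that("noise ceiling rises with signal-to-noise", {
  base <- random_rdm_matrix(10)
  ceil_at <- function(noise_sd, rep) {
    set.seed(700 + rep)
    rdms <- lapply(1:6, function(i) rdm(base + random_rdm_matrix(10) * noise_sd))
    noise_ceiling(rdms)$ceiling
  }
  grid <- c(1.5, 0.5, 0.1)
  means <- vapply(grid, function(s) {
    mean(vapply(1:20, function(r) ceil_at(s, r), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("group averaging is the missing-aware entrywise mean", {
  a <- random_rdm_matrix(5)
  b <- random_rdm_matrix(5)
  got <- as.matrix(group_average_rdm(list(rdm(a), rdm(b))))
  expect_equal(got, (a + b) / 2, ignore_attr = TRUE)
  # identical inputs returned unchanged; 0/1 inputs average to 0.5
  expect_equal(as.matrix(group_average_rdm(list(rdm(a), rdm(a)))), a,
               ignore_attr = TRUE)
  ones <- matrix(1, 5, 5) - diag(5)
  half <- as.matrix(group_average_rdm(list(rdm(ones * 0), rdm(ones))))
  expect_equal(half[lower.tri(half)], rep(0.5, 10))
  # missing-aware: an entry defined for one participant uses that one
  miss <- a; miss[2, 1] <- miss[1, 2] <- NA
  got2 <- as.matrix(group_average_rdm(list(rdm(miss), rdm(b))))
  expect_equal(got2[2, 1], b[2, 1])
  both <- b; both[2, 1] <- both[1, 2] <- NA
  expect_error(group_average_rdm(list(rdm(miss), rdm(both))),
               "missing for all")
})

test_that("MDS embeds exact configurations at ~zero stress", {
  tri <- matrix(1, 3, 3) - diag(3)
  fit <- mds_embed(rdm(tri), seed = 1)
  expect_lt(fit$stress, 1e-4)
  d12 <- dist(fit$coordinates)
  expect_lt(diff(range(d12)) / mean(d12), 1e-3)  # equilateral
  # generate-and-recover from planar coordinates
  set.seed(11)
  xy <- matrix(rnorm(20), 10, 2)
  dd <- as.matrix(dist(xy))
  fit2 <- mds_embed(rdm(dd), seed = 2)
  expect_lt(fit2$stress, 1e-3)
  pr <- vegan::procrustes(xy, fit2$coordinates, symmetric = TRUE)
  expect_lt(pr$ss, 1e-3)
  # genuinely 3-D distances cannot reach zero stress in the plane
  set.seed(12)
  xyz <- matrix(rnorm(30), 10, 3)
  d3 <- as.matrix(dist(xyz))
  fit3 <- mds_embed(rdm(d3), dims = 2, seed = 3)
  expect_gt(fit3$stress, 0.01)
  expect_lt(mds_embed(rdm(d3), dims = 3, seed = 3)$stress, 1e-3)
})

test_that("RDMs round-trip through square TSV with NA entries", {
  m <- random_rdm_matrix(5, ids = letters[1:5])
  m[2, 1] <- m[1, 2] <- NA
  r <- rdm(m, source = "behavioral")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rdm(r, f)
  r2 <- read_rdm(f)
  expect_equal(as.matrix(r2), as.matrix(r), tolerance = 1e-12)
  expect_true(is.na(as.matrix(r2)[2, 1]))
})

test_that("feature TSVs become 1 - r layer RDMs", {
  set.seed(13)
  feat <- matrix(rnorm(50), 5, 10)
  df <- data.frame(stimulus_id = paste0("s", 1:5), feat)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- rdm_from_features(f)
  expect_equal(attr(r, "source"), "feature")
  expect_equal(as.matrix(r)[1, 2], 1 - cor(feat[1, ], feat[2, ]),
               tolerance = 1e-10)
})
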