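#' All-subsets R-squared for three predictors
#'
#' Fits ordinary least squares with an intercept for every nonempty subset
#' of the three predictors and returns the coefficient of determination of
#' each fit. These seven values feed the commonality (variance-partitioning)
#' weighting identities. A collinear full design is flagged with a warning;
#' R-squared is still computed from the rank-reduced least-squares fit.
#'
#' @param y Dependent dissimilarity vector (length >= 5).
#' @param a,b,c Predictor vectors, same length as `y`.
#' @return Named numeric vector with elements `a`, `b`, `c`, `ab`, `ac`,
#'   `bc`, `abc`.
#' @export
fit_subset_r2 <- function(y, a, b, c) {
  n <- length(y)
  stopifnot(length(a) == n, length(b) == n, length(c) == n, n >= 5)
  X <- cbind(a = a, b = b, c = c)
  if (all(apply(X, 2, stats::sd) == 0)) stop("all predictors constant")
  full <- cbind(1, X)
  if (qr(full)$rank < ncol(full)) {
    warning("collinear full design; R-squared from rank-reduced fit")
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("dependent variable is constant")
  r2_of <- function(cols) {
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sst
  }
  subsets <- list(a = "a", b = "b", c = "c", ab = c("a", "b"),
                  ac = c("a", "c"), bc = c("b", "c"),
                  abc = c("a", "b", "c"))
  vapply(subsets, r2_of, numeric(1))
}

#' Commonality partition of the full-model R-squared
#'
#' Decomposes the three-predictor R-squared into seven signed components
#' via the standard weighting identities: the unique contributions
#' `U(a) = R2_abc - R2_bc` (and cyclically for b, c), the pairwise commons
#' `C(ab) = R2_ac + R2_bc - R2_c - R2_abc` (and cyclically), and the
#' three-way common
#' `C(abc) = R2_a + R2_b + R2_c - R2_ab - R2_ac - R2_bc + R2_abc`.
#' Negative commonalities are legal (suppression) and reported as-is. The
#' seven components always sum to the full-model R-squared.
#'
#' @param r2 Named vector from [fit_subset_r2()].
#' @return List of class `commonality_result` with `r2_full`, `components`
#'   (named vector `U_a, U_b, U_c, C_ab, C_ac, C_bc, C_abc`), and
#'   `percent_of_explained` (components as a share of `r2_full`).
#' @export
partition_variance <- function(r2) {
  need <- c("a", "b", "c", "ab", "ac", "bc", "abc")
  if (!all(need %in% names(r2))) {
    stop("r2 must name: ", paste(need, collapse = ", "))
  }
  comp <- c(
    U_a = r2[["abc"]] - r2[["bc"]],
    U_b = r2[["abc"]] - r2[["ac"]],
    U_c = r2[["abc"]] - r2[["ab"]],
    C_ab = r2[["ac"]] + r2[["bc"]] - r2[["c"]] - r2[["abc"]],
    C_ac = r2[["ab"]] + r2[["bc"]] - r2[["b"]] - r2[["abc"]],
    C_bc = r2[["ab"]] + r2[["ac"]] - r2[["a"]] - r2[["abc"]],
    C_abc = r2[["a"]] + r2[["b"]] + r2[["c"]] -
      r2[["ab"]] - r2[["ac"]] - r2[["bc"]] + r2[["abc"]]
  )
  structure(list(r2_full = r2[["abc"]], components = comp,
                 percent_of_explained = if (r2[["abc"]] > 0) {
                   100 * comp / r2[["abc"]]
                 } else rep(NA_real_, 7)),
            class = "commonality_result")
}

#' @export
print.commonality_result <- function(x, ...) {
  cat(sprintf("<commonality> full-model R2 = %.4f\n", x$r2_full))
  print(round(x$components, 4))
  invisible(x)
}

#' Commonality analysis of a group-averaged RDM
#'
#' Regresses the group-averaged lower-triangle dissimilarities on three
#' predictor RDMs' lower triangles and partitions the full-model R-squared
#' into unique and common components.
#'
#' @param participant_rdms List of per-participant RDMs (aligned ids); a
#'   single RDM is treated as an already-averaged group RDM.
#' @param predictors List of exactly 3 predictor RDMs (model, behavioral, or
#'   feature), aligned with the participants' RDMs.
#' @return A `commonality_result` (see [partition_variance()]) with the
#'   subset R-squared vector attached as `r2_subsets`.
#' @export
commonality_analysis <- function(participant_rdms, predictors) {
  if (length(predictors) != 3) stop("exactly 3 predictor RDMs required")
  if (is_rdm(participant_rdms) || is.matrix(participant_rdms)) {
    participant_rdms <- list(participant_rdms)
  }
  avg <- if (length(participant_rdms) == 1) {
    as.matrix(participant_rdms[[1]])
  } else as.matrix(group_average_rdm(participant_rdms))
  y <- lower_triangle_vector(avg)
  pv <- lapply(predictors, lower_triangle_vector)
  ok <- is.finite(y) & Reduce(`&`, lapply(pv, is.finite))
  r2 <- fit_subset_r2(y[ok], pv[[1]][ok], pv[[2]][ok], pv[[3]][ok])
  out <- partition_variance(r2)
  out$r2_subsets <- r2
  out
}

## Independently permute each row of the row-major strictly-lower-triangular
## vectorization of an n x n RDM (row i contributes entries d(i, 1..i-1)).
shuffle_lower_rows <- function(v, idx) {
  out <- v
  for (r in seq_along(idx$lengths)) {
    len <- idx$lengths[r]
    if (len > 1) {
      s <- idx$starts[r]
      span <- s:(s + len - 1)
      out[span] <- v[span[sample.int(len)]]
    }
  }
  out
}

#' Permutation test of the full commonality model
#'
#' Observed statistic: the three-predictor R-squared of the group-averaged
#' lower-triangle dissimilarities. Null distribution: for each participant,
#' the rows of the strictly-lower-triangular part of their RDM are
#' independently shuffled, the shuffled vectors are averaged across
#' participants, and the full model is refit; this is repeated `n_perm`
#' times. The p-value is the proportion of null R-squared values exceeding
#' the observed one, reported as `< 1/n_perm` when no null value does.
#'
#' @param participant_rdms List of per-participant RDMs.
#' @param predictors List of 3 predictor RDMs.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @param scheme `"row"` (default, per-row shuffles of the triangular
#'   array) or `"vector"` (whole lower-triangle permutation), the latter
#'   for sensitivity analysis.
#' @return List with `observed_r2`, `p` (numeric, `count / n_perm`),
#'   `p_label` (string, `"<1/n_perm"` when count is zero), `n_perm`, and
#'   `null_r2` (the null distribution).
#' @export
permutation_test_full_model <- function(participant_rdms, predictors,
                                        n_perm = 1000, seed = 1,
                                        scheme = c("row", "vector")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  if (length(predictors) != 3) stop("exactly 3 predictor RDMs required")
  if (is_rdm(participant_rdms) || is.matrix(participant_rdms)) {
    participant_rdms <- list(participant_rdms)
  }
  if (length(participant_rdms) < 2) {
    stop("permutation test needs >= 2 participants")
  }
  n <- nrow(as.matrix(participant_rdms[[1]]))
  vecs <- vapply(participant_rdms, lower_triangle_vector,
                 numeric(n * (n - 1) / 2))
  pv <- lapply(predictors, lower_triangle_vector)
  X <- cbind(1, pv[[1]], pv[[2]], pv[[3]])
  r2_fast <- function(y) {
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  obs <- r2_fast(rowMeans(vecs))
  idx <- lower_tri_row_index(n)
  null_r2 <- local_seed(seed, vapply(seq_len(n_perm), function(p) {
    shuf <- apply(vecs, 2, function(v) {
      if (scheme == "row") shuffle_lower_rows(v, idx)
      else v[sample.int(length(v))]
    })
    r2_fast(rowMeans(shuf))
  }, numeric(1)))
  count <- sum(null_r2 > obs)
  list(observed_r2 = obs,
       p = count / n_perm,
       p_label = if (count == 0) sprintf("< %g", 1 / n_perm)
         else sprintf("%g", count / n_perm),
       n_perm = n_perm,
       null_r2 = null_r2)
}
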