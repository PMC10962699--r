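#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric numeric matrix of pairwise dissimilarities among
#' stimulus conditions with a zero diagonal. Entries may be `NA` where a
#' dissimilarity is undefined (e.g. a stimulus pair that never co-occurred in
#' a triplet experiment). Stimulus identifiers are carried in the dimnames,
#' and provenance (`source`, `distance_name`) in attributes.
#'
#' @param values Square numeric matrix, symmetric with zero diagonal
#'   (`NA` allowed off-diagonal).
#' @param ids Character vector of stimulus identifiers; defaults to existing
#'   rownames or `s1..sn`.
#' @param source One of `"behavioral"`, `"neural"`, `"model"`, `"feature"`.
#' @param distance_name Free-text name of the dissimilarity measure.
#' @return An object of class `rdm` (a matrix with metadata attributes).
#' @export
rdm <- function(values, ids = NULL,
                source = c("behavioral", "neural", "model", "feature"),
                distance_name = "dissimilarity") {
  source <- match.arg(source)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) stop("RDM must be square")
  if (is.null(ids)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- paste0("s", seq_len(n))
  }
  if (length(ids) != n) stop("length(ids) must equal nrow(values)")
  if (anyDuplicated(ids)) stop("stimulus ids must be unique")
  diag(values) <- 0
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("RDM must be symmetric")
  }
  values <- (values + t(values)) / 2  # exact symmetry
  off <- values[lower.tri(values)]
  if (any(!is.na(off) & !is.finite(off))) stop("RDM entries must be finite or NA")
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("rdm", "matrix", "array"),
            source = source, distance_name = distance_name)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d stimuli, source = %s, distance = %s\n",
              nrow(x), ncol(x), attr(x, "source"), attr(x, "distance_name")))
  nm <- sum(is.na(x[lower.tri(x)]))
  if (nm > 0) cat(sprintf("  %d undefined pair(s)\n", nm))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  invisible(x)
}

#' @export
as.matrix.rdm <- function(x, ...) {
  matrix(unclass(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

is_rdm <- function(x) inherits(x, "rdm")

as_rdm <- function(x, ...) {
  if (is_rdm(x)) x else rdm(x, ...)
}

#' Vectorize the lower triangle of an RDM
#'
#' Extracts the strictly-below-diagonal entries in deterministic row-major
#' order: row 2 first (`d21`), then row 3 (`d31, d32`), and so on. The result
#' has length `n * (n - 1) / 2`. All RDM comparisons and regressions in the
#' package operate on this vectorization.
#'
#' @param rdm Square matrix (an [rdm] or plain matrix).
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
lower_triangle_vector <- function(rdm) {
  m <- as.matrix(rdm)
  if (nrow(m) != ncol(m)) stop("input must be square")
  t(m)[upper.tri(m)]
}

## Inverse of lower_triangle_vector for an n x n symmetric matrix.
vector_to_rdm_matrix <- function(v, n, ids = NULL) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[upper.tri(tm)] <- v
  m <- tm + t(tm)
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  m
}

## Row lengths / offsets of the row-major strictly-lower-triangular layout:
## row i (2..n) contributes i-1 entries.
lower_tri_row_index <- function(n) {
  lens <- seq_len(n - 1)
  starts <- cumsum(c(1, lens[-length(lens)]))
  list(lengths = lens, starts = starts)
}

#' Correlation-distance RDM from response patterns
#'
#' Builds a neural (or feature) RDM from a stimulus-by-channel response
#' matrix using the 1 - r correlation distance: `d(i, j) = 1 - cor(x_i, x_j)`
#' (Pearson), with range `[0, 2]`. A stimulus whose pattern is constant
#' across channels has an undefined correlation; its entries are returned as
#' `NA` with a warning.
#'
#' @param patterns Numeric matrix, rows = stimuli, columns = measurement
#'   channels (voxels or model units). Needs >= 2 stimuli and >= 2 channels.
#' @param source Provenance tag for the result, default `"neural"`.
#' @return An [rdm] with `distance_name = "1 - Pearson r"`.
#' @export
correlation_distance_rdm <- function(patterns, source = "neural") {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2 || ncol(patterns) < 2) {
    stop("need >= 2 stimuli and >= 2 channels")
  }
  sds <- apply(patterns, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(t(patterns)))
  d <- 1 - r
  if (any(const)) {
    warning(sprintf("%d constant stimulus pattern(s); distances set to NA",
                    sum(const)))
    d[const, ] <- NA_real_
    d[, const] <- NA_real_
  }
  diag(d) <- 0
  rdm(d, ids = rownames(patterns), source = source,
      distance_name = "1 - Pearson r")
}

#' Compare two RDMs by rank correlation
#'
#' Correlates the lower-triangle vectors of two RDMs over the jointly
#' defined (non-`NA`) pairs. Spearman rank-order correlation is the default,
#' making the comparison invariant to any monotone transform of either RDM's
#' entries; the p-value is the asymptotic two-sided one.
#'
#' @param a,b RDMs over the same stimuli in the same order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `rho` (the correlation), `p` (two-sided), and
#'   `n_pairs` (jointly defined pairs used).
#' @export
compare_rdms <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("RDMs must have identical dimensions")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("RDM stimulus ids do not match")
  }
  va <- lower_triangle_vector(a)
  vb <- lower_triangle_vector(b)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) stop("need >= 3 jointly defined pairs")
  va <- va[ok]; vb <- vb[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("an RDM's defined entries are all tied; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n_pairs = sum(ok)))
  }
  ct <- suppressWarnings(
    stats::cor.test(va, vb, method = method, exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok))
}

#' Leave-one-out noise ceiling for a set of participant RDMs
#'
#' For each participant, correlates (Pearson by default) their lower-triangle
#' vector with the mean of all other participants' vectors; the ceiling is
#' the average of these coefficients. This is the lower-bound-style estimate
#' of the maximum RDM correlation attainable given between-participant
#' variability.
#'
#' @param rdms List of per-participant RDMs with aligned stimulus ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `ceiling` (mean coefficient) and `per_participant`.
#' @export
noise_ceiling <- function(rdms, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(rdms) < 2) stop("need >= 2 participants")
  vecs <- vapply(rdms, lower_triangle_vector,
                 numeric(length(lower_triangle_vector(rdms[[1]]))))
  rs <- vapply(seq_len(ncol(vecs)), function(i) {
    others <- rowMeans(vecs[, -i, drop = FALSE], na.rm = TRUE)
    ok <- is.finite(vecs[, i]) & is.finite(others)
    stats::cor(vecs[ok, i], others[ok], method = method)
  }, numeric(1))
  list(ceiling = mean(rs), per_participant = rs)
}

#' Entrywise group average of participant RDMs
#'
#' Missing-aware mean across participants: each pair's average is taken over
#' the participants for whom it is defined. An entry missing for every
#' participant raises an error.
#'
#' @param rdms List of RDMs with aligned ids.
#' @return An [rdm] of the same size.
#' @export
group_average_rdm <- function(rdms) {
  stopifnot(length(rdms) >= 1)
  n <- nrow(rdms[[1]])
  arr <- vapply(rdms, function(r) as.matrix(r), matrix(0, n, n))
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  off <- avg[lower.tri(avg)]
  if (any(is.na(off))) stop("some entries are missing for all participants")
  rdm(avg, ids = rownames(as.matrix(rdms[[1]])),
      source = attr(rdms[[1]], "source") %||% "behavioral",
      distance_name = attr(rdms[[1]], "distance_name") %||% "dissimilarity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nonmetric MDS embedding of an RDM
#'
#' Embeds the stimuli in `dims` dimensions by nonmetric multidimensional
#' scaling with Kruskal's stress-1 criterion, using several seeded restarts
#' (classical scaling plus random jitters as starting configurations) and
#' returning the lowest-stress solution.
#'
#' @param rdm An [rdm] with no missing entries.
#' @param dims Embedding dimensionality (default 2).
#' @param seed RNG seed for the random restarts.
#' @param n_restarts Number of starting configurations (default 8).
#' @return List with `coordinates` (stimuli x dims), `stress` (stress-1 as a
#'   fraction in `[0, 1]`), and `converged`.
#' @export
mds_embed <- function(rdm, dims = 2, seed = 1, n_restarts = 8) {
  d <- as.matrix(rdm)
  if (any(is.na(d[lower.tri(d)]))) stop("MDS requires a complete RDM")
  n <- nrow(d)
  if (n <= dims) stop("need more stimuli than embedding dimensions")
  ## isoMDS cannot handle zero off-diagonal dissimilarities; nudge exact ties
  ## with zero upward by a negligible amount.
  eps <- max(d) * 1e-9 + 1e-12
  dd <- d
  dd[dd <= 0] <- eps
  diag(dd) <- 0
  local_seed(seed, {
    starts <- vector("list", n_restarts)
    cm <- stats::cmdscale(dd, k = dims)
    if (ncol(cm) < dims) {
      cm <- cbind(cm, matrix(0, n, dims - ncol(cm)))
    }
    starts[[1]] <- cm
    scale0 <- max(abs(cm)) + 1e-6
    for (i in seq_len(n_restarts)[-1]) {
      starts[[i]] <- cm + matrix(stats::rnorm(n * dims, sd = 0.25 * scale0),
                                 n, dims)
    }
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        MASS::isoMDS(dd, y = st, k = dims, maxit = 100, tol = 1e-6,
                     trace = FALSE),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    if (is.null(best)) stop("MDS failed to produce a configuration")
    rownames(best$points) <- rownames(d)
    list(coordinates = best$points,
         stress = best$stress / 100,  # isoMDS reports stress-1 in percent
         converged = TRUE)
  })
}
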