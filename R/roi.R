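#' Statistical maps and ROI masks
#'
#' A `stat_map` bundles congruent 3-D arrays of test statistics and
#' p-values (plus optional affine metadata carried through from NIfTI
#' input). An ROI mask is a logical 3-D array on the same grid.
#'
#' @param stat 3-D numeric array of per-voxel test statistics.
#' @param p 3-D numeric array of per-voxel p-values in `[0, 1]`.
#' @param affine Optional 4x4 affine (kept for NIfTI round-trips).
#' @return A list of class `stat_map`.
#' @export
stat_map <- function(stat, p, affine = NULL) {
  stat <- as.array(stat); p <- as.array(p)
  if (!identical(dim(stat), dim(p))) stop("stat and p grids must be congruent")
  if (length(dim(stat)) != 3) stop("maps must be 3-D")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  structure(list(stat = stat, p = p, affine = affine), class = "stat_map")
}

## 18-neighbor offsets: faces (6) and edges (12), corners excluded.
neighborhood_18 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  as.matrix(g[s >= 1 & s <= 2, ])
}

#' Connected components of a binary 3-D map
#'
#' Labels connected components under 18-connectivity: voxels sharing a face
#' or an edge are neighbors, voxels touching only at a corner are not.
#'
#' @param binary_map Logical (or 0/1) 3-D array.
#' @return List with `labels` (integer array, 0 = background, components
#'   numbered from 1) and `sizes` (voxel count per component, ordered by
#'   label).
#' @export
cluster_components <- function(binary_map) {
  bm <- as.array(binary_map)
  if (length(dim(bm)) != 3) stop("binary map must be 3-D")
  dims <- dim(bm)
  active <- which(bm != 0 & !is.na(bm))
  labels <- array(0L, dims)
  if (length(active) == 0) return(list(labels = labels, sizes = integer(0)))
  offs <- neighborhood_18()
  coords <- arrayInd(active, dims)
  ## map from linear voxel index to its position in `active`, for O(1) lookup
  pos <- integer(prod(dims))
  pos[active] <- seq_along(active)
  lab <- integer(length(active))
  nxt <- 0L
  stack <- integer(length(active))
  for (s in seq_along(active)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    top <- 1L
    stack[1L] <- s
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      cx <- coords[cur, 1]; cy <- coords[cur, 2]; cz <- coords[cur, 3]
      nx <- cx + offs[, 1]; ny <- cy + offs[, 2]; nz <- cz + offs[, 3]
      ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
        nz >= 1 & nz <= dims[3]
      lin <- (nz[ok] - 1L) * dims[1] * dims[2] + (ny[ok] - 1L) * dims[1] +
        nx[ok]
      np <- pos[lin]
      np <- np[np != 0L]
      np <- np[lab[np] == 0L]
      if (length(np)) {
        lab[np] <- nxt
        stack[(top + 1L):(top + length(np))] <- np
        top <- top + length(np)
      }
    }
  }
  labels[active] <- lab
  list(labels = labels, sizes = as.integer(tabulate(lab, nbins = nxt)))
}

#' Define an ROI by adaptive thresholding
#'
#' Walks the threshold sequence from most to least stringent. At each
#' threshold, voxels with `p < threshold` inside the anatomical mask are
#' clustered (18-connectivity) and clusters smaller than `min_cluster` are
#' discarded; if any voxels survive, they become the ROI and the search
#' stops. If no threshold yields a surviving cluster, no ROI is created and
#' `NULL` is returned.
#'
#' @param map A [stat_map()].
#' @param mask Logical 3-D array (anatomical mask) on the same grid.
#' @param thresholds Decreasing-stringency p thresholds,
#'   default `c(0.001, 0.005, 0.01, 0.05)`.
#' @param min_cluster Minimum cluster extent in voxels (default 40).
#' @param name ROI name carried in the result.
#' @return List of class `roi_mask` with `mask` (logical array), `name`,
#'   `threshold` (the one that succeeded), and `n_voxels`; or `NULL`.
#' @export
define_roi <- function(map, mask, thresholds = c(0.001, 0.005, 0.01, 0.05),
                       min_cluster = 40, name = "roi") {
  stopifnot(inherits(map, "stat_map"))
  mask <- as.array(mask) != 0
  if (!identical(dim(mask), dim(map$p))) stop("map and mask grid mismatch")
  for (th in sort(thresholds)) {
    supra <- map$p < th & mask
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) next
    cc <- cluster_components(supra)
    keep <- which(cc$sizes >= min_cluster)
    if (length(keep) == 0) next
    roi <- array(cc$labels %in% keep, dim(mask))
    return(structure(list(mask = roi, name = name, threshold = th,
                          n_voxels = sum(roi)), class = "roi_mask"))
  }
  NULL
}

#' Select the top-N most selective voxels
#'
#' Returns the `n` voxels with the largest selectivity statistic within the
#' mask, without any clustering. Ties at the boundary are broken
#' deterministically by linear voxel index, so repeated calls give identical
#' masks.
#'
#' @param map A [stat_map()].
#' @param mask Logical 3-D array with at least `n` voxels.
#' @param n Number of voxels to select.
#' @return An `roi_mask` of exactly `n` voxels.
#' @export
top_n_voxels <- function(map, mask, n) {
  stopifnot(inherits(map, "stat_map"))
  mask <- as.array(mask) != 0
  if (!identical(dim(mask), dim(map$stat))) stop("map and mask grid mismatch")
  idx <- which(mask)
  if (n > length(idx)) stop("n exceeds mask size")
  stat <- map$stat[idx]
  ord <- order(stat, idx, decreasing = c(TRUE, FALSE), method = "radix")
  sel <- idx[ord[seq_len(n)]]
  m <- array(FALSE, dim(mask))
  m[sel] <- TRUE
  structure(list(mask = m, name = sprintf("top%d", n), threshold = NA_real_,
                 n_voxels = n), class = "roi_mask")
}

#' Per-participant mean ROI responses
#'
#' Averages each participant's beta values over ROI voxels, at the level of
#' individual exemplars or pooled into coarser groupings (object type or
#' shape type from the design).
#'
#' @param betas Named list, one stimulus x voxel matrix per participant;
#'   rownames are stimulus ids, shared across participants.
#' @param design `stimulus_design` providing the grouping labels.
#' @param grouping `"exemplar"`, `"object_type"`, or `"shape_type"`.
#' @return Data frame with columns `participant_id`, `group`, `mean_beta`.
#' @export
roi_mean_responses <- function(betas, design,
                               grouping = c("exemplar", "object_type",
                                            "shape_type")) {
  grouping <- match.arg(grouping)
  stopifnot(length(betas) >= 1)
  validate_design(design)
  ids <- rownames(betas[[1]])
  if (is.null(ids)) stop("beta matrices need stimulus rownames")
  for (b in betas) {
    if (!identical(rownames(b), ids)) {
      stop("stimulus labels inconsistent across participants")
    }
  }
  grp <- switch(grouping,
    exemplar = ids,
    object_type = as.character(
      design$object_type[match(ids, design$stimulus_id)]),
    shape_type = design$aspect_ratio[match(ids, design$stimulus_id)]
  )
  if (anyNA(grp)) stop("stimuli missing from the design")
  pnames <- names(betas) %||% paste0("p", seq_along(betas))
  do.call(rbind, lapply(seq_along(betas), function(i) {
    per_stim <- rowMeans(betas[[i]])
    agg <- tapply(per_stim, grp, mean)
    data.frame(participant_id = pnames[i], group = names(agg),
               mean_beta = as.numeric(agg), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Paired group test between two conditions
#'
#' Two-sided paired t-test across participants of the difference in mean
#' ROI response between two conditions.
#'
#' @param means Output of [roi_mean_responses()].
#' @param condition_a,condition_b Group labels to compare.
#' @return List with `t`, `df`, `p`, `mean_difference`.
#' @export
group_condition_test <- function(means, condition_a, condition_b) {
  wide <- stats::reshape(means, idvar = "participant_id",
                         timevar = "group", direction = "wide")
  ca <- wide[[paste0("mean_beta.", condition_a)]]
  cb <- wide[[paste0("mean_beta.", condition_b)]]
  if (is.null(ca) || is.null(cb)) stop("unknown condition label")
  ok <- is.finite(ca) & is.finite(cb)
  if (sum(ok) < 2) stop("need >= 2 participants with both conditions")
  dif <- ca[ok] - cb[ok]
  if (stats::sd(dif) == 0) {
    warning("zero variance of paired differences")
    return(list(t = if (mean(dif) == 0) 0 else sign(mean(dif)) * Inf,
                df = sum(ok) - 1, p = if (mean(dif) == 0) 1 else 0,
                mean_difference = mean(dif)))
  }
  tt <- stats::t.test(ca[ok], cb[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = unname(tt$estimate))
}

#' Correlate rating profiles with ROI responses
#'
#' For each participant, Pearson-correlates a per-stimulus rating profile
#' (mean ratings or PCA scores) with that participant's per-stimulus mean
#' ROI response, then tests the coefficients against zero with a two-sided
#' one-sample t-test (optionally on Fisher-z transformed coefficients).
#'
#' @param profile Named numeric vector of per-stimulus values.
#' @param betas Named list of stimulus x voxel matrices (as in
#'   [roi_mean_responses()]).
#' @param fisher_z Transform coefficients before the t-test (default FALSE).
#' @return List with `per_participant` (r per participant), `t`, `df`, `p`.
#' @export
rating_response_correlation <- function(profile, betas, fisher_z = FALSE) {
  stopifnot(!is.null(names(profile)))
  rs <- vapply(betas, function(b) {
    common <- intersect(rownames(b), names(profile))
    if (length(common) < 3) stop("< 3 overlapping stimuli")
    stats::cor(profile[common], rowMeans(b)[common])
  }, numeric(1))
  x <- if (fisher_z) atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12)) else rs
  if (length(rs) < 2 || stats::sd(x) == 0) {
    return(list(per_participant = rs, t = NA_real_, df = NA_real_,
                p = NA_real_))
  }
  tt <- stats::t.test(x)
  list(per_participant = rs, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
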