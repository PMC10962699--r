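#' Jaccard overlap of two voxel sets
#'
#' Overlap of two binary maps on a common grid: the Jaccard index
#' `|A intersect B| / |A union B|`, together with the unique fractions
#' `|A \ B| / |A union B|` and `|B \ A| / |A union B|`. The three fractions
#' sum to 1 whenever the union is nonempty.
#'
#' @param map_a,map_b Logical arrays (or `roi_mask` objects, or integer
#'   index vectors on a shared grid).
#' @return List with `jaccard`, `unique_a`, `unique_b`, `n_union`,
#'   `n_intersection`.
#' @export
jaccard_overlap <- function(map_a, map_b) {
  a <- as_voxel_index(map_a)
  b <- as_voxel_index(map_b)
  uni <- union(a, b)
  if (length(uni) == 0) stop("empty union: overlap undefined")
  inter <- intersect(a, b)
  list(jaccard = length(inter) / length(uni),
       unique_a = length(setdiff(a, b)) / length(uni),
       unique_b = length(setdiff(b, a)) / length(uni),
       n_union = length(uni),
       n_intersection = length(inter))
}

as_voxel_index <- function(x) {
  if (inherits(x, "roi_mask")) x <- x$mask
  if (is.array(x) || is.logical(x)) return(which(x != 0))
  as.integer(x)
}

#' Thresholded overlap of two statistical maps
#'
#' Thresholds each map at `p < p_threshold` within the anatomical mask,
#' removes clusters smaller than `min_cluster` voxels (18-connectivity),
#' and computes the Jaccard overlap of the surviving voxel sets. If either
#' thresholded set is empty the overlap is undefined and reported as such
#' (`NA` with `defined = FALSE`), never as zero.
#'
#' @param map_a,map_b [stat_map()] objects on a shared grid.
#' @param mask Logical 3-D anatomical mask.
#' @param p_threshold Liberal threshold, default 0.05.
#' @param min_cluster Minimum cluster extent, default 40 voxels.
#' @return The [jaccard_overlap()] list plus `defined`; when undefined all
#'   fractions are `NA`.
#' @export
thresholded_overlap <- function(map_a, map_b, mask, p_threshold = 0.05,
                                min_cluster = 40) {
  sets <- lapply(list(map_a, map_b), function(m) {
    stopifnot(inherits(m, "stat_map"))
    supra <- m$p < p_threshold & (as.array(mask) != 0)
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) return(integer(0))
    cc <- cluster_components(supra)
    keep <- which(cc$sizes >= min_cluster)
    which(array(cc$labels %in% keep, dim(supra)))
  })
  if (length(sets[[1]]) == 0 || length(sets[[2]]) == 0) {
    return(list(jaccard = NA_real_, unique_a = NA_real_, unique_b = NA_real_,
                n_union = NA_integer_, n_intersection = NA_integer_,
                defined = FALSE))
  }
  c(jaccard_overlap(sets[[1]], sets[[2]]), list(defined = TRUE))
}

#' Top-N voxel overlap curve
#'
#' For each requested size `n`, selects the `n` most selective voxels of
#' each map within the mask (no clustering; see [top_n_voxels()]) and
#' records the Jaccard index of the two selections. The default sizes are
#' 50 to 500 in steps of 50.
#'
#' @param map_a,map_b [stat_map()] objects on a shared grid.
#' @param mask Logical 3-D mask; sizes exceeding the mask are skipped with
#'   a warning.
#' @param sizes Integer vector of selection sizes.
#' @return Data frame with columns `n` and `jaccard`.
#' @export
topn_overlap_curve <- function(map_a, map_b, mask,
                               sizes = seq(50, 500, by = 50)) {
  mask <- as.array(mask) != 0
  avail <- sum(mask)
  ok <- sizes <= avail
  if (!all(ok)) {
    warning(sprintf("mask has %d voxels; skipping sizes: %s", avail,
                    paste(sizes[!ok], collapse = ", ")))
  }
  sizes <- sizes[ok]
  if (length(sizes) == 0) stop("mask too small for every requested size")
  jac <- vapply(sizes, function(n) {
    a <- top_n_voxels(map_a, mask, n)
    b <- top_n_voxels(map_b, mask, n)
    jaccard_overlap(a, b)$jaccard
  }, numeric(1))
  data.frame(n = sizes, jaccard = jac)
}

#' Group summary of per-participant overlap fractions
#'
#' Averages per-participant overlap results, excluding participants whose
#' overlap was undefined (empty thresholded map), and runs two-sided paired
#' t-tests comparing each unique fraction against the overlap fraction.
#'
#' @param results List of per-participant [thresholded_overlap()] results.
#' @return List with `n_defined`, `mean_jaccard`, `mean_unique_a`,
#'   `mean_unique_b`, and `tests` (a data frame of the two paired
#'   comparisons).
#' @export
overlap_group_summary <- function(results) {
  def <- vapply(results, function(r) isTRUE(r$defined %||% TRUE), logical(1))
  res <- results[def]
  if (length(res) == 0) stop("no participant with a defined overlap")
  jac <- vapply(res, `[[`, numeric(1), "jaccard")
  ua <- vapply(res, `[[`, numeric(1), "unique_a")
  ub <- vapply(res, `[[`, numeric(1), "unique_b")
  test_pair <- function(x, y, label) {
    if (length(x) < 2 || stats::sd(x - y) == 0) {
      return(data.frame(comparison = label, t = NA, df = NA, p = NA))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(comparison = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }
  list(n_defined = length(res),
       mean_jaccard = mean(jac),
       mean_unique_a = mean(ua),
       mean_unique_b = mean(ub),
       tests = rbind(test_pair(ua, jac, "unique_a vs overlap"),
                     test_pair(ub, jac, "unique_b vs overlap")))
}
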