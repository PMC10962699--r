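#' Read and write RDMs as square TSV
#'
#' RDMs are serialized as a square tab-delimited table whose header row and
#' first column carry the stimulus ids; undefined pairs are written as
#' `NA`.
#'
#' @param x An [rdm].
#' @param path File path.
#' @param source,distance_name Provenance restored on read.
#' @return `read_rdm` returns an [rdm]; `write_rdm` returns `path`
#'   invisibly.
#' @export
write_rdm <- function(x, path) {
  m <- as.matrix(x)
  df <- data.frame(stimulus_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path, source = "behavioral",
                     distance_name = "dissimilarity") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), ids)) stop("row and column ids differ")
  rownames(m) <- ids
  rdm(m, ids = ids, source = source, distance_name = distance_name)
}

#' Build a feature-space RDM from a TSV of unit responses
#'
#' Reads a delimited matrix (rows = stimuli via the first column, columns =
#' model units or channels) and returns its 1 - r correlation-distance RDM.
#' This is how layer RDMs of an external network's activations enter the
#' pipeline: the package consumes arbitrary feature matrices, it never runs
#' a network.
#'
#' @param path TSV with a `stimulus_id` first column.
#' @return A feature-sourced [rdm].
#' @export
rdm_from_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  correlation_distance_rdm(m, source = "feature")
}

#' Read and write statistical maps and masks as NIfTI
#'
#' Thin wrappers over RNifti: a [stat_map()] is stored as two volumes
#' (statistic and p), a mask as one binary volume.
#'
#' @param map A [stat_map()].
#' @param stat_path,p_path NIfTI file paths for the two volumes.
#' @return `read_stat_map` returns a [stat_map()].
#' @export
write_stat_map <- function(map, stat_path, p_path) {
  stopifnot(inherits(map, "stat_map"))
  RNifti::writeNifti(RNifti::asNifti(map$stat), stat_path)
  RNifti::writeNifti(RNifti::asNifti(map$p), p_path)
  invisible(c(stat_path, p_path))
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(stat_path, p_path) {
  s <- RNifti::readNifti(stat_path)
  p <- RNifti::readNifti(p_path)
  stat_map(array(as.numeric(s), dim(s)), array(as.numeric(p), dim(p)),
           affine = tryCatch(RNifti::xform(s), error = function(e) NULL))
}

#' @rdname write_stat_map
#' @param mask Logical 3-D array or `roi_mask`.
#' @param path NIfTI path.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dim(mask))),
                     path)
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_mask <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v) != 0, dim(v))
}

#' Write a full synthetic study to disk
#'
#' Generates every input the pipeline consumes -- triplet trials, rating
#' tables, per-participant pattern matrices, paired statistical maps with
#' their anatomical mask, and the ground-truth RDM -- and writes them under
#' `dir` as TSV and NIfTI files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the generated objects.
#' @export
simulate_study <- function(config = generator_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_truth_rdm(config)
  trials <- simulate_triplet_responses(truth, config)
  profile <- stats::setNames(
    pmin(7, pmax(1, as.numeric(scale(rowMeans(as.matrix(truth)))) + 4)),
    config$design$stimulus_id)
  ratings <- simulate_ratings(profile, config)
  patterns <- simulate_subject_patterns(truth, config)
  maps <- simulate_stat_maps(config)
  write_design(config$design, file.path(dir, "design.tsv"))
  write_rdm(truth, file.path(dir, "truth_rdm.tsv"))
  write_triplet_trials(trials, file.path(dir, "triplet_trials.tsv"))
  write_ratings(ratings, file.path(dir, "ratings.tsv"))
  for (p in names(patterns)) {
    df <- data.frame(stimulus_id = rownames(patterns[[p]]), patterns[[p]],
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, sprintf("patterns_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_stat_map(maps$map_a, file.path(dir, "map_a_stat.nii.gz"),
                 file.path(dir, "map_a_p.nii.gz"))
  write_stat_map(maps$map_b, file.path(dir, "map_b_stat.nii.gz"),
                 file.path(dir, "map_b_p.nii.gz"))
  write_mask(maps$mask, file.path(dir, "anatomical_mask.nii.gz"))
  invisible(list(truth = truth, trials = trials, ratings = ratings,
                 patterns = patterns, maps = maps))
}
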