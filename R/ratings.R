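#' Likert rating tables
#'
#' Rating-task data are data frames with columns `participant_id`, `task`,
#' `stimulus_id`, and `rating` (integers 1-7). Each participant rates each
#' stimulus at most once per task.
#'
#' @param ratings Data frame of ratings.
#' @return The validated table, invisibly.
#' @export
validate_ratings <- function(ratings) {
  need <- c("participant_id", "task", "stimulus_id", "rating")
  if (!all(need %in% names(ratings))) {
    stop("ratings need columns: ", paste(need, collapse = ", "))
  }
  if (!all(ratings$rating %in% 1:7)) stop("ratings must be integers in 1..7")
  key <- interaction(ratings$participant_id, ratings$task,
                     ratings$stimulus_id, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("a participant rated the same stimulus twice in one task")
  }
  invisible(ratings)
}

#' Per-stimulus and per-type mean ratings
#'
#' Arithmetic mean rating per stimulus, and -- when a design is supplied --
#' per-object-type means with 95% confidence intervals of a normal
#' distribution centered on the mean (mean +/- 1.96 x SEM over the
#' contributing ratings).
#'
#' @param ratings A single-task rating table (see [validate_ratings()]).
#' @param design Optional `stimulus_design` for the per-type summary.
#' @return List with `stimulus_means` (data frame: `stimulus_id`, `mean`,
#'   `n`) and, if `design` is given, `type_means` (`object_type`, `mean`,
#'   `ci_lower`, `ci_upper`, `n`).
#' @export
mean_ratings <- function(ratings, design = NULL) {
  validate_ratings(ratings)
  if (length(unique(ratings$task)) > 1) {
    stop("mean_ratings expects a single task; split by task first")
  }
  sp <- split(ratings$rating, ratings$stimulus_id)
  if (any(lengths(sp) == 0)) stop("stimulus with zero ratings")
  stim <- data.frame(stimulus_id = names(sp),
                     mean = vapply(sp, mean, numeric(1)),
                     n = lengths(sp), row.names = NULL,
                     stringsAsFactors = FALSE)
  out <- list(stimulus_means = stim)
  if (!is.null(design)) {
    validate_design(design)
    miss <- setdiff(stim$stimulus_id, design$stimulus_id)
    if (length(miss)) stop("rated stimuli absent from design")
    ty <- design$object_type[match(ratings$stimulus_id, design$stimulus_id)]
    tsp <- split(ratings$rating, ty)
    z <- stats::qnorm(0.975)
    out$type_means <- data.frame(
      object_type = names(tsp),
      mean = vapply(tsp, mean, numeric(1)),
      ci_lower = vapply(tsp, function(x) {
        mean(x) - z * stats::sd(x) / sqrt(length(x))
      }, numeric(1)),
      ci_upper = vapply(tsp, function(x) {
        mean(x) + z * stats::sd(x) / sqrt(length(x))
      }, numeric(1)),
      n = lengths(tsp), row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out
}

#' Split-half reliability of a rating task
#'
#' Splits participants into random halves `n_splits` times,
#' Pearson-correlates the two halves' mean per-stimulus profiles, averages
#' the correlations, and applies the Spearman-Brown correction. Participants
#' are the only sensible split unit here because each rates each stimulus
#' once.
#'
#' @param ratings Single-task rating table with >= 2 participants.
#' @param n_splits Number of random splits (default 1000).
#' @param seed RNG seed.
#' @return List with `reliability` (corrected) and `mean_r`.
#' @export
rating_reliability <- function(ratings, n_splits = 1000, seed = 1) {
  validate_ratings(ratings)
  parts <- unique(ratings$participant_id)
  if (length(parts) < 2) stop("need >= 2 participants")
  stims <- sort(unique(ratings$stimulus_id))
  ## participant x stimulus matrix of ratings
  m <- matrix(NA_real_, length(parts), length(stims),
              dimnames = list(parts, stims))
  m[cbind(match(ratings$participant_id, parts),
          match(ratings$stimulus_id, stims))] <- ratings$rating
  local_seed(seed, {
    rs <- vapply(seq_len(n_splits), function(s) {
      half <- sample(length(parts), floor(length(parts) / 2))
      p1 <- colMeans(m[half, , drop = FALSE], na.rm = TRUE)
      p2 <- colMeans(m[-half, , drop = FALSE], na.rm = TRUE)
      ok <- is.finite(p1) & is.finite(p2)
      stats::cor(p1[ok], p2[ok])
    }, numeric(1))
    mean_r <- mean(rs, na.rm = TRUE)
    list(reliability = spearman_brown(mean_r), mean_r = mean_r)
  })
}

#' Pairwise correlations between task mean-rating profiles
#'
#' Pearson correlation between every pair of tasks' per-stimulus mean
#' profiles, with two-sided p-values. Constant profiles give `NA` with a
#' warning.
#'
#' @param profiles Numeric matrix, rows = stimuli, columns = tasks (e.g.
#'   assembled from [mean_ratings()] outputs).
#' @return List with `r` (task x task correlation matrix) and `p`
#'   (two-sided p-values, `NA` on the diagonal).
#' @export
task_correlation_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need >= 2 tasks")
  k <- ncol(profiles)
  const <- apply(profiles, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant task profile(s): ",
            paste(colnames(profiles)[const], collapse = ", "))
  }
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(profiles),
                                              colnames(profiles)))
  p <- r
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (const[i] || const[j]) next
      ct <- stats::cor.test(profiles[, i], profiles[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' PCA of action-rating task profiles
#'
#' Principal component analysis of the stimulus x task matrix of mean
#' ratings, z-scored per task (the tasks share a 1-7 scale but differ in
#' spread). Returns the first two components' stimulus scores and the
#' cumulative fraction of variance they explain, plus the full spectrum.
#'
#' @param profiles Numeric matrix, rows = stimuli (>= 3), columns = tasks
#'   (>= 2) of mean ratings.
#' @return List with `scores` (stimuli x 2), `variance_explained`
#'   (cumulative fraction for the first two PCs), `all_fractions`, and
#'   `rank_deficient` (flag).
#' @export
action_pca <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2 || nrow(profiles) < 3) {
    stop("need >= 2 tasks and >= 3 stimuli")
  }
  if (any(apply(profiles, 2, stats::sd) == 0)) {
    stop("constant task profile cannot be standardized")
  }
  pc <- stats::prcomp(profiles, center = TRUE, scale. = TRUE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  rank_def <- sum(pc$sdev > max(pc$sdev) * 1e-8) < ncol(profiles)
  if (rank_def) warning("rank-deficient task profiles")
  k <- min(2, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = sum(fr[seq_len(k)]),
       all_fractions = fr,
       rank_deficient = rank_def)
}

#' Read / write rating tables as TSV
#' @param ratings Rating data frame.
#' @param path File path.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  utils::write.table(ratings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ratings(r)
  r
}
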