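#' Enumerate all unordered stimulus triplets
#'
#' Deterministically lists every unordered triplet of `n_stimuli` stimuli in
#' lexicographic order of stimulus indices. With the default 48-stimulus
#' design this yields `choose(48, 3) = 17296` triplets.
#'
#' @param n_stimuli Number of stimuli (>= 3).
#' @return Integer matrix with `choose(n, 3)` rows and columns
#'   `i`, `j`, `k` (`i < j < k`).
#' @export
enumerate_triplets <- function(n_stimuli) {
  stopifnot(length(n_stimuli) == 1, n_stimuli == round(n_stimuli))
  if (n_stimuli < 3) stop("need at least 3 stimuli")
  m <- t(utils::combn(as.integer(n_stimuli), 3L))
  colnames(m) <- c("i", "j", "k")
  m
}

#' Randomly chunk triplets into trial sets
#'
#' Permutes the triplets with the given seed and partitions them into
#' consecutive sets of `chunk_size`, with one final remainder set if the
#' total is not a multiple. The 17296 triplets of the default design at
#' chunk size 42 give 412 sets, the last of size 34.
#'
#' @param triplets Matrix of triplets as from [enumerate_triplets()] (any
#'   row-indexed object works).
#' @param chunk_size Trials per set (>= 1).
#' @param seed RNG seed controlling the permutation.
#' @return List of matrices, one per set; their union is the input.
#' @export
chunk_trials <- function(triplets, chunk_size, seed = 1) {
  n <- NROW(triplets)
  if (n == 0) stop("no triplets to chunk")
  stopifnot(chunk_size >= 1)
  perm <- local_seed(seed, sample.int(n))
  shuffled <- triplets[perm, , drop = FALSE]
  starts <- seq(1, n, by = chunk_size)
  lapply(starts, function(s) {
    shuffled[s:min(s + chunk_size - 1, n), , drop = FALSE]
  })
}

#' Triplet trial tables
#'
#' Trial-level odd-one-out data are plain data frames with columns
#' `participant_id`, `session_id`, `stim_a`, `stim_b`, `stim_c` (the three
#' distinct members of the triplet), `choice` (the stimulus judged odd; must
#' be one of the three), and `rt_ms` (reaction time, nonnegative
#' milliseconds). `validate_triplet_trials` checks these invariants and,
#' when a stimulus universe is given, that every id occurs in it.
#'
#' @param trials Data frame of trials.
#' @param universe Optional character vector (or `stimulus_design`) of valid
#'   stimulus ids.
#' @return The validated trials, invisibly.
#' @export
validate_triplet_trials <- function(trials, universe = NULL) {
  need <- c("participant_id", "session_id", "stim_a", "stim_b", "stim_c",
            "choice", "rt_ms")
  if (!all(need %in% names(trials))) {
    stop("trials need columns: ", paste(setdiff(need, names(trials)),
                                        collapse = ", "))
  }
  trip <- trials[, c("stim_a", "stim_b", "stim_c")]
  if (any(apply(trip, 1, anyDuplicated) > 0)) {
    stop("triplet members must be distinct")
  }
  in_trip <- trials$choice == trials$stim_a |
    trials$choice == trials$stim_b | trials$choice == trials$stim_c
  if (!all(in_trip)) stop("every choice must be a member of its triplet")
  if (any(trials$rt_ms < 0)) stop("rt_ms must be nonnegative")
  if (!is.null(universe)) {
    ids <- if (is.data.frame(universe)) universe$stimulus_id else universe
    used <- unique(c(trials$stim_a, trials$stim_b, trials$stim_c))
    if (!all(used %in% ids)) {
      stop("trial stimuli absent from the universe: ",
           paste(utils::head(setdiff(used, ids)), collapse = ", "))
    }
  }
  invisible(trials)
}

#' Quality-control filter for triplet sessions
#'
#' Applies the exclusion rule per participant-session: a session is dropped
#' if the participant responded uniformly across all its trials -- always
#' choosing the same response position or always the same stimulus -- or if
#' the session's median reaction time is below `rt_low` (200 ms) or above
#' `rt_high` (10000 ms).
#'
#' @param trials Triplet trial data frame (see
#'   [validate_triplet_trials()]).
#' @param rt_low,rt_high Median reaction-time bounds in milliseconds.
#' @return List with `kept` (surviving trials), `excluded` (dropped trials),
#'   and `report`, a data frame of one row per session with its exclusion
#'   reason (`uniform`, `rt_low`, `rt_high`, or `kept`).
#' @export
qc_filter <- function(trials, rt_low = 200, rt_high = 10000) {
  validate_triplet_trials(trials)
  key <- interaction(trials$participant_id, trials$session_id, drop = TRUE)
  pos <- ifelse(trials$choice == trials$stim_a, 1L,
                ifelse(trials$choice == trials$stim_b, 2L, 3L))
  report <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key),
                                  function(idx) {
    sub <- trials[idx, ]
    med <- stats::median(sub$rt_ms)
    uniform <- length(unique(pos[idx])) == 1L ||
      length(unique(sub$choice)) == 1L
    reason <- if (uniform) "uniform"
      else if (med < rt_low) "rt_low"
      else if (med > rt_high) "rt_high"
      else "kept"
    data.frame(participant_id = sub$participant_id[1],
               session_id = sub$session_id[1],
               n_trials = nrow(sub), median_rt_ms = med,
               reason = reason, stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  bad <- report[report$reason != "kept",
                c("participant_id", "session_id")]
  drop <- interaction(trials$participant_id, trials$session_id,
                      drop = FALSE) %in%
    interaction(bad$participant_id, bad$session_id, drop = FALSE)
  list(kept = trials[!drop, , drop = FALSE],
       excluded = trials[drop, , drop = FALSE],
       report = report)
}

#' Aggregate triplet judgments into an RDM
#'
#' For each stimulus pair (i, j), the dissimilarity is the number of trials
#' containing both i and j in which either was chosen as the odd one out,
#' divided by the number of trials in which the pair co-occurred. Pairs that
#' never co-occur are `NA` in the RDM (never silently zero) and have a zero
#' co-occurrence count.
#'
#' @param trials Triplet trial data frame.
#' @param ids Stimulus universe defining the RDM's rows/columns; defaults to
#'   the sorted set of ids appearing in the trials.
#' @return List with `rdm` (a behavioral [rdm] with values in `[0, 1]`) and
#'   `counts` (symmetric co-occurrence count matrix).
#' @export
aggregate_rdm <- function(trials, ids = NULL) {
  validate_triplet_trials(trials)
  if (nrow(trials) == 0) stop("no trials to aggregate")
  if (is.null(ids)) {
    ids <- sort(unique(c(trials$stim_a, trials$stim_b, trials$stim_c)))
  } else if (is.data.frame(ids)) {
    ids <- ids$stimulus_id
  }
  n <- length(ids)
  a <- match(trials$stim_a, ids)
  b <- match(trials$stim_b, ids)
  c_ <- match(trials$stim_c, ids)
  ch <- match(trials$choice, ids)
  if (anyNA(c(a, b, c_, ch))) stop("trial stimuli absent from ids")
  pair_key <- function(p, q) {
    lo <- pmin(p, q); hi <- pmax(p, q)
    (lo - 1L) * n + hi
  }
  cooc_keys <- c(pair_key(a, b), pair_key(a, c_), pair_key(b, c_))
  cooc <- tabulate(cooc_keys, nbins = n * n)
  ## the two pairs that contain the chosen (odd) stimulus are "split"
  other1 <- ifelse(ch == a, b, a)
  other2 <- ifelse(ch == c_, b, c_)
  odd_keys <- c(pair_key(ch, other1), pair_key(ch, other2))
  odd <- tabulate(odd_keys, nbins = n * n)
  cm <- matrix(cooc, n, n, byrow = TRUE)
  om <- matrix(odd, n, n, byrow = TRUE)
  cm <- cm + t(cm)
  om <- om + t(om)
  d <- ifelse(cm > 0, om / cm, NA_real_)
  diag(d) <- 0
  dimnames(cm) <- list(ids, ids)
  list(rdm = rdm(d, ids = ids, source = "behavioral",
                 distance_name = "odd-one-out proportion"),
       counts = cm)
}

#' Split-half reliability of a triplet RDM
#'
#' Repeatedly splits the data in half, aggregates an RDM from each half,
#' Pearson-correlates the two lower triangles over the pairs defined in
#' both halves, averages the correlation over splits, and applies the
#' Spearman-Brown correction to the mean. Splits can cut across trials
#' (default) or keep whole participant-sessions together.
#'
#' Splits in which the halves share fewer than 3 defined pairs are skipped
#' and counted; if every split is skipped an error is raised.
#'
#' @param trials Triplet trial data frame.
#' @param n_splits Number of random splits (default 1000).
#' @param seed RNG seed.
#' @param split_unit `"trial"` or `"session"`.
#' @param method Correlation inside each split: `"pearson"` (default) or
#'   `"spearman"`.
#' @param ids Optional stimulus universe (passed to [aggregate_rdm()]).
#' @return List with `reliability` (Spearman-Brown corrected), `mean_r`
#'   (uncorrected mean split correlation), and `n_skipped`.
#' @export
split_half_reliability <- function(trials, n_splits = 1000, seed = 1,
                                   split_unit = c("trial", "session"),
                                   method = c("pearson", "spearman"),
                                   ids = NULL) {
  split_unit <- match.arg(split_unit)
  method <- match.arg(method)
  validate_triplet_trials(trials)
  if (is.null(ids)) {
    ids <- sort(unique(c(trials$stim_a, trials$stim_b, trials$stim_c)))
  }
  units <- switch(split_unit,
    trial = seq_len(nrow(trials)),
    session = as.integer(interaction(trials$participant_id,
                                     trials$session_id, drop = TRUE))
  )
  u <- unique(units)
  if (length(u) < 2) stop("need at least 2 split units")
  local_seed(seed, {
    rs <- numeric(0)
    skipped <- 0L
    for (s in seq_len(n_splits)) {
      half <- sample(u, floor(length(u) / 2))
      in1 <- units %in% half
      r <- tryCatch({
        r1 <- aggregate_rdm(trials[in1, , drop = FALSE], ids = ids)$rdm
        r2 <- aggregate_rdm(trials[!in1, , drop = FALSE], ids = ids)$rdm
        v1 <- lower_triangle_vector(r1)
        v2 <- lower_triangle_vector(r2)
        ok <- is.finite(v1) & is.finite(v2)
        if (sum(ok) < 3) stop("insufficient common pairs")
        stats::cor(v1[ok], v2[ok], method = method)
      }, error = function(e) NA_real_)
      if (is.na(r)) skipped <- skipped + 1L else rs <- c(rs, r)
    }
    if (length(rs) == 0) stop("all splits skipped: insufficient common pairs")
    mean_r <- mean(rs)
    list(reliability = spearman_brown(mean_r), mean_r = mean_r,
         n_skipped = skipped)
  })
}

#' Read / write triplet trial tables as TSV
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @export
write_triplet_trials <- function(trials, path) {
  validate_triplet_trials(trials)
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplet_trials
#' @export
read_triplet_trials <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_triplet_trials(tr)
  tr
}
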