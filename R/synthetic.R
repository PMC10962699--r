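#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the synthetic study in one validated list. The
#' defaults mirror the study conditions the pipeline is built for: the
#' 48-stimulus counterbalanced design; a ground-truth RDM dominated by
#' object type with a weaker shape contribution; near-deterministic triplet
#' choices (softmax temperature 0.05, 2% lapses); 20 participants; 200
#' voxels per simulated region with modest pattern noise; and paired
#' 24-cubed statistical maps whose blob centers are 4 voxels apart.
#'
#' @param design Stimulus design (default [build_default_design()]).
#' @param type_weight,shape_weight Nonnegative mixing weights of the type
#'   and shape model RDMs in the ground truth (not both zero).
#' @param decision_temperature Softmax temperature of the triplet choice
#'   rule; 0 gives deterministic argmax choices.
#' @param lapse_rate Probability of a uniformly random choice.
#' @param n_participants,n_trials_per_participant Behavioral sample sizes.
#' @param rt_median_ms Median of the log-normal reaction-time model.
#' @param rating_noise_sd,rating_participant_sd Trial- and participant-level
#'   rating noise (1-7 scale units).
#' @param n_rating_participants Participants per rating task.
#' @param n_voxels Voxels per simulated response pattern.
#' @param pattern_noise_sd Independent noise added to each pattern entry.
#' @param map_grid 3-D dimensions of simulated statistical maps.
#' @param blob_displacement Distance (voxels) between the two blob centers.
#' @param blob_sigma,blob_amplitude Gaussian blob width (voxels) and peak
#'   statistic value.
#' @param map_noise_sd Background noise SD of the statistic maps.
#' @param seed RNG seed for all generators.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(design = build_default_design(),
                             type_weight = 1, shape_weight = 0.25,
                             decision_temperature = 0.05, lapse_rate = 0.02,
                             n_participants = 20,
                             n_trials_per_participant = 42,
                             rt_median_ms = 800,
                             rating_noise_sd = 1, rating_participant_sd = 0.5,
                             n_rating_participants = 40,
                             n_voxels = 200, pattern_noise_sd = 0.2,
                             map_grid = c(24, 24, 24),
                             blob_displacement = 4, blob_sigma = 3,
                             blob_amplitude = 8, map_noise_sd = 0,
                             seed = 1) {
  validate_design(design)
  stopifnot(type_weight >= 0, shape_weight >= 0,
            lapse_rate >= 0, lapse_rate <= 1,
            decision_temperature >= 0,
            n_participants >= 1, n_trials_per_participant >= 1,
            n_voxels >= 1, length(map_grid) == 3, all(map_grid >= 1))
  if (type_weight == 0 && shape_weight == 0) {
    stop("type_weight and shape_weight cannot both be zero")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Ground-truth RDM of the synthetic study
#'
#' Weighted sum of the object-type and shape model RDMs, rescaled to
#' `[0, 1]`. Setting one weight to zero makes the truth rank-identical to
#' the other model.
#'
#' @param config A [generator_config()].
#' @return A model [rdm] with entries in `[0, 1]`.
#' @export
make_truth_rdm <- function(config = generator_config()) {
  ty <- as.matrix(make_type_model_rdm(config$design))
  sh <- as.matrix(make_shape_model_rdm(config$design))
  m <- config$type_weight * ty + config$shape_weight * sh
  m <- m / max(m)
  rdm(m, ids = config$design$stimulus_id, source = "model",
      distance_name = "synthetic ground truth")
}

#' Simulate odd-one-out triplet responses
#'
#' Choices follow a Luce-style softmax over "oddness": for triplet
#' `{i, j, k}` the oddness of `i` is `d(i, j) + d(i, k)` under the
#' ground-truth RDM, and the odd-one-out is sampled with probability
#' proportional to `exp(oddness / temperature)`; temperature 0 yields the
#' argmax. With probability `lapse_rate` the choice is uniformly random.
#' Reaction times are log-normal with the configured median (only the
#' median matters to the quality-control rule).
#'
#' With `full_enumeration = TRUE` every unique triplet is presented exactly
#' once, chunked into participant-sessions of `n_trials_per_participant`
#' (the last chunk may be short); otherwise each of the
#' `n_participants` participants receives that many randomly sampled
#' triplets.
#'
#' @param truth Ground-truth [rdm] over the design's stimuli.
#' @param config A [generator_config()].
#' @param full_enumeration Present each unique triplet exactly once.
#' @return A triplet trial data frame (see [validate_triplet_trials()]).
#' @export
simulate_triplet_responses <- function(truth, config = generator_config(),
                                       full_enumeration = TRUE) {
  D <- as.matrix(truth)
  ids <- rownames(D)
  n <- nrow(D)
  local_seed(config$seed, {
    if (full_enumeration) {
      trp <- enumerate_triplets(n)
      trp <- trp[sample.int(nrow(trp)), , drop = FALSE]
      cs <- config$n_trials_per_participant
      sess <- rep(seq_len(ceiling(nrow(trp) / cs)), each = cs)[
        seq_len(nrow(trp))]
    } else {
      nt <- config$n_participants * config$n_trials_per_participant
      trp <- enumerate_triplets(n)[
        sample.int(choose(n, 3), nt, replace = TRUE), , drop = FALSE]
      sess <- rep(seq_len(config$n_participants),
                  each = config$n_trials_per_participant)
    }
    nt <- nrow(trp)
    i <- trp[, 1]; j <- trp[, 2]; k <- trp[, 3]
    odd <- cbind(D[cbind(i, j)] + D[cbind(i, k)],
                 D[cbind(j, i)] + D[cbind(j, k)],
                 D[cbind(k, i)] + D[cbind(k, j)])
    pick <- if (config$decision_temperature == 0) {
      max.col(odd, ties.method = "first")
    } else {
      sc <- exp((odd - apply(odd, 1, max)) / config$decision_temperature)
      pr <- sc / rowSums(sc)
      u <- stats::runif(nt)
      1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
    }
    lapse <- stats::runif(nt) < config$lapse_rate
    pick[lapse] <- sample.int(3, sum(lapse), replace = TRUE)
    choice_idx <- trp[cbind(seq_len(nt), pick)]
    data.frame(
      participant_id = sprintf("p%03d", sess),
      session_id = sprintf("s%03d", sess),
      stim_a = ids[i], stim_b = ids[j], stim_c = ids[k],
      choice = ids[choice_idx],
      rt_ms = stats::rlnorm(nt, meanlog = log(config$rt_median_ms),
                            sdlog = 0.3),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a Likert rating task
#'
#' Each participant's rating of a stimulus is the true score plus a
#' participant-level offset and trial-level noise, rounded and clipped into
#' `{1..7}`.
#'
#' @param true_profile Named numeric vector of true per-stimulus scores
#'   (on the 1-7 scale).
#' @param config A [generator_config()].
#' @param task Task name recorded in the table.
#' @return A rating data frame (see [validate_ratings()]).
#' @export
simulate_ratings <- function(true_profile, config = generator_config(),
                             task = "task1") {
  stopifnot(!is.null(names(true_profile)), all(is.finite(true_profile)))
  np <- config$n_rating_participants
  ns <- length(true_profile)
  local_seed(config$seed, {
    bias <- stats::rnorm(np, sd = config$rating_participant_sd)
    val <- rep(true_profile, times = np) + rep(bias, each = ns) +
      stats::rnorm(np * ns, sd = config$rating_noise_sd)
    data.frame(
      participant_id = rep(sprintf("r%03d", seq_len(np)), each = ns),
      task = task,
      stimulus_id = rep(names(true_profile), times = np),
      rating = pmin(7L, pmax(1L, as.integer(round(val)))),
      stringsAsFactors = FALSE
    )
  })
}

## Nearest-PSD projection by eigenvalue clipping.
psd_project <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= -1e-10)) return(S)
  V <- e$vectors
  V %*% diag(pmax(e$values, 0)) %*% t(V)
}

#' Simulate per-participant voxel response patterns
#'
#' Each voxel's response profile across stimuli is drawn from a zero-mean
#' multivariate normal whose stimulus-by-stimulus covariance is
#' `1 - truth` (projected to the nearest positive-semidefinite matrix when
#' needed), with independent Gaussian noise of SD `pattern_noise_sd` added
#' per entry. As the voxel count grows and the noise shrinks, the empirical
#' 1 - r RDM of a participant's patterns converges in rank order to the
#' generating RDM.
#'
#' @param truth Ground-truth [rdm].
#' @param config A [generator_config()].
#' @return Named list of `n_participants` stimulus x voxel matrices.
#' @export
simulate_subject_patterns <- function(truth, config = generator_config()) {
  D <- as.matrix(truth)
  n <- nrow(D)
  S <- psd_project(1 - D)
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  out <- lapply(seq_len(config$n_participants), function(p) {
    local_seed(derive_seed(config$seed, p), {
      Z <- matrix(stats::rnorm(n * config$n_voxels), n, config$n_voxels)
      pat <- L %*% Z +
        matrix(stats::rnorm(n * config$n_voxels,
                            sd = config$pattern_noise_sd),
               n, config$n_voxels)
      rownames(pat) <- rownames(D)
      pat
    })
  })
  names(out) <- sprintf("p%03d", seq_len(config$n_participants))
  out
}

#' Simulate a pair of statistical maps with known overlap
#'
#' Two smooth Gaussian-profile blobs of peak statistic `blob_amplitude` and
#' width `blob_sigma`, with centers `blob_displacement` voxels apart along
#' the first axis, plus optional background noise. The noise-free voxel
#' sets exceeding the statistic value equivalent to `p_threshold`
#' (two-sided normal) define the true masks, whose Jaccard index is
#' returned as `true_overlap`.
#'
#' @param config A [generator_config()].
#' @param p_threshold Significance level defining the true blob extent.
#' @return List with `map_a`, `map_b` ([stat_map()]s), `mask` (all-`TRUE`
#'   anatomical mask), `true_overlap`, and the noise-free `truth_a`,
#'   `truth_b` masks.
#' @export
simulate_stat_maps <- function(config = generator_config(),
                               p_threshold = 0.05) {
  dims <- config$map_grid
  z_th <- stats::qnorm(1 - p_threshold / 2)
  if (config$blob_amplitude <= z_th) {
    stop("blob_amplitude too small to exceed the significance threshold")
  }
  r_th <- config$blob_sigma * sqrt(2 * log(config$blob_amplitude / z_th))
  center <- (dims + 1) / 2
  ca <- center; cb <- center
  ca[1] <- ca[1] - config$blob_displacement / 2
  cb[1] <- cb[1] + config$blob_displacement / 2
  if (ca[1] - r_th < 1 || cb[1] + r_th > dims[1] ||
      any(center[2:3] - r_th < 1) || any(center[2:3] + r_th > dims[2:3])) {
    stop("blob exits the grid; enlarge map_grid or reduce displacement")
  }
  gx <- seq_len(dims[1]); gy <- seq_len(dims[2]); gz <- seq_len(dims[3])
  blob <- function(cc) {
    d2 <- outer(outer((gx - cc[1])^2, (gy - cc[2])^2, `+`),
                (gz - cc[3])^2, `+`)
    config$blob_amplitude * exp(-d2 / (2 * config$blob_sigma^2))
  }
  sa <- blob(ca); sb <- blob(cb)
  truth_a <- sa > z_th; truth_b <- sb > z_th
  local_seed(config$seed, {
    if (config$map_noise_sd > 0) {
      sa <- sa + array(stats::rnorm(prod(dims), sd = config$map_noise_sd),
                       dims)
      sb <- sb + array(stats::rnorm(prod(dims), sd = config$map_noise_sd),
                       dims)
    }
    p_of <- function(s) array(2 * stats::pnorm(-abs(s)), dim(s))
    list(map_a = stat_map(sa, p_of(sa)),
         map_b = stat_map(sb, p_of(sb)),
         mask = array(TRUE, dims),
         true_overlap = jaccard_overlap(truth_a, truth_b)$jaccard,
         truth_a = truth_a, truth_b = truth_b)
  })
}
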