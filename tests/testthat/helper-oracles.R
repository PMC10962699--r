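# Brute-force reference implementations used as independent oracles.
# These deliberately use the slowest, most literal formulation of each
# computation so that agreement with the package's vectorized code is
# informative.

# Odd-one-out aggregation: explicit loop over trials and stimulus pairs.
oracle_aggregate <- function(trials, ids) {
  n <- length(ids)
  cooc <- matrix(0, n, n, dimnames = list(ids, ids))
  odd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (t in seq_len(nrow(trials))) {
    trio <- c(trials$stim_a[t], trials$stim_b[t], trials$stim_c[t])
    ch <- trials$choice[t]
    for (x in 1:2) for (y in (x + 1):3) {
      i <- trio[x]; j <- trio[y]
      cooc[i, j] <- cooc[i, j] + 1
      cooc[j, i] <- cooc[j, i] + 1
      if (ch == i || ch == j) {
        odd[i, j] <- odd[i, j] + 1
        odd[j, i] <- odd[j, i] + 1
      }
    }
  }
  d <- ifelse(cooc > 0, odd / cooc, NA_real_)
  diag(d) <- 0
  list(d = d, cooc = cooc)
}

# Connected components by union-find over all pairs of active voxels,
# joining those within face or edge adjacency (corners excluded).
oracle_clusters <- function(bm) {
  dims <- dim(bm)
  act <- which(bm != 0)
  if (length(act) == 0) return(integer(0))
  co <- arrayInd(act, dims)
  parent <- seq_along(act)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (a in seq_along(act)) {
    for (b in seq_along(act)) {
      if (a >= b) next
      d <- abs(co[a, ] - co[b, ])
      if (max(d) <= 1 && sum(d) >= 1 && sum(d) <= 2) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(act), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# Jaccard and unique fractions by explicit membership counting.
oracle_overlap <- function(a_idx, b_idx, grid_size) {
  in_a <- logical(grid_size); in_a[a_idx] <- TRUE
  in_b <- logical(grid_size); in_b[b_idx] <- TRUE
  uni <- sum(in_a | in_b)
  list(jaccard = sum(in_a & in_b) / uni,
       unique_a = sum(in_a & !in_b) / uni,
       unique_b = sum(in_b & !in_a) / uni)
}

# Subset R-squared from the normal equations, no lm machinery.
oracle_subset_r2 <- function(y, preds) {
  X <- cbind(1, preds)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Random symmetric zero-diagonal dissimilarity matrix.
random_rdm_matrix <- function(n, ids = paste0("x", seq_len(n))) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(ids, ids)
  m
}

# Small random triplet trial table over the given ids.
random_trials <- function(n_trials, ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trio <- t(replicate(n_trials, sample(ids, 3)))
  ch <- trio[cbind(seq_len(n_trials), sample(3, n_trials, replace = TRUE))]
  data.frame(participant_id = "p1", session_id = "s1",
             stim_a = trio[, 1], stim_b = trio[, 2], stim_c = trio[, 3],
             choice = ch, rt_ms = stats::runif(n_trials, 300, 2000),
             stringsAsFactors = FALSE)
}

tiny_design <- function(n = 6) {
  data.frame(stimulus_id = paste0("x", seq_len(n)),
             object_type = rep_len(c("FoodItem", "Animal", "SelfTool"), n),
             aspect_ratio = rep_len(c("high", "low"), n),
             display_label = "", stringsAsFactors = FALSE)
}
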