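test_that("triplet enumeration is complete, distinct, and deterministic", {
  expect_equal(nrow(enumerate_triplets(48)), 17296)
  expect_equal(nrow(enumerate_triplets(3)), 1)
  expect_equal(nrow(enumerate_triplets(5)), 10)
  t5 <- enumerate_triplets(5)
  expect_equal(anyDuplicated(t5), 0L)
  expect_true(all(t5[, 1] < t5[, 2] & t5[, 2] < t5[, 3]))
  expect_identical(t5, enumerate_triplets(5))
  expect_error(enumerate_triplets(2), "at least 3")
})

test_that("chunking partitions the permuted triplets with one remainder", {
  trip <- enumerate_triplets(48)
  ch <- chunk_trials(trip, 42, seed = 7)
  expect_length(ch, 412)
  expect_equal(vapply(ch, nrow, integer(1)),
               c(rep(42L, 411), 34L))
  recon <- do.call(rbind, ch)
  expect_equal(nrow(unique(recon)), 17296)
  ch10 <- chunk_trials(matrix(1:30, ncol = 3), 4, seed = 1)
  expect_equal(vapply(ch10, nrow, integer(1)), c(4L, 4L, 2L))
  expect_length(chunk_trials(matrix(1:126, ncol = 3), 42, seed = 1), 1)
  # the permutation is seed-controlled
  expect_identical(chunk_trials(trip, 42, seed = 7), ch)
})

test_that("qc filter drops uniform responders and extreme median RTs", {
  mk <- function(p, choice_pos, rts) {
    trio <- t(replicate(length(rts), sample(paste0("x", 1:6), 3)))
    ch <- if (is.na(choice_pos)) {
      trio[cbind(seq_along(rts), sample(3, length(rts), TRUE))]
    } else trio[, choice_pos]
    data.frame(participant_id = p, session_id = "s1",
               stim_a = trio[, 1], stim_b = trio[, 2], stim_c = trio[, 3],
               choice = ch, rt_ms = rts, stringsAsFactors = FALSE)
  }
  set.seed(1)
  trials <- rbind(mk("fast", NA, rep(150, 20)),
                  mk("slow", NA, rep(20000, 20)),
                  mk("uniform_pos", 2, runif(20, 500, 900)),
                  mk("good", NA, runif(20, 500, 900)))
  out <- qc_filter(trials)
  reasons <- setNames(out$report$reason, out$report$participant_id)
  expect_equal(reasons[["fast"]], "rt_low")
  expect_equal(reasons[["slow"]], "rt_high")
  expect_equal(reasons[["uniform_pos"]], "uniform")
  expect_equal(reasons[["good"]], "kept")
  expect_setequal(unique(out$kept$participant_id), "good")
  # always choosing the same stimulus is also uniform
  same_stim <- data.frame(participant_id = "ss", session_id = "s1",
                          stim_a = "x1", stim_b = paste0("x", 2:5),
                          stim_c = paste0("x", 3:6), choice = "x1",
                          rt_ms = 800)
  expect_equal(qc_filter(same_stim)$report$reason, "uniform")
})

test_that("aggregation matches hand-enumerated counts on worked examples", {
  tr <- data.frame(participant_id = "p1", session_id = "s1",
                   stim_a = "A", stim_b = "B", stim_c = "C",
                   choice = "C", rt_ms = 500)
  out <- aggregate_rdm(tr)
  m <- as.matrix(out$rdm)
  expect_equal(m["A", "B"], 0)
  expect_equal(m["A", "C"], 1)
  expect_equal(m["B", "C"], 1)
  tr2 <- rbind(tr, transform(tr, choice = "A"))
  expect_equal(as.matrix(aggregate_rdm(tr2)$rdm)["A", "B"], 0.5)
  # never-co-occurring pairs are NA with zero counts, not zero distance
  tr3 <- rbind(tr, transform(tr, stim_a = "D", choice = "B"))
  out3 <- aggregate_rdm(tr3)
  expect_true(is.na(as.matrix(out3$rdm)["A", "D"]))
  expect_equal(out3$counts["A", "D"], 0)
})

test_that("aggregation equals the brute-force oracle on random data", {
  ids <- paste0("x", 1:6)
  for (case in 1:25) {
    tr <- random_trials(sample(5:50, 1), ids, seed = 100 + case)
    got <- aggregate_rdm(tr, ids = ids)
    want <- oracle_aggregate(tr, ids)
    expect_equal(unname(as.matrix(got$rdm)), unname(want$d))
    expect_equal(unname(got$counts), unname(want$cooc))
  }
})

test_that("aggregated values are in [0,1], symmetric, order-invariant", {
  ids <- paste0("x", 1:8)
  tr <- random_trials(120, ids, seed = 5)
  out <- aggregate_rdm(tr, ids = ids)
  m <- as.matrix(out$rdm)
  off <- m[lower.tri(m)]
  expect_true(all(is.na(off) | (off >= 0 & off <= 1)))
  expect_equal(m, t(m))
  shuf <- tr[sample(nrow(tr)), ]
  expect_equal(as.matrix(aggregate_rdm(shuf, ids = ids)$rdm), m)
})

test_that("spearman_brown has the textbook fixed points and pole", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_error(spearman_brown(-1), "undefined")
})

test_that("split-half reliability hits its limiting values", {
  ids <- paste0("x", 1:8)
  # two identical sessions: the session split is forced to correlate a
  # dataset with an exact copy of itself
  base <- random_trials(150, ids, seed = 11)
  copy <- base
  copy$session_id <- "s2"
  rel <- split_half_reliability(rbind(base, copy), n_splits = 5, seed = 3,
                                split_unit = "session")
  expect_equal(rel$mean_r, 1)
  expect_equal(rel$reliability, 1)
  # zero decision noise, many trials: corrected reliability near 1
  d <- tiny_design(8)
  cfg <- generator_config(design = d, decision_temperature = 0,
                          lapse_rate = 0, seed = 2,
                          n_trials_per_participant = 56)
  truth <- rdm(random_rdm_matrix(8, d$stimulus_id), source = "model")
  tr <- do.call(rbind, lapply(1:30, function(i) {
    simulate_triplet_responses(truth,
      generator_config(design = d, decision_temperature = 0, lapse_rate = 0,
                       seed = i, n_trials_per_participant = 56))
  }))
  rel0 <- split_half_reliability(tr, n_splits = 30, seed = 4,
                                 ids = d$stimulus_id)
  expect_gt(rel0$reliability, 0.95)
  # pure-noise choices over many pairs: reliability near 0
  cfgN <- generator_config(lapse_rate = 1, seed = 9)
  truthN <- make_truth_rdm(cfgN)
  trN <- simulate_triplet_responses(truthN, cfgN, full_enumeration = TRUE)
  relN <- split_half_reliability(trN, n_splits = 20, seed = 4,
                                 ids = cfgN$design$stimulus_id)
  expect_lt(abs(relN$mean_r), 0.1)
})

test_that("trial tables round-trip through TSV and are validated", {
  tr <- random_trials(20, paste0("x", 1:6), seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_triplet_trials(tr, f)
  expect_equal(read_triplet_trials(f)$choice, tr$choice)
  bad <- tr; bad$choice[1] <- "zzz"
  expect_error(validate_triplet_trials(bad), "member of its triplet")
  bad2 <- tr; bad2$stim_b[1] <- bad2$stim_a[1]
  expect_error(validate_triplet_trials(bad2), "distinct")
})
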