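test_that("turn segmentation follows the gap/overlap rules", {
  # alternation with a 200 ms gap
  ts1 <- segment_turns(toy_log(list("mother", 0, 1000),
                               list("child", 1200, 2000)))
  expect_equal(nrow(ts1$turns), 2L)
  expect_equal(ts1$transitions$type, "alternation")
  expect_equal(ts1$transitions$gap_ms, 200)

  # same-speaker events within the gap merge into one turn
  ts2 <- segment_turns(toy_log(list("mother", 0, 1000),
                               list("mother", 1500, 2000)))
  expect_equal(nrow(ts2$turns), 1L)
  expect_equal(ts2$turns$n_utterances, 2L)
  expect_equal(sum(ts2$transitions$type == "alternation"), 0L)

  # overlap: partner starts before the current turn ends
  ts3 <- segment_turns(toy_log(list("mother", 0, 1000),
                               list("child", 800, 1800)))
  expect_equal(ts3$transitions$type, "overlap")
  expect_equal(ts3$transitions$overlap_ms, 200)

  # > 3000 ms pause breaks the chain without alternation credit
  ts4 <- segment_turns(toy_log(list("mother", 0, 1000),
                               list("child", 4500, 5000)))
  expect_equal(ts4$transitions$type, "long_pause_break")

  # same speaker after a long pause starts a new turn
  ts5 <- segment_turns(toy_log(list("mother", 0, 1000),
                               list("mother", 4500, 5000)))
  expect_equal(nrow(ts5$turns), 2L)
  expect_equal(ts5$transitions$type, "same_speaker_continuation")
})

test_that("turn count is invariant to splitting an event at gap zero", {
  log1 <- toy_log(list("mother", 0, 1000), list("child", 1300, 2500),
                  list("mother", 2800, 4000))
  log2 <- toy_log(list("mother", 0, 600), list("mother", 600, 1000),
                  list("child", 1300, 2500), list("mother", 2800, 4000))
  expect_equal(nrow(segment_turns(log2)$turns),
               nrow(segment_turns(log1)$turns))
})

test_that("segmentation matches the independent reference on random logs", {
  set.seed(41)
  for (rep in 1:20) {
    n_ev <- sample(2:25, 1)
    onset <- cumsum(runif(n_ev, 0, 2500))
    dur <- runif(n_ev, 100, 2800)
    ev <- data.frame(speaker = sample(c("mother", "child"), n_ev, TRUE),
                     onset_ms = onset, offset_ms = onset + dur,
                     code = "vocalization", stringsAsFactors = FALSE)
    log <- suppressWarnings(make_coding_log("r", ev))
    got <- segment_turns(log)
    ref <- ref_segment(log$events)
    expect_equal(nrow(got$turns), ref$n_turns)
    got_types <- table(factor(got$transitions$type, names(ref$types)))
    expect_equal(as.numeric(got_types), as.numeric(ref$types))
    expect_equal(sum(got$transitions$overlap_ms), ref$total_overlap)
  }
})

test_that("composite scores use equally weighted signed counts", {
  mk <- function(codes) {
    onset <- seq(0, by = 1000, length.out = length(codes))
    toy_log2 <- make_coding_log("c", data.frame(
      speaker = rep(c("mother", "child"), length.out = length(codes)),
      onset_ms = onset, offset_ms = onset + 800, code = codes,
      stringsAsFactors = FALSE))
    composite_scores(toy_log2)
  }
  sc <- mk(c(rep("alternating_turn", 10), rep("long_turn", 4)))
  expect_equal(sc$turn_taking, 7)                      # mean(10, 4)
  sc2 <- mk(c(rep("interrupts", 2), "simultaneous"))
  expect_equal(sc2$intrusiveness, 1)                   # mean(0, 2, 1)
  sc3 <- mk(c(rep("relevant", 6), rep("irrelevant", 2)))
  expect_equal(sc3$relevance, 2)                       # mean(6, -2)
  sc4 <- mk(c(rep("contingent", 3), rep("noncontingent", 5)))
  expect_equal(sc4$contingency, -1)                    # mean(3, -5)

  empty <- make_coding_log("e", data.frame(speaker = character(),
                                           onset_ms = numeric(),
                                           offset_ms = numeric(),
                                           code = character()))
  sc0 <- composite_scores(empty)
  expect_equal(sc0$turn_taking, 0)
  expect_equal(sc0$relevance, 0)
  expect_equal(sc0$intrusiveness, 0)
  expect_equal(sc0$mean_turn_duration_ms, 0)

  # row-order permutation invariance (events are sorted on construction)
  ev <- data.frame(speaker = c("mother", "child", "mother"),
                   onset_ms = c(0, 1200, 2600),
                   offset_ms = c(1000, 2200, 3600),
                   code = c("alternating_turn", "relevant", "long_turn"),
                   stringsAsFactors = FALSE)
  a <- composite_scores(make_coding_log("p", ev))
  b <- composite_scores(make_coding_log("p", ev[c(3, 1, 2), ]))
  expect_equal(scores_row(a), scores_row(b))
})

test_that("ICC(2,1) matches the ANOVA decomposition", {
  ratings <- cbind(r1 = c(9, 6, 8, 7, 10, 6),
                   r2 = c(2, 1, 4, 1, 5, 2))
  got <- icc(ratings)
  # independent oracle: mean squares from aov()
  df <- data.frame(y = c(ratings),
                   subj = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  ref <- (ms[1] - ms[3]) / (ms[1] + (2 - 1) * ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(got$value, ref, tolerance = 1e-12)
  expect_equal(got$msr, ms[1], tolerance = 1e-12)
  expect_equal(got$mse, ms[3], tolerance = 1e-12)

  # identical raters -> 1
  same <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc(same)$value, 1)
  # constant offset penalized under absolute agreement
  off <- cbind(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_lt(icc(off)$value, 1)
  expect_gt(icc(off)$value, 0)
  expect_error(icc(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc(cbind(1:3)), ">= 2")
})

test_that("weighted kappa matches the direct confusion-matrix formula", {
  r1 <- c(1, 2, 3, 1, 2, 3, 3, 2, 1, 1)
  r2 <- c(1, 2, 2, 1, 3, 3, 3, 1, 1, 2)
  got <- weighted_kappa(r1, r2)
  # independent direct computation
  k <- 3
  O <- matrix(0, k, k)
  for (i in seq_along(r1)) O[r1[i], r2[i]] <- O[r1[i], r2[i]] + 1
  w <- abs(outer(1:k, 1:k, `-`)) / (k - 1)
  E <- outer(rowSums(O), colSums(O)) / length(r1)
  ref <- 1 - sum(w * O) / sum(w * E)
  expect_equal(got, ref, tolerance = 1e-12)

  expect_equal(weighted_kappa(r1, r1), 1)
  set.seed(42)
  a <- sample(1:4, 10000, TRUE); b <- sample(1:4, 10000, TRUE)
  expect_lt(abs(weighted_kappa(a, b)), 0.05)
  expect_error(weighted_kappa(rep(1, 5), rep(1, 5)), "single category")
  expect_error(weighted_kappa(1:3, 1:4), "length")
})
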