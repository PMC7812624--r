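# Conversation-pattern scoring: segmentation of coded utterance events into
# turns, per-dyad composite scores (turn-taking, relevance, contingency,
# intrusiveness), and inter-rater reliability statistics.

#' Segment coded utterance events into turns
#'
#' A turn is one speaker's speech bounded by pauses or by the other
#' speaker's speech. Consecutive events by the same speaker separated by at
#' most `max_gap_ms` merge into a single turn. A speaker change with a gap
#' in `[min_gap_ms, max_gap_ms]` is an alternation; a change after a longer
#' pause is a `long_pause_break` (no alternation credit); a same-speaker
#' restart after a longer pause is a `same_speaker_continuation`; a partner
#' onset before the current offset is an `overlap` transition with the
#' overlap duration recorded.
#'
#' @param log a `coding_log`.
#' @param max_gap_ms maximal within-turn / alternation gap (default 3000).
#' @param min_gap_ms minimal alternation gap (default 0).
#' @return a `turn_sequence`: list with data frames `turns` (speaker,
#'   start_ms, end_ms, n_utterances) and `transitions` (from_turn, to_turn,
#'   gap_ms, type, overlap_ms).
#' @export
segment_turns <- function(log, max_gap_ms = 3000, min_gap_ms = 0) {
  stopifnot(inherits(log, "coding_log"))
  ev <- log$events
  turns <- data.frame(speaker = character(), start_ms = numeric(),
                      end_ms = numeric(), n_utterances = integer(),
                      stringsAsFactors = FALSE)
  transitions <- data.frame(from_turn = integer(), to_turn = integer(),
                            gap_ms = numeric(), type = character(),
                            overlap_ms = numeric(), stringsAsFactors = FALSE)
  if (nrow(ev)) {
    cur <- list(speaker = ev$speaker[1], start = ev$onset_ms[1],
                end = ev$offset_ms[1], n = 1L)
    for (i in seq_len(nrow(ev))[-1]) {
      gap <- ev$onset_ms[i] - cur$end
      same <- ev$speaker[i] == cur$speaker
      if (same && gap <= max_gap_ms) {
        cur$end <- max(cur$end, ev$offset_ms[i])
        cur$n <- cur$n + 1L
        next
      }
      turns[nrow(turns) + 1L, ] <- list(cur$speaker, cur$start, cur$end, cur$n)
      type <- if (!same && gap < min_gap_ms) "overlap"
        else if (!same && gap <= max_gap_ms) "alternation"
        else if (!same) "long_pause_break"
        else "same_speaker_continuation"
      overlap_ms <- if (type == "overlap") {
        min(cur$end, ev$offset_ms[i]) - ev$onset_ms[i]
      } else 0
      transitions[nrow(transitions) + 1L, ] <-
        list(nrow(turns), nrow(turns) + 1L, gap, type, overlap_ms)
      cur <- list(speaker = ev$speaker[i], start = ev$onset_ms[i],
                  end = ev$offset_ms[i], n = 1L)
    }
    turns[nrow(turns) + 1L, ] <- list(cur$speaker, cur$start, cur$end, cur$n)
  }
  structure(list(turns = turns, transitions = transitions,
                 max_gap_ms = max_gap_ms, min_gap_ms = min_gap_ms),
            class = "turn_sequence")
}

#' @export
print.turn_sequence <- function(x, ...) {
  cat(sprintf("<turn_sequence> %d turns, %d transitions (%d alternations)\n",
              nrow(x$turns), nrow(x$transitions),
              sum(x$transitions$type == "alternation")))
  invisible(x)
}

#' Per-dyad conversation composite scores
#'
#' Each category composite is the equally-weighted mean of its sub-category
#' counts: turn-taking = mean(alternating, long turns); relevance =
#' mean(relevant, -irrelevant); contingency = mean(contingent,
#' -noncontingent); intrusiveness = mean(fails-to-leave-time, interrupts,
#' simultaneous). The "non-"/"ir-" sub-categories enter negatively so that
#' higher relevance/contingency means a more cohesive conversation; this
#' sign convention is recorded in the result.
#'
#' @param log a `coding_log`.
#' @param turns optional `turn_sequence` from [segment_turns()]; computed
#'   from `log` if missing. Supplies turn/overlap durations.
#' @return a `dyad_scores` list: composites, `mean_turn_duration_ms`,
#'   `total_overlap_ms` and the raw sub-category `counts`.
#' @export
composite_scores <- function(log, turns = NULL) {
  stopifnot(inherits(log, "coding_log"))
  if (is.null(turns)) turns <- segment_turns(log)
  cnt <- function(code) sum(log$events$code == code)
  counts <- c(
    alternating_turn = cnt("alternating_turn"), long_turn = cnt("long_turn"),
    relevant = cnt("relevant"), irrelevant = cnt("irrelevant"),
    contingent = cnt("contingent"), noncontingent = cnt("noncontingent"),
    no_time_for_response = cnt("no_time_for_response"),
    interrupts = cnt("interrupts"), simultaneous = cnt("simultaneous")
  )
  dur <- turns$turns$end_ms - turns$turns$start_ms
  structure(list(
    dyad_id = log$dyad_id,
    turn_taking = mean(c(counts["alternating_turn"], counts["long_turn"])),
    relevance = mean(c(counts["relevant"], -counts["irrelevant"])),
    contingency = mean(c(counts["contingent"], -counts["noncontingent"])),
    intrusiveness = mean(c(counts["no_time_for_response"],
                           counts["interrupts"], counts["simultaneous"])),
    mean_turn_duration_ms = if (length(dur)) mean(dur) else 0,
    total_overlap_ms = sum(turns$transitions$overlap_ms),
    counts = counts,
    sign_convention = "negative counts for irrelevant/noncontingent"
  ), class = "dyad_scores")
}

#' @export
print.dyad_scores <- function(x, ...) {
  cat(sprintf(
    "<dyad_scores> %s: turn-taking %.1f, relevance %.1f, contingency %.1f, intrusiveness %.2f\n",
    x$dyad_id, x$turn_taking, x$relevance, x$contingency, x$intrusiveness))
  invisible(x)
}

#' Flatten dyad scores to a one-row data frame (the TSV layout)
#'
#' @param x a `dyad_scores`.
#' @return one-row data frame.
#' @export
scores_row <- function(x) {
  stopifnot(inherits(x, "dyad_scores"))
  cbind(
    data.frame(dyad_id = x$dyad_id, turn_taking = x$turn_taking,
               relevance = x$relevance, contingency = x$contingency,
               intrusiveness = x$intrusiveness,
               mean_turn_duration_ms = x$mean_turn_duration_ms,
               total_overlap_ms = x$total_overlap_ms,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(x$counts))
  )
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation from the ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 2 of each), no missing cells.
#' @return list with `value`, and mean squares `msr` (rows/subjects),
#'   `msc` (columns/raters), `mse` (residual).
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stop("ICC requires a complete rating table")
  grand <- mean(ratings)
  if (isTRUE(all.equal(stats::var(as.vector(ratings)), 0))) {
    stop("ICC undefined: zero total variance")
  }
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  value <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(value = value, msr = msr, msc = msc, mse = mse)
}

#' Weighted Cohen's kappa
#'
#' `kappa_w = 1 - sum(w * O) / sum(w * E)` with linear (or quadratic)
#' disagreement weights on the ordinal category grid and the
#' marginal-product expected table.
#'
#' @param r1,r2 equal-length vectors of ordinal categories (factor levels
#'   define the order; otherwise sorted unique values of both raters).
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(r1, r2, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(r1) != length(r2)) stop("rating vectors differ in length")
  lev <- if (is.factor(r1)) levels(r1) else sort(unique(c(r1, r2)))
  if (length(lev) < 2L) {
    stop("weighted kappa undefined: a single category present in both raters")
  }
  f1 <- factor(r1, levels = lev); f2 <- factor(r2, levels = lev)
  O <- table(f1, f2)
  n <- sum(O)
  k <- length(lev)
  d <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  w <- if (weights == "linear") d else d^2
  E <- outer(rowSums(O), colSums(O)) / n
  denom <- sum(w * E)
  if (denom == 0) stop("weighted kappa undefined: degenerate marginals")
  1 - sum(w * O) / denom
}
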