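# Region-of-interest labels for the default 16-channel cap.
ROI_LEVELS <- c("dlPFC-L", "dlPFC-R", "TPJ-L", "TPJ-R")

# Conversation-pattern code vocabulary (categories and sub-categories of the
# coding scheme: turn-taking, relevance, contingency, intrusiveness, plus the
# raw vocalization events turn segmentation consumes).
CODING_VOCAB <- c(
  "alternating_turn", "long_turn",
  "relevant", "irrelevant",
  "contingent", "noncontingent",
  "no_time_for_response", "interrupts", "simultaneous",
  "vocalization"
)

#' Build the default 16-channel, four-ROI probe montage
#'
#' Constructs the standard hyperscanning cap layout used throughout the
#' package: four 2x2 probe sets (8 sources, 8 detectors) yielding 16
#' measurement channels at 30 mm source-detector separation, grouped into
#' four regions of interest -- left/right dorsolateral prefrontal cortex
#' (probes around AF3/AF4) and left/right temporo-parietal junction (around
#' CP5/CP6). Channels 1-4, 5-8, 9-12 and 13-16 map to dlPFC-L, dlPFC-R,
#' TPJ-L and TPJ-R respectively; this per-channel assignment is a declared
#' convention of the package and can be overridden via [make_montage()].
#'
#' @return An object of class `fnirs_montage`: a list with data frames
#'   `sources`, `detectors` and `channels` (columns `channel_id`,
#'   `source_id`, `detector_id`, `roi`, `separation_mm`).
#' @export
#' @examples
#' m <- build_default_montage()
#' table(m$channels$roi)
build_default_montage <- function() {
  rois <- rep(ROI_LEVELS, each = 4L)
  # each 2x2 probe set: 2 sources, 2 detectors, 4 channels
  probe_set <- (seq_len(16L) - 1L) %/% 4L          # 0..3
  within_set <- (seq_len(16L) - 1L) %% 4L          # 0..3
  source_id <- probe_set * 2L + ifelse(within_set %in% c(0L, 1L), 1L, 2L)
  detector_id <- probe_set * 2L + ifelse(within_set %in% c(0L, 2L), 1L, 2L)
  anchors <- c("AF3", "AF4", "CP5", "CP6")
  sources <- data.frame(
    source_id = 1:8,
    label = paste0("S", 1:8, "_", rep(anchors, each = 2L)),
    stringsAsFactors = FALSE
  )
  detectors <- data.frame(
    detector_id = 1:8,
    label = paste0("D", 1:8, "_", rep(anchors, each = 2L)),
    stringsAsFactors = FALSE
  )
  channels <- data.frame(
    channel_id = 1:16,
    source_id = source_id,
    detector_id = detector_id,
    roi = rois,
    separation_mm = 30,
    stringsAsFactors = FALSE
  )
  make_montage(sources, detectors, channels)
}

#' Construct and validate a probe montage
#'
#' @param sources data frame with columns `source_id`, `label`.
#' @param detectors data frame with columns `detector_id`, `label`.
#' @param channels data frame with columns `channel_id`, `source_id`,
#'   `detector_id`, `roi`, `separation_mm`.
#' @return `fnirs_montage` object.
#' @export
make_montage <- function(sources, detectors, channels) {
  stopifnot(is.data.frame(sources), is.data.frame(detectors),
            is.data.frame(channels))
  req <- c("channel_id", "source_id", "detector_id", "roi", "separation_mm")
  missing_cols <- setdiff(req, names(channels))
  if (length(missing_cols)) {
    stop("montage channels lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(channels$source_id %in% sources$source_id)) {
    stop("montage references unknown source ids")
  }
  if (!all(channels$detector_id %in% detectors$detector_id)) {
    stop("montage references unknown detector ids")
  }
  if (anyDuplicated(channels$channel_id)) {
    stop("duplicated channel ids in montage")
  }
  structure(
    list(sources = sources, detectors = detectors, channels = channels),
    class = "fnirs_montage"
  )
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("<fnirs_montage> ", nrow(x$channels), " channels, ",
      nrow(x$sources), " sources, ", nrow(x$detectors), " detectors\n",
      sep = "")
  print(table(ROI = x$channels$roi))
  invisible(x)
}

n_channels <- function(montage) nrow(montage$channels)

montage_equal <- function(a, b) {
  isTRUE(all.equal(a$channels[c("channel_id", "source_id", "detector_id",
                                "roi", "separation_mm")],
                   b$channels[c("channel_id", "source_id", "detector_id",
                                "roi", "separation_mm")],
                   check.attributes = FALSE))
}

#' Construct a raw intensity recording
#'
#' @param intensity numeric array `[2 wavelengths x n_channels x n_samples]`
#'   of strictly positive detector intensities (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param subject_role `"mother"` or `"child"`.
#' @param dyad_id dyad identifier.
#' @param montage an `fnirs_montage`; defaults to [build_default_montage()].
#' @param wavelengths_nm the two measurement wavelengths, default `c(760, 850)`.
#' @return An object of class `fnirs_recording`.
#' @export
make_recording <- function(intensity, fs = 7.81,
                           subject_role = c("mother", "child"),
                           dyad_id = "dyad1",
                           montage = build_default_montage(),
                           wavelengths_nm = c(760, 850)) {
  subject_role <- match.arg(subject_role)
  if (!is.array(intensity) || length(dim(intensity)) != 3L || dim(intensity)[1] != 2L) {
    stop("intensity must be a [2 x n_channels x n_samples] array")
  }
  if (dim(intensity)[2] != n_channels(montage)) {
    stop("intensity has ", dim(intensity)[2], " channels but montage declares ",
         n_channels(montage))
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  bad <- which(intensity <= 0 | !is.finite(intensity), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-positive/non-finite intensity at wavelength %d, channel %d, sample %d",
      bad[1, 1], bad[1, 2], bad[1, 3]))
  }
  structure(
    list(subject_role = subject_role, dyad_id = dyad_id, fs = fs,
         wavelengths_nm = wavelengths_nm, intensity = intensity,
         montage = montage),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<fnirs_recording> %s of %s: %d wl x %d ch x %d samples @ %.2f Hz (%.1f s)\n",
              x$subject_role, x$dyad_id, d[1], d[2], d[3], x$fs, d[3] / x$fs))
  invisible(x)
}

rec_n_samples <- function(rec) dim(rec$intensity)[3]

#' Pair a mother and a child recording into a dyad
#'
#' Both members must share `dyad_id`, sampling rate and montage. If the two
#' recordings differ in length, both are truncated to the shorter series
#' (no data are invented by padding).
#'
#' @param mother,child `fnirs_recording` objects with roles mother/child.
#' @return An object of class `dyad_recording` with elements `mother`,
#'   `child` and `duration_s`.
#' @export
pair_dyad <- function(mother, child) {
  stopifnot(inherits(mother, "fnirs_recording"), inherits(child, "fnirs_recording"))
  if (mother$subject_role != "mother" || child$subject_role != "child") {
    stop("pair_dyad() expects a mother recording and a child recording")
  }
  if (!identical(mother$dyad_id, child$dyad_id)) {
    stop("dyad_id mismatch: ", mother$dyad_id, " vs ", child$dyad_id)
  }
  if (!isTRUE(all.equal(mother$fs, child$fs))) stop("sampling rate mismatch")
  if (!montage_equal(mother$montage, child$montage)) stop("montage mismatch")
  n <- min(rec_n_samples(mother), rec_n_samples(child))
  mother$intensity <- mother$intensity[, , seq_len(n), drop = FALSE]
  child$intensity <- child$intensity[, , seq_len(n), drop = FALSE]
  structure(
    list(mother = mother, child = child, duration_s = n / mother$fs),
    class = "dyad_recording"
  )
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> %s: %.1f s @ %.2f Hz, %d channels\n",
              x$mother$dyad_id, x$duration_s, x$mother$fs,
              n_channels(x$mother$montage)))
  invisible(x)
}

#' Construct a conversation coding log
#'
#' Events are sorted by onset; codes are validated against the coding
#' vocabulary; overlapping same-speaker events of the same code are merged
#' with a warning.
#'
#' @param dyad_id dyad identifier.
#' @param events data frame with columns `speaker` (mother/child),
#'   `onset_ms`, `offset_ms`, `code`.
#' @return An object of class `coding_log`.
#' @export
make_coding_log <- function(dyad_id, events) {
  req <- c("speaker", "onset_ms", "offset_ms", "code")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("coding log lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  events <- as.data.frame(events)[req]
  if (nrow(events)) {
    bad_code <- setdiff(unique(events$code), CODING_VOCAB)
    if (length(bad_code)) {
      stop("unknown conversation code(s): ", paste(bad_code, collapse = ", "))
    }
    if (!all(events$speaker %in% c("mother", "child"))) {
      stop("speaker must be 'mother' or 'child'")
    }
    if (any(events$offset_ms <= events$onset_ms)) {
      stop("event offset_ms must exceed onset_ms")
    }
    events <- events[order(events$onset_ms, events$offset_ms), , drop = FALSE]
    events <- merge_same_speaker_overlaps(events)
    rownames(events) <- NULL
  }
  structure(list(dyad_id = dyad_id, events = events), class = "coding_log")
}

# Overlapping identical-speaker, identical-code events are coder slips:
# merge into one spanning event (warning emitted).
merge_same_speaker_overlaps <- function(events) {
  if (nrow(events) < 2L) return(events)
  keep <- rep(TRUE, nrow(events))
  merged_any <- FALSE
  i <- 1L
  while (i < nrow(events)) {
    j <- i + 1L
    while (j <= nrow(events) && keep[i]) {
      if (keep[j] &&
          events$speaker[j] == events$speaker[i] &&
          events$code[j] == events$code[i] &&
          events$onset_ms[j] < events$offset_ms[i]) {
        events$offset_ms[i] <- max(events$offset_ms[i], events$offset_ms[j])
        keep[j] <- FALSE
        merged_any <- TRUE
      } else if (events$onset_ms[j] >= events$offset_ms[i]) {
        break
      }
      j <- j + 1L
    }
    i <- i + 1L
  }
  if (merged_any) {
    warning("merged overlapping identical-speaker events in coding log")
    events <- events[keep, , drop = FALSE]
  }
  events
}

#' @export
print.coding_log <- function(x, ...) {
  cat(sprintf("<coding_log> %s: %d events\n", x$dyad_id, nrow(x$events)))
  invisible(x)
}
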