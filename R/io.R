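# Recording and coding-log file formats.
#
# Recording TSV dialect: comment-style header lines "#key<TAB>value" carrying
# fs, role, dyad_id and wavelengths, then a column-header row and one row per
# sample with columns w<wavelength>_ch<k>, e.g. w760_ch1 ... w850_ch16.

#' Write a raw recording to the documented TSV dialect
#'
#' @param rec an `fnirs_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fnirs_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#fs\t", format(rec$fs, digits = 15)),
    paste0("#role\t", rec$subject_role),
    paste0("#dyad_id\t", rec$dyad_id),
    paste0("#wavelengths\t", paste(rec$wavelengths_nm, collapse = ","))
  ), con)
  nc <- dim(rec$intensity)[2]
  cols <- c(paste0("w", rec$wavelengths_nm[1], "_ch", seq_len(nc)),
            paste0("w", rec$wavelengths_nm[2], "_ch", seq_len(nc)))
  # samples x (2*nc): wavelength-major column blocks
  mat <- cbind(t(rec$intensity[1, , , drop = TRUE]),
               t(rec$intensity[2, , , drop = TRUE]))
  if (dim(rec$intensity)[3] == 1L) {  # t() dropped dims for single sample
    mat <- rbind(c(rec$intensity[1, , 1], rec$intensity[2, , 1]))
  }
  colnames(mat) <- cols
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a raw recording
#'
#' Reads the TSV dialect written by [write_recording()]. SNIRF input is not
#' supported by this build; requesting it raises an informative error.
#'
#' @param path input file path.
#' @param dialect `"tsv"` (default) or `"snirf"`.
#' @param montage montage to attach; default [build_default_montage()].
#' @return An `fnirs_recording`.
#' @export
read_recording <- function(path, dialect = c("tsv", "snirf"),
                           montage = build_default_montage()) {
  dialect <- match.arg(dialect)
  if (dialect == "snirf") {
    stop("SNIRF input is not supported by this build; convert to the TSV dialect")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || any(diff(hdr_idx) != 1L) || hdr_idx[1] != 1L) {
    stop("malformed recording header in ", path)
  }
  hdr <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)
  if (any(lengths(hdr) != 2L)) stop("malformed recording header in ", path)
  meta <- stats::setNames(vapply(hdr, `[`, "", 2L), vapply(hdr, `[`, "", 1L))
  for (k in c("fs", "role", "dyad_id", "wavelengths")) {
    if (!k %in% names(meta)) stop("recording header missing key '", k, "'")
  }
  fs <- as.numeric(meta[["fs"]])
  wl <- as.numeric(strsplit(meta[["wavelengths"]], ",", fixed = TRUE)[[1]])
  if (length(wl) != 2L || anyNA(wl)) stop("malformed wavelengths header")
  body <- lines[-hdr_idx]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  nc <- length(cols) / 2L
  expected <- c(paste0("w", wl[1], "_ch", seq_len(nc)),
                paste0("w", wl[2], "_ch", seq_len(nc)))
  if (!identical(cols, expected)) stop("unexpected column layout in ", path)
  mat <- matrix(as.numeric(unlist(strsplit(body[-1], "\t", fixed = TRUE))),
                ncol = length(cols), byrow = TRUE)
  nt <- nrow(mat)
  intensity <- array(NA_real_, c(2L, nc, nt))
  intensity[1, , ] <- t(mat[, seq_len(nc), drop = FALSE])
  intensity[2, , ] <- t(mat[, nc + seq_len(nc), drop = FALSE])
  make_recording(intensity, fs = fs, subject_role = meta[["role"]],
                 dyad_id = meta[["dyad_id"]], montage = montage,
                 wavelengths_nm = wl)
}

#' Read a conversation coding log TSV
#'
#' Expects columns `dyad_id`, `speaker`, `onset_ms`, `offset_ms`, `code`.
#' Events are sorted by onset and codes validated against the coding
#' vocabulary.
#'
#' @param path input TSV path.
#' @return A `coding_log`.
#' @export
read_coding_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("dyad_id", "speaker", "onset_ms", "offset_ms", "code")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("coding log TSV lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ids <- unique(df$dyad_id)
  if (length(ids) > 1L) stop("coding log mixes dyads: ", paste(ids, collapse = ", "))
  make_coding_log(if (length(ids)) ids else "unknown",
                  df[c("speaker", "onset_ms", "offset_ms", "code")])
}

#' Write a conversation coding log TSV
#'
#' @param log a `coding_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coding_log <- function(log, path) {
  stopifnot(inherits(log, "coding_log"))
  df <- cbind(dyad_id = log$dyad_id, log$events)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
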