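# Pipeline orchestration: a validated config (YAML), deterministic
# execution of simulate/load -> preprocess -> coherence -> surrogates ->
# behavior -> model ladder, TSV outputs and a JSON run manifest carrying
# the config hash.

#' Default pipeline configuration
#'
#' Every analysis parameter in one place: 0.01-0.5 Hz second-order
#' zero-phase Butterworth band-pass, DPF 6 (mother) / 5.5 (child),
#' 0.06-0.15 Hz analysis band, 30-s epochs, Morlet omega0 = 6 with
#' dj = 1/12, and 1000 random-pair surrogate draws.
#'
#' @return nested list of defaults, amendable via [pipeline_config()].
#' @export
default_config <- function() {
  list(
    chromophore = "HbO",
    preprocess = list(iqr_alpha = 1.5, cardiac_band_hz = c(0.6, 1.5),
                      power_ratio_min = 0.2, low_hz = 0.01, high_hz = 0.5,
                      qc = TRUE),
    wtc = list(band_hz = c(0.06, 0.15), epoch_len_s = 30, omega0 = 6,
               dj = 1 / 12),
    surrogate = list(kind = "random_pair", n_draws = 1000L, seed = 1L),
    model = list(ladder_through = 7L, roi = NULL),
    simulate = list(enabled = TRUE, n_dyads = 4L, seed = 1L,
                    duration_s = 240, fs = 7.81, coupling_base = 0.45,
                    coupling_slope = 0.01, behavior_link = 0.02),
    input = list(recordings = NULL, logs = NULL),
    out_dir = "dyadsync_out",
    seed = 1L
  )
}

#' Load and validate a pipeline configuration
#'
#' @param path YAML file path, or NULL.
#' @param overrides list merged over the file/defaults.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  fs <- if (isTRUE(cfg$simulate$enabled)) cfg$simulate$fs else 7.81
  band <- as.numeric(cfg$wtc$band_hz)
  if (length(band) != 2 || !(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop("invalid analysis band: must satisfy 0 < low < high < fs/2")
  }
  cfg$wtc$band_hz <- band
  if (cfg$wtc$epoch_len_s <= 0) stop("epoch_len_s must be positive")
  if (isTRUE(cfg$simulate$enabled)) {
    dur <- cfg$simulate$duration_s
    if (abs(dur / cfg$wtc$epoch_len_s - round(dur / cfg$wtc$epoch_len_s)) > 1e-9) {
      warning("duration is not an integer number of epochs; last partial epoch dropped")
    }
  }
  if (cfg$surrogate$n_draws > 0 && is.null(cfg$surrogate$seed)) {
    stop("surrogate draws requested but no seed configured")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> preprocess -> coherence -> surrogates ->
#' behavior scoring -> beta mixed model ladder, writes all result tables
#' (TSV), a JSON manifest (config hash, seeds, package version, row counts
#' per stage) and a human-readable summary to `config$out_dir`. Identical
#' config and seed give identical outputs.
#'
#' @param config a `pipeline_config` (or list coercible via
#'   [pipeline_config()] overrides).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `coherence` tables, `surrogate`,
#'   `pairing`, `scores`, `frame`, `ladder`, `trends`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(overrides = config)
  }
  say <- function(...) if (!quiet) message(...)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  result <- tryCatch({
    # ---- input stage -------------------------------------------------
    if (isTRUE(config$simulate$enabled)) {
      s <- config$simulate
      spec <- simulation_spec(n_dyads = s$n_dyads, duration_s = s$duration_s,
                              fs = s$fs, coupling_base = s$coupling_base,
                              coupling_slope = s$coupling_slope,
                              behavior_link = s$behavior_link,
                              epoch_len_s = config$wtc$epoch_len_s,
                              seed = s$seed)
      cohort <- simulate_cohort(spec)
      recs <- lapply(cohort$dyads, function(d) list(mother = d$mother,
                                                   child = d$child))
      logs <- cohort$logs
      say(sprintf("simulated %d dyads (%.0f s at %.2f Hz)",
                  length(recs), s$duration_s, s$fs))
    } else {
      paths <- config$input$recordings
      if (is.null(paths)) stop("no input recordings configured")
      recs <- lapply(paths, function(p) list(
        mother = read_recording(p$mother), child = read_recording(p$child)))
      logs <- lapply(config$input$logs, read_coding_log)
    }
    # ---- preprocess --------------------------------------------------
    stage <- "preprocess"
    qc_rows <- list()
    hbs <- lapply(recs, function(r) {
      pm <- preprocess_recording(r$mother, config$preprocess)
      pc <- preprocess_recording(r$child, config$preprocess)
      qc_rows[[length(qc_rows) + 1L]] <<- rbind(
        cbind(dyad_id = r$mother$dyad_id, role = "mother", pm$qc_report),
        cbind(dyad_id = r$child$dyad_id, role = "child", pc$qc_report))
      list(mother = pm$hb, child = pc$hb)
    })
    retained <- vapply(hbs, function(h)
      sum(h$mother$channel_mask & h$child$channel_mask), 1L)
    say(sprintf("preprocessed %d dyads; %.1f%% of channels retained",
                length(hbs), 100 * mean(retained) / n_channels(
                  hbs[[1]]$mother$montage)))
    # ---- coherence ---------------------------------------------------
    stage <- "coherence"
    w <- config$wtc
    coh <- lapply(hbs, function(h) dyad_coherence(
      h$mother, h$child, chromophore = config$chromophore,
      band_hz = w$band_hz, epoch_len_s = w$epoch_len_s,
      omega0 = w$omega0, dj = w$dj))
    coh_df <- do.call(rbind, lapply(coh, coherence_long))
    say(sprintf("coherence: %d dyads x %d channels x %d epochs (mean %.3f)",
                length(coh), nrow(coh[[1]]$values), ncol(coh[[1]]$values),
                mean(coh_df$wtc, na.rm = TRUE)))
    # ---- surrogates --------------------------------------------------
    stage <- "surrogate"
    surrogate <- NULL; pairing <- NULL
    if (config$surrogate$n_draws > 0 && length(hbs) >= 2) {
      mothers <- lapply(hbs, `[[`, "mother")
      children <- lapply(hbs, `[[`, "child")
      surrogate <- if (config$surrogate$kind == "phase_randomized") {
        phase_randomized_null(mothers, children,
                              n_draws = config$surrogate$n_draws,
                              seed = config$surrogate$seed,
                              chromophore = config$chromophore,
                              band_hz = w$band_hz,
                              epoch_len_s = w$epoch_len_s,
                              omega0 = w$omega0, dj = w$dj)
      } else {
        random_pair_null(mothers, children,
                         n_draws = config$surrogate$n_draws,
                         seed = config$surrogate$seed,
                         chromophore = config$chromophore,
                         band_hz = w$band_hz, epoch_len_s = w$epoch_len_s,
                         omega0 = w$omega0, dj = w$dj)
      }
      pairing <- pairing_comparison(coh, surrogate)
      say(sprintf("surrogates (%s, %d draws): original %.3f vs null %.3f",
                  surrogate$kind, surrogate$n_draws,
                  mean(coh_df$wtc, na.rm = TRUE),
                  mean(surrogate$values, na.rm = TRUE)))
    }
    # ---- behavior ----------------------------------------------------
    stage <- "behavior"
    scores <- lapply(logs, composite_scores)
    scores_df <- do.call(rbind, lapply(scores, scores_row))
    # ---- stats -------------------------------------------------------
    stage <- "stats"
    frame <- build_model_frame(coh, scores)
    if (!is.null(config$model$roi)) {
      frame <- frame[frame$roi %in% config$model$roi, , drop = FALSE]
    }
    ladder <- model_ladder(frame, through = config$model$ladder_through)
    trends <- NULL
    if (config$model$ladder_through >= 3) {
      trends <- trend_contrast(ladder$fits$m3)
    }
    say(sprintf("ladder fit through model %d on %d rows",
                config$model$ladder_through, nrow(frame)))
    # ---- outputs -----------------------------------------------------
    stage <- "output"
    write_tsv(coh_df, file.path(out_dir, "coherence.tsv"))
    write_tsv(scores_df, file.path(out_dir, "scores.tsv"))
    if (length(qc_rows)) {
      write_tsv(do.call(rbind, qc_rows), file.path(out_dir, "qc_report.tsv"))
    }
    if (!is.null(surrogate)) {
      write_tsv(surrogate_summary(surrogate),
                file.path(out_dir, "surrogate_summary.tsv"))
      write_tsv(pairing$lrts, file.path(out_dir, "pairing_lrts.tsv"))
    }
    write_tsv(ladder$lrts, file.path(out_dir, "ladder_lrts.tsv"))
    coefs <- do.call(rbind, lapply(names(ladder$fits), function(nm) {
      cbind(model = nm, ladder$fits[[nm]]$fixef)
    }))
    write_tsv(coefs, file.path(out_dir, "coefficients.tsv"))
    if (!is.null(trends)) {
      write_tsv(trends$trends, file.path(out_dir, "trends.tsv"))
    }
    manifest <- list(
      package = "dyadsync",
      version = as.character(utils::packageVersion("dyadsync")),
      config_hash = config_hash(config),
      seeds = list(master = config$seed,
                   simulate = config$simulate$seed,
                   surrogate = config$surrogate$seed),
      n_dyads = length(coh),
      n_channels = nrow(coh[[1]]$values),
      n_epochs = ncol(coh[[1]]$values),
      n_frame_rows = nrow(frame),
      n_dropped = attr(frame, "n_dropped"),
      channels_retained_pct = 100 * mean(retained) /
        n_channels(hbs[[1]]$mother$montage)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary_lines <- c(
      sprintf("dyadsync run (config %s)", manifest$config_hash),
      sprintf("dyads: %d, channels: %d, epochs: %d", manifest$n_dyads,
              manifest$n_channels, manifest$n_epochs),
      sprintf("mean WTC (original): %.4f", mean(coh_df$wtc, na.rm = TRUE)),
      if (!is.null(surrogate)) sprintf(
        "mean WTC (%s null): %.4f", surrogate$kind,
        mean(surrogate$values, na.rm = TRUE)),
      "ladder:",
      utils::capture.output(print(ladder$lrts, row.names = FALSE))
    )
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    list(coherence = coh, surrogate = surrogate, pairing = pairing,
         scores = scores, frame = frame, ladder = ladder, trends = trends,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Command-line dispatch
#'
#' Backs the `exec/dyadsync` script. Subcommands: `simulate`,
#' `preprocess`, `coherence`, `surrogate`, `behavior`, `fit`, `run-all`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dyadsync <simulate|preprocess|coherence|surrogate|behavior|fit|run-all>",
    "[--config FILE] [--seed N] [--out DIR] [--chromophore hbo|hbr]",
    "[--roi NAME] [--log FILE] [--mother FILE] [--child FILE]",
    "[--coherence FILE] [--scores FILE]")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--")) { message("unknown argument: ", rest[i]);
      return(2L) }
    key <- sub("^--", "", rest[i])
    if (i == length(rest)) { message("missing value for --", key); return(2L) }
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  known <- c("config", "seed", "out", "chromophore", "roi", "log", "mother",
             "child", "coherence", "scores")
  bad <- setdiff(names(opts), known)
  if (length(bad)) { message("unknown flag(s): --", paste(bad, collapse = " --"));
    return(2L) }
  res <- tryCatch({
    ov <- list()
    if (!is.null(opts$seed)) {
      sd <- as.integer(opts$seed)
      ov <- utils::modifyList(ov, list(seed = sd, simulate = list(seed = sd),
                                       surrogate = list(seed = sd)))
    }
    if (!is.null(opts$out)) ov$out_dir <- opts$out
    if (!is.null(opts$chromophore)) {
      ov$chromophore <- toupper(sub("hbo", "HbO", sub("hbr", "HbR",
                                                      opts$chromophore)))
    }
    if (!is.null(opts$roi)) ov$model <- list(roi = opts$roi)
    switch(cmd,
      "run-all" = {
        run_pipeline(pipeline_config(opts$config, ov))
      },
      "simulate" = {
        cfg <- pipeline_config(opts$config, ov)
        s <- cfg$simulate
        spec <- simulation_spec(n_dyads = s$n_dyads, duration_s = s$duration_s,
                                fs = s$fs, coupling_base = s$coupling_base,
                                coupling_slope = s$coupling_slope,
                                behavior_link = s$behavior_link, seed = s$seed)
        cohort <- simulate_cohort(spec)
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_along(cohort$dyads)) {
          d <- cohort$dyads[[i]]
          id <- d$truth$dyad_id
          write_recording(d$mother, file.path(cfg$out_dir,
                                              paste0(id, "_mother.tsv")))
          write_recording(d$child, file.path(cfg$out_dir,
                                             paste0(id, "_child.tsv")))
          write_coding_log(cohort$logs[[i]],
                           file.path(cfg$out_dir, paste0(id, "_coding.tsv")))
        }
        write_tsv(cohort$truth, file.path(cfg$out_dir, "truth.tsv"))
        message("wrote ", length(cohort$dyads), " dyads to ", cfg$out_dir)
      },
      "preprocess" = {
        if (is.null(opts$mother) && is.null(opts$child)) {
          stop("preprocess needs --mother and/or --child recording TSVs")
        }
        cfg <- pipeline_config(opts$config, ov)
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        for (p in c(opts$mother, opts$child)) {
          pp <- preprocess_recording(read_recording(p), cfg$preprocess)
          base <- tools::file_path_sans_ext(basename(p))
          if (!is.null(pp$qc_report)) {
            write_tsv(pp$qc_report,
                      file.path(cfg$out_dir, paste0(base, "_qc.tsv")))
          }
        }
        message("QC reports written to ", cfg$out_dir)
      },
      "coherence" = {
        if (is.null(opts$mother) || is.null(opts$child)) {
          stop("coherence needs --mother and --child recording TSVs")
        }
        cfg <- pipeline_config(opts$config, ov)
        hm <- preprocess_recording(read_recording(opts$mother), cfg$preprocess)$hb
        hc <- preprocess_recording(read_recording(opts$child), cfg$preprocess)$hb
        ct <- dyad_coherence(hm, hc, chromophore = cfg$chromophore,
                             band_hz = cfg$wtc$band_hz,
                             epoch_len_s = cfg$wtc$epoch_len_s,
                             omega0 = cfg$wtc$omega0, dj = cfg$wtc$dj)
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_tsv(coherence_long(ct), file.path(cfg$out_dir, "coherence.tsv"))
        message("coherence table written to ", cfg$out_dir)
      },
      "surrogate" = ,
      "fit" = {
        cfg <- pipeline_config(opts$config, ov)
        if (cmd == "fit" && (is.null(opts$coherence) || is.null(opts$scores))) {
          stop("fit needs --coherence and --scores TSVs (run coherence/behavior first)")
        }
        if (cmd == "surrogate") {
          run_pipeline(cfg)   # surrogates require the full cohort context
        } else {
          coh_df <- utils::read.delim(opts$coherence)
          sc_df <- utils::read.delim(opts$scores)
          frame <- frame_from_tables(coh_df, sc_df)
          ladder <- model_ladder(frame, through = cfg$model$ladder_through)
          dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
          write_tsv(ladder$lrts, file.path(cfg$out_dir, "ladder_lrts.tsv"))
          message("ladder written to ", cfg$out_dir)
        }
      },
      "behavior" = {
        if (is.null(opts$log)) stop("behavior needs --log coding TSV")
        cfg <- pipeline_config(opts$config, ov)
        sc <- composite_scores(read_coding_log(opts$log))
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_tsv(scores_row(sc), file.path(cfg$out_dir, "scores.tsv"))
        message("scores written to ", cfg$out_dir)
      },
      {
        message("unknown subcommand: ", cmd); message(usage); return(2L)
      }
    )
    0L
  }, error = function(e) {
    message("dyadsync ", cmd, " failed: ", conditionMessage(e))
    1L
  })
  if (is.null(res)) 0L else res
}

# Model frame from already-written long tables (CLI `fit` path).
frame_from_tables <- function(coh_df, scores_df) {
  frame <- merge(coh_df, scores_df, by = "dyad_id")
  frame <- frame[!is.na(frame$wtc), , drop = FALSE]
  if (!nrow(frame)) stop("empty join between coherence and scores tables")
  frame$wtc <- compress_boundary(frame$wtc)
  frame$turn_taking_z <- zstd(frame$turn_taking)
  frame$relevance_z <- zstd(frame$relevance)
  frame$contingency_z <- zstd(frame$contingency)
  frame$intrusiveness_z <- zstd(frame$intrusiveness)
  frame$turn_duration_z <- zstd(frame$mean_turn_duration_ms)
  frame$time_z <- zstd(frame$epoch)
  frame$pairing <- "original"
  frame
}
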