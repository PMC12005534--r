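# Plain-text session-bundle layout:
#   <dir>/config.json                JSON of the intent_config fields
#   <dir>/trials.csv                 one row per trial
#   <dir>/spikes.csv                 long table of spike events
#   <dir>/decoder/<trial_id>.csv     t_ms,value per 100 ms bin
#   <dir>/lfp/<trial_id>.csv         t_ms,value
# Missing values are empty fields, never sentinel numbers.

#' Read / write a session bundle
#'
#' A session bundle is a directory holding the session configuration
#' (`config.json`), the trial table (`trials.csv`: trial_id, condition,
#' report_query, clock_phase_units, t_action_ms, t_tone_ms,
#' t_decoder_intent_ms, report_units, plus t_start_ms and duration_ms locating
#' each trial on the session timeline), the spike table (`spikes.csv`) and one
#' CSV per trial for decoder and (optionally) LFP traces. A write/read round
#' trip reproduces every field to full double precision.
#'
#' @param path Directory to read from / write into.
#' @param bundle A [session_bundle()].
#' @return `read_session_bundle` returns a [session_bundle()];
#'   `write_session_bundle` returns `path` invisibly.
#' @export
read_session_bundle <- function(path) {
  for (f in c("config.json", "trials.csv", "spikes.csv")) {
    if (!file.exists(file.path(path, f)))
      stop(sprintf("session bundle at '%s' is missing required file '%s'",
                   path, f))
  }
  cfg_raw <- jsonlite::read_json(file.path(path, "config.json"),
                                 simplifyVector = TRUE)
  config <- do.call(intent_config, cfg_raw)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            colClasses = trial_col_classes(),
                            stringsAsFactors = FALSE)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            colClasses = c(unit_id = "character"),
                            stringsAsFactors = FALSE)
  if (nrow(spikes) == 0) spikes <- empty_spikes()
  decoder <- read_trace_dir(file.path(path, "decoder"), "DECODER",
                            1000 / config$decoder_bin_ms)
  lfp <- read_trace_dir(file.path(path, "lfp"), "LFP", NA)
  session_bundle(config, trials, spikes, decoder,
                 lfp = if (length(lfp)) lfp else NULL)
}

#' @rdname read_session_bundle
#' @export
write_session_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(bundle$config),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_csv_full(bundle$trials, file.path(path, "trials.csv"))
  write_csv_full(bundle$spikes, file.path(path, "spikes.csv"))
  write_trace_dir(bundle$decoder, file.path(path, "decoder"))
  if (length(bundle$lfp)) write_trace_dir(bundle$lfp, file.path(path, "lfp"))
  invisible(path)
}

trial_col_classes <- function() {
  c(trial_id = "character", condition = "character",
    report_query = "character", clock_phase_units = "numeric",
    t_action_ms = "numeric", t_tone_ms = "numeric",
    t_decoder_intent_ms = "numeric", report_units = "numeric",
    t_start_ms = "numeric", duration_ms = "numeric")
}

# write.csv with full double precision (17 significant digits round-trips
# IEEE doubles exactly through the reader)
write_csv_full <- function(df, file) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- vapply(v, function(x) {
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE)
      }, character(1))
      out[[j]] <- s
    }
  }
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
}

write_trace_dir <- function(traces, dir) {
  if (!length(traces)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    return(invisible(NULL))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    df <- data.frame(t_ms = trace_times(tr), value = as.numeric(tr$values))
    attr(df, "fs_hz") <- tr$fs_hz
    hdr <- sprintf("# kind=%s fs_hz=%s t0_ms=%s", tr$kind,
                   format(tr$fs_hz, digits = 17),
                   format(tr$t0_ms, digits = 17))
    con <- file(file.path(dir, paste0(nm, ".csv")), "w")
    writeLines(hdr, con)
    utils::write.csv(within(df, {
      t_ms <- format(t_ms, digits = 17, scientific = FALSE)
      value <- format(value, digits = 17, scientific = FALSE)
    }), con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(NULL)
}

read_trace_dir <- function(dir, kind, default_fs) {
  if (!dir.exists(dir)) return(list())
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  out <- list()
  for (f in files) {
    hdr <- readLines(f, n = 1)
    meta <- regmatches(hdr, gregexpr("[a-z0-9_]+=[^ ]+", hdr))[[1]]
    kv <- strsplit(meta, "=")
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    fs <- as.numeric(vals[["fs_hz"]] %||% default_fs)
    t0 <- as.numeric(vals[["t0_ms"]] %||% 0)
    df <- utils::read.csv(f, skip = 1)
    out[[sub("\\.csv$", "", basename(f))]] <-
      continuous_trace(kind, fs, t0, df$value)
  }
  out
}

#' Validate a session bundle directory
#'
#' Reads the bundle (which runs all schema checks) and reports a short
#' summary; schema violations raise errors naming the offending file or
#' records.
#'
#' @param path Bundle directory.
#' @return The validated [session_bundle()], invisibly.
#' @export
validate_session_bundle <- function(path) {
  b <- read_session_bundle(path)
  message(sprintf("valid bundle: %d trials, %d spikes, %d decoder traces",
                  nrow(b$trials), nrow(b$spikes), length(b$decoder)))
  invisible(b)
}
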