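pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF or CSV
#'
#' EDF (European Data Format) output is a minimal single-channel file: the
#' standard fixed-width ASCII header (sampling rate recoverable from the
#' record duration and samples-per-record fields, channel label and µV
#' physical dimension included) followed by one data record of 16-bit
#' little-endian samples scaled between the physical extrema. CSV output
#' is two columns `time_s, amplitude_uV` preceded by a metadata comment
#' line carrying the sampling rate, label and start time.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param format `"edf"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") write_edf1(rec, path) else write_eeg_csv(rec, path)
  invisible(path)
}

write_edf1 <- function(rec, path) {
  x <- rec$samples
  n <- length(x)
  duration <- n / rec$fs
  pmin <- min(x); pmax <- max(x)
  if (pmax == pmin) pmax <- pmin + 1   # constant signal: avoid zero span
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
  header_bytes <- 256L + 256L
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  put("0", 8); put("synthetic", 80); put("bbisim recording", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(header_bytes, 8); put("", 44)
  put(1L, 8)                                   # one data record
  put(format(duration, digits = 7), 8)         # record duration in seconds
  put(1L, 4)                                   # one signal
  put(rec$label, 16); put("synthetic EEG", 80); put("uV", 8)
  put(format(pmin, digits = 7), 8); put(format(pmax, digits = 7), 8)
  put(dmin, 8); put(dmax, 8); put("", 80)
  put(n, 8); put("", 32)
  writeBin(dig, con, size = 2L, endian = "little")
}

write_eeg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%s label=%s start_time=%s",
                     format(rec$fs, digits = 15), rec$label,
                     format(rec$start_time, digits = 15)), con)
  writeLines("time_s,amplitude_uV", con)
  t <- rec$start_time + (seq_along(rec$samples) - 1L) / rec$fs
  writeLines(paste(format(t, digits = 15, trim = TRUE, scientific = FALSE),
                   format(rec$samples, digits = 15, trim = TRUE),
                   sep = ","), con)
}

#' Read a recording from EDF or CSV
#'
#' Counterpart of [write_eeg()]; the round trip is lossless up to format
#' precision (16-bit quantization for EDF, printed digits for CSV).
#'
#' @param path Input path.
#' @param format `"edf"` or `"csv"`; guessed from the extension.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") read_edf1(path) else read_eeg_csv(path)
}

read_edf1 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- get(8)
  if (version != "0") stop("corrupt EDF header: unexpected version field")
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8)); get(44)
  n_records <- as.integer(get(8))
  rec_duration <- as.numeric(get(8))
  ns <- as.integer(get(4))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count")
  field <- function(w) vapply(seq_len(ns), function(i) get(w), character(1))
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8)); field(80)
  nsamp <- as.integer(field(8)); field(32)
  if (any(is.na(c(rec_duration, nsamp[1]))) || rec_duration <= 0)
    stop("EDF header is missing the record duration (sampling rate unrecoverable)")
  seek(con, header_bytes)
  out <- numeric(0)
  for (r in seq_len(n_records)) {
    for (sig in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nsamp[sig], size = 2L,
                     endian = "little")
      if (sig == 1L)
        out <- c(out, (dig - dmin[1]) / (dmax[1] - dmin[1]) *
                   (pmax[1] - pmin[1]) + pmin[1])
    }
  }
  eeg_recording(out, fs = nsamp[1] / rec_duration, label = labels[1])
}

read_eeg_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#", first) || !grepl("fs_hz=", first))
    stop("CSV is missing the fs_hz metadata line; sampling rate unknown")
  meta_of <- function(key, default = NA) {
    m <- regmatches(first, regexpr(paste0(key, "=[^ ]+"), first))
    if (length(m) == 0L) return(default)
    sub(paste0(key, "="), "", m)
  }
  fs <- as.numeric(meta_of("fs_hz"))
  if (is.na(fs)) stop("CSV metadata line has an unreadable fs_hz value")
  df <- utils::read.csv(path, comment.char = "#")
  eeg_recording(df$amplitude_uV, fs = fs,
                label = meta_of("label", "Oz"),
                start_time = as.numeric(meta_of("start_time", 0)))
}

#' Write a session log to CSV or JSON
#'
#' CSV: one row per trial x round with the full decision chain, preceded
#' by comment lines embedding the session plan and seed for provenance.
#' JSON: a `meta` object (seed, plan) plus the same rows.
#'
#' @param log A `"session_log"`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(log, "session_log"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  plan <- attr(log, "plan")
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# seed=%d", attr(log, "seed")),
      sprintf("# plan_seed=%d", plan$seed),
      sprintf("# n_trials=%d", plan$n_trials),
      sprintf("# bad_sender=%d", plan$bad_sender),
      sprintf("# forced_error_trials=%s",
              paste(plan$forced_error_trials, collapse = ";")),
      sprintf("# truths=%s", paste(plan$trials, collapse = ";"))), con)
    utils::write.csv(as.data.frame(unclass(log)), con, row.names = FALSE)
  } else {
    obj <- list(
      meta = list(seed = attr(log, "seed"),
                  plan = list(seed = plan$seed, n_trials = plan$n_trials,
                              trials = plan$trials,
                              bad_sender = plan$bad_sender,
                              forced_error_trials = plan$forced_error_trials)),
      rows = as.data.frame(unclass(log)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path Input path.
#' @return A `"session_log"` with its plan and seed attributes restored.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$rows)
    p <- obj$meta$plan
    plan <- structure(list(trials = as.integer(p$trials),
                           bad_sender = as.integer(p$bad_sender),
                           forced_error_trials = as.integer(p$forced_error_trials),
                           seed = as.integer(p$seed),
                           n_trials = as.integer(p$n_trials)),
                      class = "session_plan")
    seed <- as.integer(obj$meta$seed)
  } else {
    hdr <- readLines(path, n = 20L)
    hdr <- hdr[grepl("^#", hdr)]
    val <- function(key) sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
    plan <- structure(list(
      trials = as.integer(strsplit(val("truths"), ";")[[1]]),
      bad_sender = as.integer(val("bad_sender")),
      forced_error_trials = as.integer(strsplit(val("forced_error_trials"), ";")[[1]]),
      seed = as.integer(val("plan_seed")),
      n_trials = as.integer(val("n_trials"))), class = "session_plan")
    seed <- as.integer(val("seed"))
    df <- utils::read.csv(path, comment.char = "#")
  }
  df$forced_flag <- as.logical(df$forced_flag)
  df$excluded_flag <- as.logical(df$excluded_flag)
  structure(df, class = c("session_log", "data.frame"),
            plan = plan, seed = seed)
}

#' Serialize a [evaluate()] result to plain lists (for JSON reports)
#'
#' @param res A `"triad_result"`.
#' @return A nested list of plain vectors.
#' @export
triad_result_to_list <- function(res) {
  roc_list <- function(v) lapply(v, function(r) list(tpr = r$tpr, fpr = r$fpr, auc = r$auc))
  mi_list <- function(v) lapply(v, function(m) list(mi = m$mi, n_samples = m$n_samples, bias = m$bias))
  trend_list <- function(t) list(beta_good = t$beta_good, beta_bad = t$beta_bad,
                                 se_good = t$se_good, se_bad = t$se_bad, z = t$z)
  list(accuracy = res$accuracy, mean_accuracy = res$mean_accuracy,
       pooled = res$pooled,
       roc = lapply(res$roc, roc_list), mean_auc = res$mean_auc,
       mi = lapply(res$mi, mi_list), mean_mi = res$mean_mi,
       mi_bias = res$mi_bias,
       learning = res$learning,
       trend = lapply(res$trend, trend_list),
       n_triads = res$n_triads)
}
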