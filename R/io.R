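#' Read a single-lead ECG from CSV or WFDB
#'
#' CSV dialect: header row naming a time column (`t`, `t_seconds` or `time`,
#' in seconds) and a voltage column; comma separator, decimal point. The
#' sampling rate is inferred from the time column, which must be uniform to
#' within 0.1 percent. WFDB: a standard `.hea`/`.dat` pair in format 16
#' (16-bit little-endian interleaved integers); the sampling rate is taken
#' from the header and samples are converted to physical units via the
#' per-signal gain and baseline.
#'
#' @param path path to the `.csv` file or to the WFDB record (with or
#'   without the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`; guessed from the extension by default.
#' @param channel 1-based channel index (WFDB records may be multi-channel).
#' @return an [ecg_signal()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), channel = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") read_ecg_csv(path, channel) else read_ecg_wfdb(path, channel)
}

read_ecg_csv <- function(path, channel = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  tcol <- intersect(c("t", "t_seconds", "time"), names(df))[1]
  if (is.na(tcol)) stop("CSV must contain a time column named t, t_seconds or time",
                        call. = FALSE)
  vcols <- setdiff(names(df), tcol)
  if (channel < 1 || channel > length(vcols)) {
    stop("channel ", channel, " not present (", length(vcols),
         " voltage column(s))", call. = FALSE)
  }
  tt <- df[[tcol]]
  if (length(tt) < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(tt)
  med <- median(dt)
  if (med <= 0 || any(abs(dt - med) > 0.001 * med)) {
    stop("non-uniform sampling: time column deviates by more than 0.1% ",
         "from a uniform grid", call. = FALSE)
  }
  ecg_signal(as.numeric(df[[vcols[channel]]]), fs = 1 / med,
             meta = basename(path))
}

#' Write an ECG signal (or synthetic record) to CSV
#'
#' Columns `t` (seconds) and `voltage`, full double precision so the file
#' round-trips bit-exactly through [read_ecg()]. For an `ecg_record`, the
#' fiducial truth table and labels are written to a JSON sidecar
#' `<path>.truth.json`.
#'
#' @param x an [ecg_signal()] or `ecg_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(x, path) {
  if (inherits(x, "ecg_record")) {
    sidecar <- paste0(path, ".truth.json")
    jsonlite::write_json(list(fs = x$signal$fs, truth = x$truth,
                              labels = x$labels),
                         sidecar, auto_unbox = TRUE, digits = NA)
    x <- x$signal
  }
  stopifnot(inherits(x, "ecg_signal"))
  n <- length(x$samples)
  tt <- (seq_len(n) - 1) / x$fs
  lines <- c("t,voltage",
             sprintf("%.17g,%.17g", tt, x$samples))
  writeLines(lines, path)
  invisible(path)
}

# --- minimal WFDB (format 16) support ---------------------------------------

read_ecg_wfdb <- function(path, channel = 1) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4) stop("unparseable WFDB header line: ", lines[1],
                            call. = FALSE)
  nsig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  nsamp <- as.integer(rec[4])
  if (channel < 1 || channel > nsig) {
    stop("channel ", channel, " not present (", nsig, " signal(s))",
         call. = FALSE)
  }
  sig <- lines[1 + seq_len(nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*", "", f[2])
    gain_field <- f[3]
    baseline <- 0
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_field))
    }
    gain <- as.numeric(sub("[(/].*", "", gain_field))
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline)
  }
  info <- lapply(sig, parse_sig)
  if (any(vapply(info, function(s) s$fmt, "") != "16")) {
    stop("only WFDB format 16 is supported", call. = FALSE)
  }
  dat <- file.path(dirname(hea), info[[channel]]$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat,
                              call. = FALSE)
  raw <- readBin(dat, what = "integer", size = 2, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  if (length(raw) < nsig * nsamp) {
    stop("WFDB signal file shorter than header declares", call. = FALSE)
  }
  stored <- matrix(raw, nrow = nsig)[channel, ]
  g <- info[[channel]]$gain
  if (!is.finite(g) || g == 0) g <- 200
  ecg_signal((stored - info[[channel]]$baseline) / g, fs = fs,
             meta = rec[1])
}

#' Write an ECG signal as a WFDB format-16 record
#'
#' Emits `<record>.hea` and `<record>.dat` with a single signal, gain 200
#' ADU per unit, baseline 0.
#'
#' @param ecg an [ecg_signal()].
#' @param record path/record name (no extension).
#' @return `record`, invisibly.
#' @export
write_ecg_wfdb <- function(ecg, record) {
  stopifnot(inherits(ecg, "ecg_signal"))
  gain <- 200
  stored <- as.integer(round(ecg$samples * gain))
  stored <- pmin(pmax(stored, -32768L), 32767L)
  name <- basename(record)
  writeLines(c(sprintf("%s 1 %.6g %d", name, ecg$fs, length(stored)),
               sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 ECG", name, gain)),
             paste0(record, ".hea"))
  writeBin(stored, paste0(record, ".dat"), size = 2, endian = "little")
  invisible(record)
}
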