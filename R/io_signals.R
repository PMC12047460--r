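#' Single-lead ECG signal container
#'
#' @param samples Numeric vector of voltages in microvolts (uV).
#' @param fs Sampling rate (Hz), > 0.
#' @param t0 Time of the first sample, seconds from record start.
#' @param lead_label Channel name, e.g. `"MLII"`.
#'
#' @return An object of class `ecg_signal`: a list with fields `samples`,
#'   `fs`, `t0`, `lead_label`.  The time of sample `i` (1-based) is
#'   `t0 + (i - 1) / fs`.
#' @export
#' @examples
#' s <- ecg_signal(sin(2 * pi * 1 * seq(0, 1, by = 1/250)), fs = 250)
#' duration(s)
ecg_signal <- function(samples, fs, t0 = 0, lead_label = "ECG") {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal contains non-finite samples")
  structure(list(samples = samples, fs = fs, t0 = t0,
                 lead_label = as.character(lead_label)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s: %d samples @ %g Hz (%.1f s), range [%.0f, %.0f] uV\n",
              x$lead_label, length(x$samples), x$fs, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Record duration in seconds
#' @param signal An `ecg_signal`.
#' @return Duration in seconds (`n / fs`).
#' @export
duration <- function(signal) length(signal$samples) / signal$fs

sample_times <- function(signal)
  signal$t0 + (seq_along(signal$samples) - 1) / signal$fs

# index of the sample nearest to time t (1-based, clamped)
time_to_index <- function(signal, t) {
  i <- round((t - signal$t0) * signal$fs) + 1
  pmin(pmax(i, 1L), length(signal$samples))
}

## ---------------------------------------------------------------------------
## WFDB header / signal / annotation files
##
## Minimal reader and writer for the PhysioNet WFDB family: '.hea' headers,
## '.dat' signals in formats 212 (packed 12-bit pairs) and 16 (little-endian
## int16), and MIT-format '.atr' annotations.  Physical units are converted
## to uV on read.
## ---------------------------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  n_samp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  sig <- lapply(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[[i + 1]]), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    units <- "mV"
    baseline <- NA_real_
    g <- gain_spec
    if (grepl("/", g)) { units <- sub("^.*/", "", g); g <- sub("/.*$", "", g) }
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gain <- as.numeric(g)
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (!is.finite(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else
      paste0("ch", i)
    list(file = f[1], fmt = sub("x.*|:.*|\\+.*", "", f[2]), gain = gain,
         baseline = baseline, units = units, desc = desc)
  })
  list(record = rec[1], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

read_dat_samples <- function(dat_path, fmt, n_sig) {
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == "16") {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                 endian = "little", signed = TRUE)
    matrix(v, ncol = n_sig, byrow = TRUE)
  } else if (fmt == "212") {
    n_tri <- length(raw) %/% 3
    b <- matrix(as.integer(raw[seq_len(3 * n_tri)]), nrow = 3)
    s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0FL), 8)
    s2 <- b[3, ] + bitwShiftL(bitwShiftR(b[2, ], 4), 8)
    s1 <- ifelse(s1 > 2047, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], ncol = n_sig,
           byrow = TRUE)
  } else stop("unsupported WFDB signal format: ", fmt)
}

units_to_uv <- function(units) {
  switch(tolower(units), "mv" = 1000, "uv" = 1, "v" = 1e6,
         1000)  # WFDB default physical unit is mV
}

#' Read a WFDB record and its beat annotations
#'
#' Reads a WFDB header/signal pair (formats 212 and 16 are supported),
#' selects one channel, converts it to microvolts, and reads the `.atr`
#' annotation file when present.
#'
#' @param path Record path without extension (e.g. `"mitdb/100"`).
#' @param lead_selector Channel name to extract (e.g. `"MLII"`).  With a
#'   single-channel record the selector may be omitted.
#' @param annotator Annotation file extension, default `"atr"`.
#'
#' @return A list with elements `signal` (an [ecg_signal] in uV) and
#'   `annotations` (a data frame `time`, `symbol`; empty if no annotation
#'   file exists).
#' @export
read_record <- function(path, lead_selector = NULL, annotator = "atr") {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- parse_wfdb_header(hea)
  labels <- vapply(h$signals, `[[`, "", "desc")
  idx <- if (is.null(lead_selector)) {
    if (h$n_sig > 1)
      stop("record has ", h$n_sig, " channels (", paste(labels, collapse = ", "),
           "); a lead_selector is required")
    1L
  } else {
    m <- which(labels == lead_selector)
    if (!length(m))
      stop("lead '", lead_selector, "' not found; available channels: ",
           paste(labels, collapse = ", "))
    m[1]
  }
  dat_path <- file.path(dirname(hea), h$signals[[idx]]$file)
  mat <- read_dat_samples(dat_path, h$signals[[idx]]$fmt, h$n_sig)
  adu <- mat[, idx]
  si <- h$signals[[idx]]
  uv <- (adu - si$baseline) / si$gain * units_to_uv(si$units)
  sig <- ecg_signal(uv, fs = h$fs, lead_label = labels[idx])
  atr <- paste0(path, ".", annotator)
  ann <- if (file.exists(atr)) read_wfdb_annotations(atr, fs = h$fs) else
    data.frame(time = numeric(0), symbol = character(0))
  list(signal = sig, annotations = ann)
}

#' Write a single-channel WFDB record (format 16)
#'
#' @param signal An [ecg_signal] in uV.
#' @param path Record path without extension; `.hea` and `.dat` are created.
#' @param gain ADC units per millivolt (default 4000, i.e. 0.25 uV
#'   resolution over roughly +-8 mV).
#' @return `path`, invisibly.
#' @export
write_record <- function(signal, path, gain = 4000) {
  rec <- basename(path)
  adu <- as.integer(round(signal$samples / 1000 * gain))
  if (any(abs(adu) > 32767)) stop("signal exceeds int16 range at this gain")
  writeBin(adu, paste0(path, ".dat"), size = 2, endian = "little")
  hea <- c(sprintf("%s 1 %g %d", rec, signal$fs, length(adu)),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s", rec, gain,
                   adu[1], sum(adu) %% 65536, signal$lead_label))
  writeLines(hea, paste0(path, ".hea"))
  invisible(path)
}

## MIT annotation code <-> symbol table (beat and non-beat)
.ann_codes <- c("N","L","R","a","V","F","J","A","S","E","j","/","Q","~","",
                "|","","s","T","*","D","\"","=","p","B","^","t","+","u","?",
                "!","[","]","e","n","@","x","f","(",")","r")
.beat_symbols <- c("N","L","R","a","V","F","J","A","S","E","j","/","Q","e",
                   "n","x","f","r","B","!")

symbol_to_code <- function(sym) {
  i <- match(sym, .ann_codes)
  if (anyNA(i)) stop("unknown annotation symbol(s): ",
                     paste(unique(sym[is.na(i)]), collapse = " "))
  i
}

#' Read MIT-format WFDB annotations
#'
#' @param path Annotation file path (e.g. `"100.atr"`).
#' @param fs Sampling rate used to convert sample indices to seconds.
#' @return Data frame with `time` (seconds) and `symbol` columns, in file
#'   order.
#' @export
read_wfdb_annotations <- function(path, fs) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  w <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
               endian = "little", signed = FALSE)
  t_samp <- 0
  times <- integer(0); codes <- integer(0)
  i <- 1
  while (i <= length(w)) {
    code <- bitwShiftR(w[i], 10)
    inc <- bitwAnd(w[i], 1023L)
    if (code == 0 && inc == 0) break
    if (code == 59) {           # SKIP: 4-byte interval, high word first
      t_samp <- t_samp + w[i + 1] * 65536 + w[i + 2]
      i <- i + 3
    } else if (code %in% c(60, 61, 62)) {  # NUM / SUB / CHN: no time advance
      i <- i + 1
    } else if (code == 63) {    # AUX: inc bytes of payload, even-padded
      i <- i + 1 + ceiling(inc / 2)
    } else {
      t_samp <- t_samp + inc
      times <- c(times, t_samp)
      codes <- c(codes, code)
      i <- i + 1
    }
  }
  data.frame(time = times / fs, symbol = .ann_codes[codes],
             stringsAsFactors = FALSE)
}

#' Write MIT-format WFDB annotations
#'
#' @param annotations Data frame with `time` (seconds) and `symbol`.
#' @param path Output file path.
#' @param fs Sampling rate used to convert seconds to sample indices.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(annotations, path, fs) {
  ord <- order(annotations$time)
  samp <- round(annotations$time[ord] * fs)
  codes <- symbol_to_code(annotations$symbol[ord])
  words <- integer(0)
  prev <- 0
  for (k in seq_along(samp)) {
    dt <- samp[k] - prev
    if (dt >= 1024) {
      words <- c(words, bitwShiftL(59L, 10),
                 dt %/% 65536, dt %% 65536, bitwShiftL(codes[k], 10))
    } else {
      words <- c(words, bitwShiftL(codes[k], 10) + dt)
    }
    prev <- samp[k]
  }
  words <- c(words, 0L)
  writeBin(as.integer(words), path, size = 2, endian = "little")
  invisible(path)
}

#' Read / write annotations as CSV
#'
#' Plain-text exchange format: a two-column CSV `time_s,symbol`.
#'
#' @param path CSV file path.
#' @return `read_annotations_csv`: data frame `time`, `symbol`.
#' @export
read_annotations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("numeric", "character"))
  names(d) <- c("time", "symbol")
  d
}

#' @rdname read_annotations_csv
#' @param annotations Data frame with `time` and `symbol` columns.
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(data.frame(time_s = annotations$time,
                              symbol = annotations$symbol),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Preconditioning and amplitude quality control
## ---------------------------------------------------------------------------

#' Band-pass and resample a signal
#'
#' Zero-phase preconditioning: a second-order Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), followed by cubic-spline
#' resampling to the working rate.  The zero-phase design guarantees no net
#' fiducial shift.
#'
#' @param signal An [ecg_signal].
#' @param band_lo,band_hi Pass-band corners (Hz); `band_lo = 0` disables the
#'   high-pass branch.
#' @param target_fs Output sampling rate (Hz).
#' @return A new [ecg_signal] at `target_fs`.
#' @export
preprocess <- function(signal, band_lo = 0.5, band_hi = 40, target_fs = 256) {
  if (band_lo < 0 || band_lo >= band_hi || band_hi >= target_fs / 2)
    stop("invalid band: need 0 <= band_lo < band_hi < target_fs/2")
  x <- signal$samples
  fs <- signal$fs
  ny <- fs / 2
  if (band_hi < ny * 0.999) {
    bl <- signal::butter(2, band_hi / ny, type = "low")
    x <- signal::filtfilt(bl, x)
  }
  if (band_lo > 0) {
    x <- x - mean(x)      # shrink the filtfilt edge transient on DC offsets
    bh <- signal::butter(2, band_lo / ny, type = "high")
    x <- signal::filtfilt(bh, x)
  }
  if (!isTRUE(all.equal(target_fs, fs))) {
    n_out <- floor(duration(signal) * target_fs)
    t_out <- (seq_len(n_out) - 1) / target_fs
    x <- stats::spline(x = (seq_along(x) - 1) / fs, y = x, xout = t_out,
                       method = "natural")$y
  }
  ecg_signal(x, fs = target_fs, t0 = signal$t0, lead_label = signal$lead_label)
}

#' Mean R-wave amplitude quality control
#'
#' Records whose mean R-wave amplitude falls below the floor (default
#' 100 uV) carry too little signal for reliable morphology analysis and are
#' rejected.  The per-beat amplitude is the maximum absolute voltage in a
#' +-50 ms window around each fiducial.
#'
#' @param signal An [ecg_signal].
#' @param beats Data frame of beats with a `time` column (see
#'   [detect_beats]).
#' @param min_mean_r_uv Minimum acceptable mean R amplitude (uV).
#' @return List with `pass` (logical) and `mean_r_uv`.
#' @export
amplitude_qc <- function(signal, beats, min_mean_r_uv = 100) {
  if (is.null(beats) || nrow(beats) == 0)
    stop("amplitude_qc requires a non-empty beat list")
  half <- round(0.050 * signal$fs)
  n <- length(signal$samples)
  amps <- vapply(beats$time, function(t) {
    i <- time_to_index(signal, t)
    max(abs(signal$samples[max(1, i - half):min(n, i + half)]))
  }, 0)
  m <- mean(amps)
  list(pass = m >= min_mean_r_uv, mean_r_uv = m)
}
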