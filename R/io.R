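#' Read a heart-sound recording from a WAV file
#'
#' Parses a RIFF/WAV file into a [pcg_signal()]. 16- and 32-bit integer PCM
#' and 32-bit IEEE float encodings are supported. Integer PCM is rescaled to
#' float in \[-1, 1\] by dividing by the type's maximum magnitude (32768 or
#' 2147483648); float samples are used as-is. Multi-channel audio is averaged
#' to mono. No gain normalisation is applied.
#'
#' @param path Path to an existing WAV file.
#' @return A mono [pcg_signal()] with `fs` taken from the file header.
#' @seealso [write_wav()], [read_serial_csv()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("not-found error: no such file: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("format error: not a RIFF file: ", path)
  }
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("format error: RIFF file is not WAVE: ", path)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2L)
      if (size < 16L) stop("format error: truncated fmt chunk")
      u16 <- function(off) {
        sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      }
      u32 <- function(off) {
        sum(as.numeric(body[off + 1:4]) * c(1, 256, 65536, 16777216))
      }
      fmt <- list(format = u16(0L), channels = u16(2L),
                  fs = u32(4L), bits = u16(14L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }

  if (is.null(fmt) || is.null(data_raw)) {
    stop("format error: missing fmt or data chunk: ", path)
  }
  if (fmt$channels < 1L) stop("format error: zero channels")
  if (length(data_raw) == 0L) {
    stop("empty-input error: WAV file contains no audio samples: ", path)
  }

  x <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) %/% 4L, size = 4L,
            endian = "little") / 2147483648
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", length(data_raw) %/% 4L, size = 4L,
            endian = "little")
  } else {
    stop("format error: unsupported WAV encoding (format tag ", fmt$format,
         ", ", fmt$bits, " bits); use PCM16, PCM32 or float32")
  }

  if (length(x) == 0L) {
    stop("empty-input error: WAV file contains no audio samples: ", path)
  }
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  pcg_signal(x, fs = fmt$fs, source = basename(path))
}

#' Write a heart-sound signal to a WAV file
#'
#' Writes a mono 32-bit IEEE-float WAV at the signal's sampling rate.
#' A subsequent [read_wav()] reproduces the samples to within single-float
#' precision (about 1e-7 for amplitudes in \[-1, 1\]) and the rate exactly.
#'
#' @param signal A valid [pcg_signal()].
#' @param path Destination file path.
#' @return `invisible(path)`.
#' @export
write_wav <- function(signal, path) {
  if (!inherits(signal, "pcg_signal")) {
    stop("argument error: `signal` must be a pcg_signal")
  }
  if (!all(is.finite(signal$samples))) {
    stop("validation error: signal contains non-finite samples")
  }
  n <- length(signal$samples)
  data_bytes <- 4L * n
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error: cannot open ", path,
                                           " for writing"))
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(4L + 24L + 12L + 8L + data_bytes)       # WAVE + fmt + fact + data hdr
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(3L); w16(1L)                  # IEEE float, mono
  w32(round(signal$fs)); w32(round(signal$fs) * 4L)
  w16(4L); w16(32L)
  writeChar("fact", con, eos = NULL)
  w32(4L); w32(n)
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  writeBin(signal$samples, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a serial data-logger CSV export
#'
#' Parses amplitude time-series exported by a serial logger (the spreadsheet
#' style export of an Arduino serial monitor). Accepts comma- or
#' whitespace-delimited text with an optional single header row; the
#' amplitude is taken from the last column whose values are all numeric.
#' Logger exports carry no sampling rate, so `fs` must be supplied.
#'
#' @param path Path to the delimited text file.
#' @param fs Sampling rate in Hz of the logged amplitudes.
#' @return A [pcg_signal()].
#' @export
read_serial_csv <- function(path, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("argument error: `fs` must be a single positive number")
  }
  if (!file.exists(path)) {
    stop("not-found error: no such file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty-input error: file has no data rows: ", path)
  }
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[[:space:]]+"
  split_row <- function(l) trimws(strsplit(l, sep)[[1]])
  first <- suppressWarnings(as.numeric(split_row(lines[1L])))
  if (anyNA(first)) lines <- lines[-1L]  # header row
  if (length(lines) == 0L) {
    stop("empty-input error: file has no data rows: ", path)
  }
  cells <- lapply(lines, split_row)
  ncol <- max(lengths(cells))
  cols <- lapply(seq_len(ncol), function(j) {
    vapply(cells, function(r) if (j <= length(r)) r[j] else NA_character_,
           character(1))
  })
  numeric_cols <- vapply(cols, function(v) {
    v <- suppressWarnings(as.numeric(v))
    !anyNA(v)
  }, logical(1))
  if (!any(numeric_cols)) {
    stop("format error: no all-numeric column found in ", path)
  }
  amp <- as.numeric(cols[[max(which(numeric_cols))]])
  pcg_signal(amp, fs = fs, source = basename(path))
}

# Read either a WAV (by extension) or a logger CSV; used by the CLI.
read_signal <- function(path, fs = NULL) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    read_wav(path)
  } else {
    if (is.null(fs)) {
      stop("argument error: `fs` is required for non-WAV input")
    }
    read_serial_csv(path, fs)
  }
}
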