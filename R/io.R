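#' Write and read a chord schedule as a TSV event list
#'
#' The event list has columns `onset_time_s`, `channel_index` (0-based in
#' the file, low-to-high frequency) and `center_freq_hz`; a JSON sidecar
#' (`<path>.json`) records `n_channels`, `n_bins`, `bin_width_s`,
#' `p_onset`, and `seed` so the binary grid can be reconstructed exactly.
#'
#' @param schedule a [draw_chord_schedule()] result.
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @param map optional [make_cochleotopic_map()] result for the
#'   `center_freq_hz` column.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path, map = NULL) {
  ev <- schedule_events(schedule, map)
  ev$channel_index <- ev$channel_index - 1L
  utils::write.table(ev, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(n_channels = nrow(schedule), n_bins = ncol(schedule),
               bin_width_s = attr(schedule, "bin_width_s"),
               p_onset = attr(schedule, "p_onset"),
               seed = attr(schedule, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @return For the reader, the reconstructed `chord_schedule` matrix.
#' @export
read_schedule_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- utils::read.table(path, sep = "\t", header = TRUE)
  x <- matrix(0L, nrow = meta$n_channels, ncol = meta$n_bins)
  if (nrow(ev) > 0) {
    bins <- round(ev$onset_time_s / meta$bin_width_s) + 1L
    x[cbind(ev$channel_index + 1L, bins)] <- 1L
  }
  structure(x, bin_width_s = meta$bin_width_s, p_onset = meta$p_onset,
            seed = meta$seed,
            class = c("chord_schedule", "matrix", "array"))
}

#' Write a cochleotopic map as CSV
#'
#' Columns: `index`, `center_freq_hz`, `erb_hz`, `bw_hz`.
#'
#' @param map a [make_cochleotopic_map()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Minimal WAV writer and reader
#'
#' Writes a mono waveform as a RIFF/WAVE file, either 16-bit integer PCM
#' (`format = "pcm16"`, samples clipped to \[-1, 1\] and scaled to 32767)
#' or 32-bit IEEE float (`format = "float32"`, samples stored verbatim).
#' The reader returns the samples (floats verbatim; PCM rescaled to
#' \[-1, 1\]) and the header sample rate.
#'
#' @param samples numeric waveform.
#' @param path file path.
#' @param sample_rate_hz sampling rate written to the header.
#' @param format `"pcm16"` or `"float32"`.
#' @return Writer: `path`, invisibly. Reader: list with `samples` and
#'   `sample_rate_hz`.
#' @export
write_wav <- function(samples, path, sample_rate_hz,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bits <- if (format == "pcm16") 16L else 32L
  audio_fmt <- if (format == "pcm16") 1L else 3L
  block <- bits / 8L
  data_bytes <- n * block
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * block), con, size = 4,
           endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) rlang::abort("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) rlang::abort("not a RIFF/WAVE file")
  fmt <- NULL; rate <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) rlang::abort("no data chunk")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (fmt == 1L && bits == 16L) {
        x <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt == 3L && bits == 32L) {
        x <- readBin(con, "numeric", size / 4, size = 4, endian = "little")
      } else rlang::abort("unsupported WAV encoding")
      return(list(samples = x, sample_rate_hz = rate))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

#' Read a raw field-potential trace
#'
#' Accepts a WAV file or a single-column CSV with a JSON sidecar
#' (`<path>.json` containing `sample_rate_hz`).
#'
#' @param path input file; `.wav` or `.csv`.
#' @return A list of class `raw_trace` with `samples` and
#'   `sample_rate_hz`.
#' @export
read_raw_trace <- function(path) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    w <- read_wav(path)
    raw_trace(w$samples, w$sample_rate_hz)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    x <- utils::read.csv(path)[[1]]
    raw_trace(x, meta$sample_rate_hz)
  }
}

#' Construct a raw trace object
#'
#' @param samples numeric voltage samples; must be finite.
#' @param sample_rate_hz sampling rate, Hz; must exceed 300 Hz so the
#'   70-150 Hz band is representable.
#' @return A list of class `raw_trace`.
#' @export
raw_trace <- function(samples, sample_rate_hz) {
  if (!all(is.finite(samples))) rlang::abort("trace must be finite")
  if (sample_rate_hz <= 300)
    rlang::abort("sample rate must exceed 300 Hz to contain 70-150 Hz")
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz), class = "raw_trace")
}

#' Write a high-gamma series as CSV
#'
#' Columns `time_s` and `log_power`.
#'
#' @param hg an [extract_high_gamma()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_high_gamma_csv <- function(hg, path) {
  tt <- (seq_along(hg$log_power) - 1) / hg$output_rate_hz
  utils::write.csv(data.frame(time_s = tt, log_power = hg$log_power),
                   path, row.names = FALSE)
  invisible(path)
}
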