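# External representations: RIFF PCM WAV, EDF, delimited matrices with
# key-value sidecars, ratings CSV, JSON result records.

#' Read a PCM WAV file
#'
#' Reads RIFF PCM audio (8/16/32-bit integer or 32/64-bit float). Multichannel
#' files are averaged to mono; integer samples are scaled to [-1, 1].
#'
#' @param path file path.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk in ", path)
  bytes <- fmt$bits / 8
  n_total <- length(data_raw) %/% (bytes * fmt$channels)
  if (fmt$audio_format == 1) {          # integer PCM
    if (fmt$bits == 8) {
      x <- (as.integer(data_raw) - 128) / 128
    } else if (fmt$bits == 16) {
      x <- readBin(data_raw, "integer", n_total * fmt$channels, 2,
                   signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 32) {
      x <- readBin(data_raw, "integer", n_total * fmt$channels, 4,
                   endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$audio_format == 3) {   # IEEE float
    x <- readBin(data_raw, "double", n_total * fmt$channels, bytes,
                 endian = "little")
  } else stop("unsupported WAV format code: ", fmt$audio_format)
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  waveform(x, fmt$rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param w a [waveform()]; samples are clipped to [-1, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")              # PCM, mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate) * 2L, con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

#' Write an EDF file
#'
#' Minimal European Data Format writer (16-bit samples, 1-second data
#' records). Used to exchange synthetic EEG and in tests.
#'
#' @param e an [eeg_recording()] with an integer sampling rate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(e, path) {
  stopifnot(inherits(e, "eeg_recording"))
  rate <- as.integer(round(e$rate))
  if (abs(rate - e$rate) > 1e-9) stop("EDF writer requires an integer rate")
  nch <- nrow(e$data)
  nrec <- ncol(e$data) %/% rate
  if (nrec < 1) stop("recording shorter than one data record")
  dat <- e$data[, seq_len(nrec * rate), drop = FALSE]
  pmin_ <- apply(dat, 1, min); pmax_ <- apply(dat, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("cacor", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field(1, 8), pad_field(nch, 4))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", width = width),
                    collapse = ""), con, eos = NULL, useBytes = TRUE)
  field(e$channel_labels, 16)
  field(rep("", nch), 80)
  field(rep("uV", nch), 8)
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep(-32768, nch), 8)
  field(rep(32767, nch), 8)
  field(rep("", nch), 80)
  field(rep(rate, nch), 8)
  field(rep("", nch), 32)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (c in seq_len(nch)) {
      dig <- round((dat[c, idx] - pmin_[c]) / (pmax_[c] - pmin_[c]) *
                     65535 - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  nbytes_hdr <- as.integer(substr(hdr, 185, 192))
  nrec <- as.integer(substr(hdr, 237, 244))
  nch <- as.integer(substr(hdr, 253, 256))
  dur <- as.numeric(substr(hdr, 245, 252))
  sig_hdr <- readChar(con, nbytes_hdr - 256, useBytes = TRUE)
  # field offsets in bytes within the per-signal header block:
  off <- c(label = 0, transducer = 16 * nch, dim = 96 * nch,
           pmin = 104 * nch, pmax = 112 * nch, dmin = 120 * nch,
           dmax = 128 * nch, prefilter = 136 * nch, nsamp = 216 * nch)
  getf <- function(key, width) {
    base <- off[[key]]
    vapply(seq_len(nch), function(i)
      trimws(substr(sig_hdr, base + (i - 1) * width + 1,
                    base + i * width)), "")
  }
  labels <- getf("label", 16)
  pmin_ <- as.numeric(getf("pmin", 8))
  pmax_ <- as.numeric(getf("pmax", 8))
  dmin_ <- as.numeric(getf("dmin", 8))
  dmax_ <- as.numeric(getf("dmax", 8))
  nsamp <- as.integer(getf("nsamp", 8))
  if (length(unique(nsamp)) != 1)
    stop("EDF with heterogeneous per-signal rates is not supported")
  ns <- nsamp[1]
  dat <- matrix(0, nch, nrec * ns)
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", nch * ns, 2, signed = TRUE,
                     endian = "little")
    m <- matrix(block, nrow = ns, ncol = nch)   # signals sequential in record
    dat[, ((r - 1) * ns + 1):(r * ns)] <- t(m)
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  dat <- (dat - dmin_) * scale + pmin_
  list(data = dat, rate = ns / dur, labels = labels)
}

parse_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    out[[key]] <- val
  }
  out
}

#' Read an EEG recording
#'
#' Accepts either an EDF file or a delimited numeric matrix with a key-value
#' sidecar file (`rate`, `labels` comma-separated, optional `subject_id`,
#' `stimulus_id`, `presentation_index`). Orientation is enforced to channels
#' on rows: a matrix whose column count matches the label count is
#' transposed. Earlobe channels A1/A2 are dropped (they are outside the head
#' model), with a message.
#'
#' @param path EDF or delimited matrix file.
#' @param metadata for matrix input, path to the sidecar file or a named list
#'   with the same keys; ignored for EDF except for the identity fields.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- if (is.character(metadata)) parse_sidecar(metadata)
          else if (is.list(metadata)) metadata else list()
  is_edf <- grepl("\\.edf$", path, ignore.case = TRUE)
  if (is_edf) {
    raw <- read_edf_matrix(path)
    dat <- raw$data; rate <- raw$rate; labels <- raw$labels
  } else {
    dat <- as.matrix(utils::read.table(path, header = FALSE, sep = "",
                                       colClasses = "numeric"))
    dimnames(dat) <- NULL
    if (is.null(meta$rate)) stop("matrix EEG input requires a sidecar 'rate'")
    rate <- as.numeric(meta$rate)
    if (is.null(meta$labels)) stop("matrix EEG input requires sidecar 'labels'")
    labels <- trimws(strsplit(meta$labels, ",")[[1]])
    if (nrow(dat) != length(labels)) {
      if (ncol(dat) == length(labels)) {
        dat <- t(dat)
      } else {
        stop("matrix shape matches the label count on neither axis")
      }
    }
  }
  drop <- toupper(labels) %in% c("A1", "A2")
  if (any(drop)) {
    message("dropping earlobe channel(s) outside the head model: ",
            paste(labels[drop], collapse = ", "))
    dat <- dat[!drop, , drop = FALSE]
    labels <- labels[!drop]
  }
  eeg_recording(dat, rate, labels,
                subject_id = if (!is.null(meta$subject_id))
                  meta$subject_id else NA_character_,
                stimulus_id = if (!is.null(meta$stimulus_id))
                  meta$stimulus_id else NA_character_,
                presentation_index = if (!is.null(meta$presentation_index))
                  as.integer(meta$presentation_index) else NA_integer_)
}

#' Read a continuous-rating CSV
#'
#' One column per rater, header row, uniform sampling.
#'
#' @param path CSV path.
#' @param rate sampling rate in Hz (default 50, the joystick rate).
#' @param stimulus_id stimulus identifier.
#' @return A [rating_set()].
#' @export
read_ratings <- function(path, rate = 50, stimulus_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  if (nrow(df) == 0) stop("empty ratings file: ", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric rating values in ", path)
  rating_set(t(m), rate = rate, stimulus_id = stimulus_id)
}

#' Write a result record as JSON
#'
#' Serializes any result record (plus a config echo and version tag) to
#' structured JSON. Non-finite numbers are serialized as null.
#'
#' @param results a list or S3 record.
#' @param path output path.
#' @param config optional [run_config()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = NULL) {
  payload <- list(
    version = as.character(utils::packageVersion("cacor")),
    class = class(results)[1],
    config = if (!is.null(config)) unclass(config),
    results = unclass_rec(results))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_rec)
    attr(x, "class") <- NULL
    x
  } else x
}

#' Read back a result record written by [write_results()]
#'
#' @param path JSON path.
#' @return The `results` payload with nulls restored to `NA`.
#' @export
read_results <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- restore_nulls(obj$results)
  if (!is.null(obj$class) && obj$class != "list") class(res) <- obj$class
  res
}

# JSON null round-trips to NA, not to a dropped field
restore_nulls <- function(x) {
  if (is.null(x)) return(NA)
  if (is.list(x)) return(lapply(x, restore_nulls))
  x
}
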