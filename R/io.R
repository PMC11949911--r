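# Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32) plus
# JSON (de)serialization of filter settings.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float32 mono/stereo files.
#'
#' @param path file path.
#' @return An [AudioBuffer-class].
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmtRaw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = sum(as.integer(fmtRaw[1:2]) * c(1, 256)),
        channels = sum(as.integer(fmtRaw[3:4]) * c(1, 256)),
        sampleRate = sum(as.integer(fmtRaw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(fmtRaw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw)) stop("missing fmt/data chunk: ", path)
  nc <- fmt$channels
  x <- if (fmt$audioFormat == 3L && fmt$bits == 32L) {
    readBin(dataRaw, "numeric", length(dataRaw) / 4, size = 4,
            endian = "little")
  } else if (fmt$audioFormat == 1L && fmt$bits == 16L) {
    readBin(dataRaw, "integer", length(dataRaw) / 2, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audioFormat == 1L && fmt$bits == 24L) {
    b <- as.integer(dataRaw)
    n <- length(b) / 3
    v <- b[seq(1, by = 3, length.out = n)] +
         b[seq(2, by = 3, length.out = n)] * 256 +
         b[seq(3, by = 3, length.out = n)] * 65536
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else stop("unsupported WAV format (format tag ", fmt$audioFormat,
              ", ", fmt$bits, " bits)")
  audioBuffer(matrix(x, ncol = nc, byrow = TRUE), fmt$sampleRate)
}

#' Write a WAV file
#'
#' @param audio an [AudioBuffer-class].
#' @param path output file path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(audio, path, format = c("pcm16", "float32")) {
  stopifnot(is(audio, "AudioBuffer"))
  format <- match.arg(format)
  s <- t(audio@samples)  # interleave channels
  nc <- nChannels(audio)
  fs <- as.integer(round(audio@sampleRate))
  bytesPer <- if (format == "pcm16") 2L else 4L
  dataSize <- length(s) * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (format == "pcm16") 1 else 3), con, size = 2,
           endian = "little")
  writeBin(as.integer(nc), con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * nc * bytesPer), con, size = 4, endian = "little")
  writeBin(as.integer(nc * bytesPer), con, size = 2, endian = "little")
  writeBin(as.integer(8 * bytesPer), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (format == "pcm16") {
    v <- as.integer(pmin(pmax(round(as.numeric(s) * 32768), -32768), 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(s), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read / write filter settings as flat JSON
#'
#' Settings are serialized as a flat JSON object keyed `<filter>.<param>`
#' plus a `"task"` entry.
#'
#' @param settings a [FilterSettings-class].
#' @param path file path.
#' @return `readSettings`: a [FilterSettings-class].
#' @export
writeSettings <- function(settings, path) {
  stopifnot(is(settings, "FilterSettings"))
  obj <- c(list(task = settings@task), as.list(settings@values))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn writeSettings read settings back; unknown or out-of-range keys
#'   raise an error naming them.
#' @export
readSettings <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$task)) stop("settings JSON must contain a 'task' entry")
  task <- obj$task
  obj$task <- NULL
  filterSettings(task, values = unlist(obj))
}
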