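#' Waveform synthesis specification
#'
#' Describes a synthetic hydrophone recording: stationary Gaussian ambient
#' noise at a given level (dB re full scale), plus zero or more broadband
#' detonation-like transients. Each transient rises to its peak within
#' `rise_time` (default 1 ms, an unambiguous "near instantaneous" onset)
#' and decays as an exponential reverberation tail with time constant
#' `reverb_time_constant`.
#'
#' @param sample_rate Hz (> 0); the fielded recorders used 50 kHz, but any
#'   rate is accepted (test fixtures use lower rates)
#' @param duration seconds
#' @param ambient_level ambient RMS level, dB re full scale (negative)
#' @param transients data.frame with columns `onset` (s), `peak_db`
#'   (dB above ambient, > 0) and `tau` (reverberation time constant, s);
#'   NULL for noise only
#' @param rise_time onset ramp length in seconds
#' @param seed integer; rendering is deterministic given the seed
#'   (stream `seed + 2`)
#' @return object of class `waveform_spec`
#' @export
waveform_spec <- function(sample_rate = 4000, duration = 60,
                          ambient_level = -40, transients = NULL,
                          rise_time = 1e-3, seed = 1L) {
  if (sample_rate <= 0) stop("parameter error: sample_rate must be > 0")
  if (!is.null(transients)) {
    stopifnot(all(c("onset", "peak_db", "tau") %in% names(transients)))
    if (any(transients$onset < 0 | transients$onset >= duration))
      stop("transient onsets must lie in [0, duration)")
    if (any(transients$peak_db <= 0))
      stop("parameter error: transient peak level must be > 0 dB")
  }
  structure(list(sample_rate = sample_rate, duration = duration,
                 ambient_level = ambient_level, transients = transients,
                 rise_time = rise_time, seed = as.integer(seed)),
            class = "waveform_spec")
}

#' Render a synthetic waveform
#'
#' Ambient noise is white Gaussian with RMS `10^(ambient_level/20)` (re full
#' scale). A transient is broadband noise whose amplitude envelope ramps
#' linearly to `ambient RMS * 10^(peak_db/20)` over `rise_time` and then
#' decays as `exp(-(t - onset)/tau)`.
#'
#' @param spec a [waveform_spec()]
#' @return numeric vector of samples with attribute `sample_rate`
#' @export
synthesize_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration * sr)
  amb_rms <- 10^(spec$ambient_level / 20)
  set.seed(spec$seed + 2L)
  x <- stats::rnorm(n, sd = amb_rms)
  tr <- spec$transients
  if (!is.null(tr) && nrow(tr) > 0) {
    t <- (seq_len(n) - 1L) / sr
    for (i in seq_len(nrow(tr))) {
      dt <- t - tr$onset[i]
      env <- ifelse(dt < 0, 0,
                    pmin(dt / spec$rise_time, 1) * exp(-pmax(dt, 0) / tr$tau[i]))
      peak_rms <- amb_rms * 10^(tr$peak_db[i] / 20)
      idx <- which(env > 1e-6)
      if (length(idx))
        x[idx] <- x[idx] + stats::rnorm(length(idx)) * peak_rms * env[idx]
    }
  }
  structure(x, sample_rate = sr)
}

#' Minimal mono PCM WAV writer
#'
#' Writes a numeric vector (full scale `[-1, 1]`, clipped) as a mono RIFF/WAVE
#' file with 16- or 24-bit integer PCM samples.
#'
#' @param samples numeric vector
#' @param sample_rate Hz
#' @param path output file
#' @param bits 16 or 24
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  stopifnot(bits %in% c(16, 24))
  bytes <- bits / 8
  n <- length(samples)
  x <- pmin(pmax(samples, -1), 1)
  scale <- 2^(bits - 1) - 1
  ints <- as.integer(round(x * scale))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(ints, con, size = 2, endian = "little")
  } else {
    neg <- ints < 0
    u <- ints
    u[neg] <- u[neg] + 2^24
    raw3 <- sapply(u, function(v)
      as.raw(c(v %% 256, (v %/% 256) %% 256, v %/% 65536)))
    writeBin(as.vector(raw3), con)
  }
  invisible(path)
}

#' Minimal mono PCM WAV reader (16/24-bit)
#'
#' @param path WAV file written by [write_wav()] or any mono integer-PCM WAV
#' @return numeric samples in `[-1, 1]` with attribute `sample_rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  sample_rate <- NA_integer_; bits <- NA_integer_; channels <- 1L
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (identical(id, "data")) {
      if (bits == 16) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           endian = "little") / (2^15 - 1)
      } else if (bits == 24) {
        r <- readBin(con, raw(), n = size)
        m <- matrix(as.integer(r), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v[v >= 2^23] <- v[v >= 2^23] - 2^24
        samples <- v / (2^23 - 1)
      } else stop("unsupported bit depth: ", bits)
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (channels != 1) stop("only mono WAV supported")
  structure(samples, sample_rate = sample_rate)
}
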