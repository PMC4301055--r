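## Feature extraction: the 14 acoustic variables of one contact call.
## Analysis conventions: 11025 Hz working rate, 50 Hz high-pass, spectrogram
## frames of 512 samples (Hamming) zero-padded to a 1024-point FFT.

.vocalid_rate <- 11025

## Periodic-sinc (FFT-domain) resampling to `n_out` samples. Exact for
## band-limited content; brick-wall anti-aliasing on downsampling.
.fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  ## mirror-pad so the implicit periodic extension has no step discontinuity
  ## (which would otherwise spray broadband energy near the signal edges)
  np <- min(n, 2048L)
  xp <- c(rev(x[seq_len(np)]), x, rev(x[(n - np + 1L):n]))
  mp <- as.integer(round(np * n_out / n))
  y <- .fft_resample_core(xp, n_out + 2L * mp)
  return(y[(mp + 1L):(mp + n_out)])
}

.fft_resample_core <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  half <- min(n, n_out)
  kpos <- seq_len(ceiling(half / 2))
  Y[kpos] <- X[kpos]
  nneg <- floor((half - 1) / 2)
  if (nneg > 0) {
    kneg <- seq_len(nneg)
    Y[n_out - kneg + 1] <- X[n - kneg + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

## Linear-phase FIR high-pass, applied with group-delay compensation so that
## temporal landmarks (onset, offset, dur-to-max) are not shifted.
.highpass <- function(x, rate, cutoff) {
  ord <- 1536L  # transition band narrow enough to reach -40 dB by 30 Hz
  b <- signal::fir1(ord, cutoff / (rate / 2), type = "high")
  ## mirror-pad so the convolution's partial-overlap region sees signal
  ## rather than silence (suppresses edge transients), then remove the
  ## linear-phase group delay
  n <- length(x)
  np <- min(n - 1L, ord)
  ## odd (point) reflection: continuous in value and slope at the joins
  xp <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- signal::fftfilt(b, c(xp, numeric(ord)))
  y[(np + ord / 2 + 1):(np + ord / 2 + n)]
}

#' Standardize a waveform for analysis
#'
#' Resamples to the 11025 Hz working rate and applies a 50 Hz high-pass filter
#' (linear-phase FIR, delay-compensated), attenuating low-frequency background
#' noise by more than 40 dB. Upsampling is refused: recordings are expected at
#' 11025 Hz or above.
#'
#' @param w A [waveform()].
#' @param rate Target sampling rate (Hz); default 11025.
#' @param highpass High-pass cutoff (Hz); `0` disables filtering.
#' @return A [waveform()] at `rate` Hz.
#' @export
preprocess <- function(w, rate = .vocalid_rate, highpass = 50) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate < rate)
    stop(sprintf("input rate %g Hz is below the %g Hz working rate; refusing to upsample",
                 w$rate, rate))
  x <- w$samples
  if (w$rate > rate)
    x <- .fft_resample(x, as.integer(round(length(x) * rate / w$rate)))
  if (highpass > 0)
    x <- .highpass(x, rate, highpass)
  waveform(x, rate)
}

#' Detect call onset and offset by an energy threshold
#'
#' Block RMS energy (10 ms blocks) is compared against a threshold relative to
#' the loudest block; the call spans the first to the last block above
#' threshold. Synthetic calls carry exact bounds, so this detector is mainly
#' for field recordings where bounds are not annotated.
#'
#' @param w A [waveform()].
#' @param threshold_db Threshold relative to the call peak (dB); default -25.
#' @param block Block length in seconds; default 0.01.
#' @return Named numeric vector `c(onset, offset)` in seconds.
#' @export
detect_call_bounds <- function(w, threshold_db = -25, block = 0.01) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  bl <- max(1L, as.integer(round(block * w$rate)))
  nb <- n %/% bl
  if (nb < 1L) stop("waveform shorter than one energy block; onset undetectable")
  m <- matrix(w$samples[seq_len(nb * bl)], nrow = bl)
  rms <- sqrt(colMeans(m^2))
  thr <- max(rms) * 10^(threshold_db / 20)
  above <- which(rms >= thr)
  if (length(above) == 0L || max(rms) == 0)
    stop("no energy above threshold; onset undetectable")
  c(onset = (min(above) - 1) * bl / w$rate,
    offset = max(above) * bl / w$rate)
}

#' Summary statistics of a fundamental-frequency contour
#'
#' @param contour An `f0_contour` from [extract_f0_contour()].
#' @return List with `f0beg`, `f0end`, `f0max`, `f0min`, `f0mean`, `delta_f0`
#'   (all Hz) and `t_f0max`, the time (s) of the contour maximum.
#' @export
measure_f0_stats <- function(contour) {
  stopifnot(inherits(contour, "f0_contour"))
  v <- contour[contour$voiced, , drop = FALSE]
  if (nrow(v) < 2L)
    stop("f0 contour has fewer than 2 voiced frames; cannot measure f0 statistics")
  imax <- which.max(v$f0)
  list(
    f0beg = v$f0[1L],
    f0end = v$f0[nrow(v)],
    f0max = v$f0[imax],
    f0min = min(v$f0),
    f0mean = mean(v$f0),
    delta_f0 = v$f0[imax] - min(v$f0),
    t_f0max = v$time[imax]
  )
}

#' Temporal variables of a call
#'
#' `durat` is the call duration; `dur_to_max` the time from call onset to the
#' fundamental-frequency maximum.
#'
#' @param w A [waveform()]; used to detect bounds when `onset`/`offset` are
#'   not supplied.
#' @param contour An `f0_contour` covering the call.
#' @param onset,offset Call bounds in seconds; detected by
#'   [detect_call_bounds()] when `NULL`.
#' @return List with `durat` and `dur_to_max` (s).
#' @export
measure_temporal <- function(w, contour, onset = NULL, offset = NULL) {
  if (is.null(onset) || is.null(offset)) {
    b <- detect_call_bounds(w)
    if (is.null(onset)) onset <- b[["onset"]]
    if (is.null(offset)) offset <- b[["offset"]]
  }
  st <- measure_f0_stats(contour)
  durat <- unname(offset - onset)
  list(durat = durat,
       dur_to_max = unname(min(max(st$t_f0max - onset, 0), durat)))
}

#' Mean power spectrum of a 50 ms fragment around the f0 maximum
#'
#' Averages Hamming-windowed power spectra (512-sample frames zero-padded to a
#' 1024-point FFT, 16-sample hop) over the 50 ms fragment centered on the
#' fundamental-frequency maximum. The fragment is clipped (never zero-padded)
#' at call bounds.
#'
#' @param w A [waveform()] at the working rate.
#' @param t_f0max Time (s) of the f0 maximum.
#' @param onset,offset Call bounds (s); default to the waveform extent.
#' @param window Fragment length (s); default 0.05.
#' @return A `power_spectrum`: data frame with `freq` (Hz) and `power`
#'   (linear, arbitrary units).
#' @export
mean_power_spectrum_50ms <- function(w, t_f0max, onset = NULL, offset = NULL,
                                     window = 0.05) {
  stopifnot(inherits(w, "waveform"))
  rate <- w$rate
  n <- length(w$samples)
  if (is.null(onset)) onset <- 0
  if (is.null(offset)) offset <- n / rate
  if (t_f0max < onset || t_f0max > offset)
    stop("t_f0max lies outside the call")
  lo <- max(onset, t_f0max - window / 2)
  hi <- min(offset, t_f0max + window / 2)
  i0 <- max(1L, as.integer(round(lo * rate)) + 1L)
  i1 <- min(n, as.integer(round(hi * rate)))
  frag <- w$samples[i0:i1]
  win_len <- 512L
  nfft <- 1024L
  hop <- 16L
  if (length(frag) < win_len) win_len <- 256L  # short calls clipped at edges
  if (length(frag) < win_len)
    stop("call fragment shorter than one analysis frame (",
         round(win_len / rate * 1000), " ms)")
  ham <- signal::hamming(win_len)
  starts <- seq(1L, length(frag) - win_len + 1L, by = hop)
  acc <- numeric(nfft / 2 + 1)
  for (s in starts) {
    fr <- frag[s:(s + win_len - 1L)] * ham
    X <- stats::fft(c(fr, numeric(nfft - win_len)))
    acc <- acc + Mod(X[seq_len(nfft / 2 + 1)])^2
  }
  out <- data.frame(freq = (seq_len(nfft / 2 + 1) - 1) * rate / nfft,
                    power = acc / length(starts))
  class(out) <- c("power_spectrum", "data.frame")
  out
}

#' Spectral-energy variables from a call power spectrum
#'
#' `fpeak` is the frequency of maximum amplitude; `q25`, `q50`, `q75` the
#' frequencies below which 25/50/75% of the spectral energy lies; `peak_harm`
#' the order of the harmonic carrying the peak (`round(fpeak / f0)`); and
#' `power_f0` the dB difference between the peak-harmonic band and the f0
#' band. A "band" is the set of FFT bins within half an f0 spacing of the
#' harmonic center. `power_f0` is 0 exactly when the f0 band is the peak band.
#'
#' @param spectrum A `power_spectrum` from [mean_power_spectrum_50ms()].
#' @param f0_at_max Fundamental frequency (Hz) at the spectrum's time point.
#' @return List with `fpeak`, `q25`, `q50`, `q75` (Hz), `power_f0` (dB,
#'   non-negative) and `peak_harm` (integer >= 1).
#' @export
measure_power_vars <- function(spectrum, f0_at_max) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (!is.numeric(f0_at_max) || f0_at_max <= 0)
    stop("f0_at_max must be positive")
  p <- spectrum$power
  f <- spectrum$freq
  total <- sum(p)
  if (total <= 0) stop("zero-energy spectrum")
  fpeak <- f[which.max(p)]
  cum <- cumsum(p)
  qat <- function(frac) f[which(cum >= frac * total)[1L]]
  peak_harm <- max(1L, as.integer(round(fpeak / f0_at_max)))
  band_level <- function(k) {
    idx <- abs(f - k * f0_at_max) <= f0_at_max / 2
    10 * log10(sum(p[idx]) + .Machine$double.xmin)
  }
  power_f0 <- if (peak_harm == 1L) 0 else max(0, band_level(peak_harm) - band_level(1L))
  list(fpeak = fpeak, q25 = qat(0.25), q50 = qat(0.50), q75 = qat(0.75),
       power_f0 = power_f0, peak_harm = peak_harm)
}

#' Extract the 14 acoustic variables from one call
#'
#' Runs the full measurement chain: preprocessing (if needed), call-bound
#' determination, cross-correlation f0 contour extraction with parameters set
#' by the caller class, f0 statistics, temporal variables, and
#' spectral-energy variables from the 50 ms spectrum around the f0 maximum.
#'
#' @param w A [waveform()].
#' @param meta List or one-row data frame of call metadata; must contain
#'   `caller_class` (`"hind"` or `"calf"`). Other columns (e.g. `call_id`,
#'   `individual_id`, `call_type`, `sex`, `year`, `body_mass_kg`) are carried
#'   through to the output.
#' @param onset,offset Call bounds in seconds; detected from energy when
#'   `NULL`.
#' @return One-row data frame: the metadata columns followed by the 14
#'   variables of [call_feature_names()].
#' @export
extract_features <- function(w, meta, onset = NULL, offset = NULL) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"caller_class" %in% names(meta))
    stop("meta must contain `caller_class`")
  id <- if ("call_id" %in% names(meta)) meta$call_id[1L] else "<unnamed>"
  tryCatch({
    if (w$rate != .vocalid_rate) w <- preprocess(w)
    if (is.null(onset) || is.null(offset)) {
      b <- detect_call_bounds(w)
      if (is.null(onset)) onset <- b[["onset"]]
      if (is.null(offset)) offset <- b[["offset"]]
    }
    pp <- pitch_params(meta$caller_class[1L])
    contour <- extract_f0_contour(w, pp, onset = onset, offset = offset)
    st <- measure_f0_stats(contour)
    tm <- measure_temporal(w, contour, onset = onset, offset = offset)
    sp <- mean_power_spectrum_50ms(w, st$t_f0max, onset = onset, offset = offset)
    pw <- measure_power_vars(sp, f0_at_max = st$f0max)
    feats <- data.frame(
      durat = tm$durat, dur_to_max = tm$dur_to_max,
      f0beg = st$f0beg, f0end = st$f0end, f0max = st$f0max,
      f0min = st$f0min, f0mean = st$f0mean, delta_f0 = st$delta_f0,
      fpeak = pw$fpeak, q25 = pw$q25, q50 = pw$q50, q75 = pw$q75,
      power_f0 = pw$power_f0, peak_harm = pw$peak_harm
    )
    cbind(meta, feats)
  }, error = function(e) {
    stop("feature extraction failed for call ", id, ": ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Extract a feature table from a set of synthetic calls
#'
#' @param calls List of `synth_call` objects from [synth_call()] or
#'   [synth_calls()].
#' @param use_truth_bounds Use the generator's exact call bounds (default);
#'   set `FALSE` to exercise energy-based bound detection.
#' @return Data frame with one row per call: metadata plus the 14 variables.
#' @export
extract_feature_table <- function(calls, use_truth_bounds = TRUE) {
  stopifnot(length(calls) > 0)
  rows <- lapply(calls, function(cl) {
    if (use_truth_bounds)
      extract_features(cl$wave, cl$meta, onset = cl$onset, offset = cl$offset)
    else
      extract_features(cl$wave, cl$meta)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
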