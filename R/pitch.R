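## Fundamental-frequency contour extraction.
##
## Primary tracker: per-frame normalized cross-correlation, two passes. The
## first pass searches the whole [floor, ceiling] lag range with a window of
## one floor-period; the second pass re-estimates each frame with a short
## window (~1.5 periods) sized from the smoothed first-pass contour, which
## keeps the effective analysis span small so that frames near call edges and
## in frequency-modulated segments track the instantaneous f0 closely.
## A spectrogram-peak tracker is provided as an independent consistency
## estimator.

## normalized cross-correlation of x[start..start+L-1] against itself at lags
## lag_min..lag_max; returns c(interpolated_lag, peak_correlation).
## The correlation function is sinc-oversampled (spectral zero-padding, 4x)
## before peak picking: broadband voiced signals have correlation peaks only
## ~2 samples wide, so an integer lag grid undersamples the true-period peak
## while a near-integer multiple-period peak is sampled exactly, which would
## bias selection toward sub-octaves. Among near-maximal local peaks the
## shortest lag wins (multiples of the true period tie for periodic signals).
.frame_xcorr <- function(x, start, L, lag_min, lag_max, os = 4L) {
  span <- L + lag_max
  seg <- x[start:(start + span - 1L)]
  sw <- seg[seq_len(L)]
  e0 <- sum(sw * sw)
  if (e0 <= 0) return(c(NA_real_, 0))
  nfft <- 2^ceiling(log2(span + L))
  S1 <- stats::fft(c(sw, numeric(nfft - L)))
  S2 <- stats::fft(c(seg, numeric(nfft - span)))
  C <- Conj(S1) * S2
  half <- nfft %/% 2L
  C4 <- c(C[seq_len(half)], C[half + 1L] / 2,
          complex(length.out = (os - 1L) * nfft - 1L),
          C[half + 1L] / 2, C[(half + 2L):nfft])
  cc <- Re(stats::fft(C4, inverse = TRUE)) / nfft
  idx <- (lag_min * os):(lag_max * os) + 1L
  lagf <- (idx - 1L) / os
  ## running energy of the lagged window, linearly interpolated to the
  ## fine lag grid
  cs <- cumsum(seg * seg)
  il <- lag_min:lag_max
  el_int <- cs[il + L] - cs[il]
  el <- stats::approx(il, el_int, xout = lagf, rule = 2)$y
  r <- cc[idx] / sqrt(e0 * pmax(el, .Machine$double.eps))
  rmax <- max(r)
  n_r <- length(r)
  ## only interior local maxima qualify: a rising edge at the lag-range
  ## boundary is not a period candidate
  is_peak <- c(FALSE,
               if (n_r > 2L) r[2:(n_r - 1L)] >= r[1:(n_r - 2L)] &
                             r[2:(n_r - 1L)] >= r[3:n_r],
               FALSE)
  cand <- which(is_peak & r >= rmax - 0.02)
  if (!length(cand)) return(c(NA_real_, 0))
  j <- cand[1L]
  lag <- lagf[j]
  if (j > 1L && j < n_r) {
    den <- r[j - 1L] - 2 * r[j] + r[j + 1L]
    if (is.finite(den) && den < 0) {
      d <- 0.5 * (r[j - 1L] - r[j + 1L]) / den
      if (abs(d) <= 1) lag <- lag + d / os
    }
  }
  c(lag, r[j])
}

## median-based octave-jump repair: frames deviating > 60% from the local
## median are halved/doubled towards it, or marked unvoiced if still deviant
.repair_octave_jumps <- function(f0, voiced, floor, ceiling) {
  vi <- which(voiced)
  nv <- length(vi)
  if (nv < 3L) return(list(f0 = f0, voiced = voiced))
  ## two sequential passes (forward then backward) against a clipped-window
  ## local median; repaired values replace originals immediately and frames
  ## marked unvoiced drop out of later medians, so a run of consistent
  ## outliers at either contour end cannot become its own reference
  fwork <- ifelse(voiced, f0, NA_real_)
  for (ord in list(seq_len(nv), rev(seq_len(nv)))) {
    for (j in ord) {
      i <- vi[j]
      if (is.na(fwork[i])) next
      nb <- fwork[vi[setdiff(max(1L, j - 3L):min(nv, j + 3L), j)]]
      nb <- nb[!is.na(nb)]
      if (length(nb) < 2L) next
      med <- stats::median(nb)
      ## multiplicative deviation, so halvings and doublings are treated
      ## symmetrically (a halved frame is -50% linearly but a full octave off)
      if (abs(log2(fwork[i] / med)) > log2(1.6)) {
        cand <- c(fwork[i] * 2, fwork[i] / 2)
        k <- which.min(abs(log2(cand / med)))
        if (abs(log2(cand[k] / med)) < log2(1.3) &&
            cand[k] >= floor && cand[k] <= ceiling) {
          fwork[i] <- cand[k]
        } else {
          fwork[i] <- NA_real_
        }
      }
    }
  }
  ## global plausibility gate: these contact calls are moderately modulated
  ## (max/median and min/median well inside [1/2.2, 1.6]), while harmonic
  ## mistracking lands near 2x or 0.5x of the local f0 — runs of such frames
  ## can defeat the local median above but not the whole-contour median
  keep <- !is.na(fwork)
  if (sum(keep) >= 3L) {
    med_all <- stats::median(fwork[keep])
    bad <- keep & (fwork > 1.6 * med_all | fwork < med_all / 2.2)
    fwork[bad] <- NA_real_
  }
  list(f0 = ifelse(is.na(fwork), f0, fwork), voiced = voiced & !is.na(fwork))
}

.contour_df <- function(time, f0, voiced, params) {
  out <- data.frame(time = time, f0 = f0, voiced = voiced)
  class(out) <- c("f0_contour", "data.frame")
  attr(out, "params") <- params
  out
}

#' Extract the fundamental-frequency contour by cross-correlation
#'
#' Frame-wise normalized cross-correlation pitch tracking within
#' `[p$floor, p$ceiling]` Hz at `p$time_step` intervals. Frames whose peak
#' normalized correlation falls below `voicing_threshold` are marked unvoiced.
#' Octave jumps are repaired deterministically by median-filter comparison
#' (frames deviating more than 60% from the local median are halved/doubled
#' toward it).
#'
#' @param w A [waveform()] (preprocessed; any rate accepted).
#' @param p Pitch parameters from [pitch_params()] or a list with `time_step`,
#'   `floor`, `ceiling`.
#' @param onset,offset Analysis limits in seconds; default to the full
#'   waveform.
#' @param voicing_threshold Minimum normalized correlation for a voiced frame
#'   (default 0.45).
#' @return An `f0_contour`: data frame with `time` (s), `f0` (Hz, `NA` when
#'   unvoiced) and `voiced` (logical).
#' @export
extract_f0_contour <- function(w, p, onset = NULL, offset = NULL,
                               voicing_threshold = 0.45) {
  stopifnot(inherits(w, "waveform"))
  rate <- w$rate
  x <- w$samples
  if (is.null(onset)) onset <- 0
  if (is.null(offset)) offset <- length(x) / rate
  i_lo <- max(1L, as.integer(floor(onset * rate)) + 1L)
  i_hi <- min(length(x), as.integer(ceiling(offset * rate)))
  lag_min <- max(2L, as.integer(floor(rate / p$ceiling)))
  lag_max <- as.integer(ceiling(rate / p$floor))
  L1 <- as.integer(round(rate / p$floor))
  span1 <- L1 + lag_max
  if (i_hi - i_lo + 1L < span1 + as.integer(p$time_step * rate))
    stop("call too short for f0 extraction (need at least 2 analysis frames)")

  times <- seq(onset, offset, by = p$time_step)
  nfr <- length(times)
  f0 <- rep(NA_real_, nfr)
  rpk <- numeric(nfr)

  ## pass 1: fixed window, full lag range, centered frames only
  for (k in seq_len(nfr)) {
    st <- as.integer(round(times[k] * rate)) + 1L - span1 %/% 2L
    if (st < i_lo || st + span1 - 1L > i_hi) next
    res <- .frame_xcorr(x, st, L1, lag_min, lag_max)
    if (is.finite(res[1L])) {
      f0[k] <- rate / res[1L]
      rpk[k] <- res[2L]
    }
  }
  voiced <- !is.na(f0) & rpk >= voicing_threshold &
    f0 >= p$floor & f0 <= p$ceiling
  rep1 <- .repair_octave_jumps(f0, voiced, p$floor, p$ceiling)
  f0 <- rep1$f0; voiced <- rep1$voiced

  nv <- sum(voiced)
  if (nv < 3L || nv / nfr < 0.2)
    return(.contour_df(times, ifelse(voiced, f0, NA_real_), voiced, p))

  ## pass 2: short adaptive windows sized from the smoothed pass-1 contour
  ref <- stats::approx(times[voiced], f0[voiced], xout = times, rule = 2)$y
  f0_2 <- rep(NA_real_, nfr)
  r_2 <- numeric(nfr)
  for (k in seq_len(nfr)) {
    lag_est <- rate / ref[k]
    L2 <- max(lag_min + 2L, as.integer(round(1.5 * lag_est)))
    lo2 <- max(lag_min, as.integer(floor(0.75 * lag_est)))
    hi2 <- min(lag_max, as.integer(ceiling(1.35 * lag_est)))
    if (hi2 <= lo2) next
    span2 <- L2 + hi2
    st0 <- as.integer(round(times[k] * rate)) + 1L - span2 %/% 2L
    st <- min(max(st0, i_lo), i_hi - span2 + 1L)  # shift window inside call
    if (st < i_lo) next
    ## a window displaced far from the frame time measures a different part
    ## of the contour; drop such edge frames rather than mislabel them
    if (abs(st - st0) > max(span2 %/% 4L, 8L)) next
    res <- .frame_xcorr(x, st, L2, lo2, hi2)
    if (is.finite(res[1L])) {
      f0_2[k] <- rate / res[1L]
      r_2[k] <- res[2L]
    }
  }
  voiced2 <- !is.na(f0_2) & r_2 >= voicing_threshold &
    f0_2 >= p$floor & f0_2 <= p$ceiling
  rep2 <- .repair_octave_jumps(f0_2, voiced2, p$floor, p$ceiling)
  .contour_df(times, ifelse(rep2$voiced, rep2$f0, NA_real_), rep2$voiced, p)
}

#' Spectrogram-peak fundamental-frequency estimate
#'
#' Independent f0 estimator used as a consistency check on the
#' cross-correlation tracker: per frame, the peak of the Hamming-windowed
#' power spectrum within `[p$floor, p$ceiling]`, refined by parabolic
#' interpolation on log power. Frames whose peak does not stand out from the
#' in-range median spectrum level are marked unvoiced.
#'
#' @inheritParams extract_f0_contour
#' @param prominence_db Minimum peak-above-median level for voicing (dB).
#' @return An `f0_contour`.
#' @export
estimate_f0_spectral <- function(w, p, onset = NULL, offset = NULL,
                                 prominence_db = 12) {
  stopifnot(inherits(w, "waveform"))
  rate <- w$rate
  x <- w$samples
  if (is.null(onset)) onset <- 0
  if (is.null(offset)) offset <- length(x) / rate
  i_lo <- max(1L, as.integer(floor(onset * rate)) + 1L)
  i_hi <- min(length(x), as.integer(ceiling(offset * rate)))
  win_len <- 2^ceiling(log2(4 * rate / p$floor))
  if (i_hi - i_lo + 1L < win_len + as.integer(p$time_step * rate))
    stop("call too short for spectral f0 estimation")
  nfft <- 4L * win_len
  ham <- signal::hamming(win_len)
  freqs <- (seq_len(nfft / 2 + 1L) - 1L) * rate / nfft
  in_range <- which(freqs >= p$floor & freqs <= p$ceiling)
  fv_range <- freqs[in_range]

  times <- seq(onset, offset, by = p$time_step)
  nfr <- length(times)
  f0 <- rep(NA_real_, nfr)
  voiced <- logical(nfr)
  for (k in seq_len(nfr)) {
    st0 <- as.integer(round(times[k] * rate)) + 1L - win_len %/% 2L
    st <- min(max(st0, i_lo), i_hi - win_len + 1L)
    if (st < i_lo) next
    ## drop frames whose window had to be displaced far from the frame time
    ## (they measure a different part of the contour)
    if (abs(st - st0) > win_len %/% 8L) next
    fr <- x[st:(st + win_len - 1L)] * ham
    P <- Mod(stats::fft(c(fr, numeric(nfft - win_len)))[seq_len(nfft / 2 + 1L)])^2
    pr <- P[in_range]
    med <- stats::median(pr) + .Machine$double.xmin
    ## candidate = local maxima; the fundamental is the LOWEST sufficiently
    ## strong peak, not the strongest (higher harmonics can carry more
    ## energy and may fall inside the search range)
    n_pr <- length(pr)
    is_pk <- c(pr[1L] > pr[2L],
               pr[2:(n_pr - 1L)] >= pr[1:(n_pr - 2L)] &
               pr[2:(n_pr - 1L)] > pr[3:n_pr],
               pr[n_pr] > pr[n_pr - 1L])
    ## voicing is gated on the strongest in-range peak standing out of the
    ## median level; the fundamental is then the lowest local peak within
    ## 20 dB of that maximum that is harmonically consistent with it: either
    ## the strongest peak itself, or a near-integer divisor of it with a
    ## supported second harmonic. The 20 dB floor keeps genuine fundamentals
    ## (a weak f0 band sits ~10 dB under the emphasized harmonic) while
    ## excluding noise-floor and windowing-skirt peaks
    if (10 * log10(max(pr) / med) < prominence_db) next
    strong <- which(is_pk & 10 * log10(pr / max(pr)) >= -20)
    if (!length(strong)) next
    f_top <- fv_range[which.max(pr)]
    sel <- NA_integer_
    for (s in strong) {
      fc <- fv_range[s]
      if (abs(fc - f_top) < 1e-9) { sel <- s; break }
      ratio <- f_top / fc
      if (abs(ratio / round(ratio) - 1) > 0.05) next
      has_h2 <- any(abs(fv_range[strong] / (2 * fc) - 1) <= 0.05)
      if (has_h2) { sel <- s; break }
    }
    if (is.na(sel)) sel <- which.max(pr)
    jj <- in_range[sel]
    fhat <- freqs[jj]
    if (jj > 1L && jj < length(freqs)) {
      y <- log10(P[(jj - 1L):(jj + 1L)] + .Machine$double.xmin)
      den <- y[1L] - 2 * y[2L] + y[3L]
      if (is.finite(den) && den < 0) {
        d <- 0.5 * (y[1L] - y[3L]) / den
        if (abs(d) <= 1) fhat <- fhat + d * rate / nfft
      }
    }
    ## estimates hugging the search-range bounds are artifact signatures
    ## (e.g. the low-frequency pile-up edge of an out-of-range harmonic
    ## sweeping through the ceiling), not credible fundamentals
    if (fhat >= 1.05 * p$floor && fhat <= 0.95 * p$ceiling) {
      f0[k] <- fhat
      voiced[k] <- TRUE
    }
  }
  rep1 <- .repair_octave_jumps(f0, voiced, p$floor, p$ceiling)
  .contour_df(times, ifelse(rep1$voiced, rep1$f0, NA_real_), rep1$voiced, p)
}
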