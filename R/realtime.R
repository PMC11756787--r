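#' Alpha asymmetry index of a single analysis window
#'
#' Computes the somatosensory alpha asymmetry index (AAI) from one 1,000 ms
#' multichannel EEG segment, exactly as the real-time feedback engine does:
#' each channel is demeaned, Hanning-tapered and Fourier transformed at
#' 1 Hz resolution; power is averaged over the 8--12 Hz bins and over the
#' right ({C4, CP4, CP6}) and left ({C3, CP3, CP5}) somatosensory channel
#' groups; the index is the normalized difference
#' `(alpha_right - alpha_left) / (alpha_right + alpha_left)`, in `[-1, 1]`.
#'
#' @param window numeric matrix, channels x samples, spanning exactly
#'   1,000 ms. Row names (or `channels`) identify the montage.
#' @param channels character vector of channel names, one per row; defaults
#'   to `rownames(window)`.
#' @param right,left channel groups averaged for the two hemispheres.
#' @param srate sampling rate in Hz (default 500).
#' @param band numeric length-2, frequency band in Hz averaged over
#'   (default `c(8, 12)`, i.e. bins 8, 9, 10, 11, 12 at 1 Hz resolution).
#' @return single numeric AAI; `NA` (with a warning) if total band power
#'   is zero, in which case the index is undefined.
#' @examples
#' w <- matrix(rnorm(6 * 500), 6, 500,
#'   dimnames = list(c("C3", "CP3", "CP5", "C4", "CP4", "CP6"), NULL)
#' )
#' compute_aai(w)
#' @export
compute_aai <- function(window, channels = rownames(window),
                        right = c("C4", "CP4", "CP6"),
                        left = c("C3", "CP3", "CP5"),
                        srate = 500, band = c(8, 12)) {
  stopifnot(is.matrix(window), is.numeric(window))
  if (is.null(channels)) stop("channel names are required")
  n <- ncol(window)
  if (abs(n / srate - 1) > 1e-9) {
    stop("window must span exactly 1,000 ms (", srate, " samples)")
  }
  missing <- setdiff(c(right, left), channels)
  if (length(missing)) {
    stop("window lacks required channels: ", paste(missing, collapse = ", "))
  }
  p <- window_band_power(window, srate, band)
  names(p) <- channels
  a_r <- mean(p[right])
  a_l <- mean(p[left])
  if (a_r + a_l == 0) {
    warning("zero total alpha power: AAI undefined")
    return(NA_real_)
  }
  (a_r - a_l) / (a_r + a_l)
}

# per-channel mean band power of a demeaned, Hanning-tapered window.
# One-sided amplitude normalization: a sinusoid of amplitude A centred on
# a bin contributes A^2 / 2 (its variance) to that bin.
window_band_power <- function(window, srate, band) {
  n <- ncol(window)
  x <- window - rowMeans(window)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  x <- sweep(x, 2L, taper, `*`)
  spec <- Mod(t(stats::mvfft(t(x))))^2 * 2 / sum(taper)^2
  freqs <- (seq_len(n) - 1L) * srate / n
  bins <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9 &
    freqs <= srate / 2)
  rowMeans(spec[, bins, drop = FALSE])
}

# sliding-window AAI over many window starts at once: per channel, all
# windows are stacked into one matrix and transformed with a single
# multivariate FFT (same demean/taper/binning as compute_aai)
batched_aai <- function(stream, starts, win, srate,
                        right = c("C4", "CP4", "CP6"),
                        left = c("C3", "CP3", "CP5"),
                        band = c(8, 12)) {
  chans <- c(right, left)
  missing <- setdiff(chans, rownames(stream))
  if (length(missing)) {
    stop("stream lacks required channels: ", paste(missing, collapse = ", "))
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1L) / (win - 1L))
  freqs <- (seq_len(win) - 1L) * srate / win
  bins <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9 &
    freqs <= srate / 2)
  idx <- outer(seq_len(win) - 1L, starts, `+`)
  power <- vapply(chans, function(nm) {
    w <- matrix(stream[nm, idx], nrow = win)
    w <- sweep(w, 2L, colMeans(w))
    colMeans(Mod(stats::mvfft(w * taper)[bins, , drop = FALSE])^2) *
      2 / sum(taper)^2
  }, numeric(length(starts)))
  if (length(starts) == 1L) power <- matrix(power, nrow = 1L)
  a_r <- rowMeans(power[, right, drop = FALSE])
  a_l <- rowMeans(power[, left, drop = FALSE])
  out <- (a_r - a_l) / (a_r + a_l)
  if (any(!is.finite(out))) {
    warning("zero total alpha power: AAI undefined for some windows")
    out[!is.finite(out)] <- NA_real_
  }
  out
}

#' Temporal smoothing of an AAI series
#'
#' Applies the causal, linearly weighted moving average used to stabilize
#' the visual feedback signal: the smoothed value at time `t` is the
#' integral of the piecewise-linearly interpolated raw series over the
#' trailing `delta_tau` seconds, weighted by
#' `W(tau) = 2 * (delta_tau - tau) / delta_tau^2` (which integrates to one
#' over its support). When less than `delta_tau` of history exists the
#' weights are renormalized over the available span; the very first sample
#' is returned unchanged.
#'
#' The product of the linear interpolant and the linear weight is
#' quadratic on every inter-sample segment, so each segment is integrated
#' exactly with Simpson's rule.
#'
#' @param series a data frame with columns `t` (seconds, 100 ms steps) and
#'   `aai`, or a numeric vector of AAI values at 100 ms steps.
#' @param delta_tau temporal support of the weighting kernel in seconds
#'   (default 3.0).
#' @return a tibble of class `aai_series` with columns `t`, `aai`, `faai`.
#' @examples
#' smooth_aai(c(0, 0, 1, 1, 1))
#' @export
smooth_aai <- function(series, delta_tau = 3.0) {
  if (is.numeric(series)) {
    series <- tibble::tibble(t = (seq_along(series) - 1L) * 0.1, aai = series)
  }
  stopifnot(all(c("t", "aai") %in% names(series)))
  tt <- series$t
  aai <- series$aai
  if (!length(tt)) stop("empty series")
  if (length(tt) > 1L && any(abs(diff(tt) - 0.1) > 1e-6)) {
    stop("series must be sampled at 100 ms steps")
  }
  h <- 0.1
  n_full <- ceiling(delta_tau / h - 1e-9)
  kernels <- lapply(seq_len(n_full), function(m) {
    smoothing_kernel(min(m * h, delta_tau), delta_tau, h)
  })
  faai <- vapply(seq_along(tt), function(i) {
    m <- min(i - 1L, n_full)
    if (m == 0L) {
      return(aai[i])
    }
    sum(kernels[[m]] * aai[i - (0:m)])
  }, numeric(1))
  tibble::new_tibble(
    tibble::tibble(t = tt, aai = aai, faai = faai),
    class = "aai_series"
  )
}

# lag-coefficient kernel of the linearly weighted trailing average over a
# (possibly truncated) span: on each inter-sample segment both the
# interpolated series and the weight W are linear, so the product is
# integrated exactly; coefficients are renormalized by the integral of W
# over the available span
smoothing_kernel <- function(span, delta_tau, h) {
  wfun <- function(tau) 2 * (delta_tau - tau) / delta_tau^2
  n_seg <- ceiling(span / h - 1e-9)
  coef <- numeric(n_seg + 1L)
  simpson <- function(f, a, b) {
    (b - a) / 6 * (f(a) + 4 * f((a + b) / 2) + f(b))
  }
  for (j in seq_len(n_seg)) {
    a <- (j - 1) * h
    b <- min(j * h, span)
    # basis integrals of the two linear interpolation hats times W
    coef[j] <- coef[j] +
      simpson(function(tau) (1 - (tau - a) / h) * wfun(tau), a, b)
    coef[j + 1L] <- coef[j + 1L] +
      simpson(function(tau) ((tau - a) / h) * wfun(tau), a, b)
  }
  norm <- (2 * delta_tau * span - span^2) / delta_tau^2
  coef / norm
}

#' Map an AAI value to feedback image visibility
#'
#' Piecewise-linear mapping from the (smoothed) asymmetry index to the
#' visibility parameter `c` of the feedback image, in `[0, 1]`. On the
#' rewarded side of zero visibility rises from the floor with slope 4/3 in
#' `|AAI|` and saturates at 1 beyond `|AAI| = 0.6`; on the punished side it
#' falls with slope 1/3 and reaches 0 beyond the opposite saturation
#' point. Under ART (attention-right training) positive AAI is rewarded;
#' under ALT the map is mirrored.
#'
#' @param aai numeric vector of asymmetry values in `[-1, 1]`.
#' @param condition `"ART"` or `"ALT"`.
#' @param saturation AAI magnitude at full visibility (default 0.6).
#' @param floor visibility at `AAI = 0` (default 0.2).
#' @return numeric vector of visibilities in `[0, 1]`.
#' @examples
#' visibility(c(-0.7, -0.3, 0, 0.3, 0.7), "ART")
#' @export
visibility <- function(aai, condition = c("ART", "ALT"),
                       saturation = 0.6, floor = 0.2) {
  condition <- match.arg(condition)
  stopifnot(saturation > 0, saturation <= 1, floor >= 0, floor < 1)
  s <- if (condition == "ART") 1 else -1
  v <- s * aai # signed value on the rewarded axis
  up_slope <- (1 - floor) / saturation
  down_slope <- floor / saturation
  out <- ifelse(v >= saturation, 1,
    ifelse(v >= 0, floor + up_slope * abs(aai),
      ifelse(v >= -saturation, floor - down_slope * abs(aai), 0)
    )
  )
  pmin(pmax(out, 0), 1)
}

#' Per-trial monetary reward from the mean AAI
#'
#' The base reward rises linearly from 0 to 0.25 euro as the trial-mean
#' AAI moves from 0 to the saturation point (0.6) on the rewarded side
#' (positive under ART, negative under ALT), stays 0 on the other side,
#' and a 0.25 euro bonus is added beyond saturation, capping the trial at
#' 0.50 euro.
#'
#' @param mean_aai numeric vector of trial-mean AAI values.
#' @param condition `"ART"` or `"ALT"`.
#' @param saturation AAI magnitude of the reward cap and bonus threshold
#'   (default 0.6).
#' @param base_max base reward at saturation in euro (default 0.25).
#' @param bonus bonus beyond saturation in euro (default 0.25).
#' @return numeric vector of rewards in euro.
#' @examples
#' compute_reward(c(-0.2, 0.3, 0.7), "ART")
#' @export
compute_reward <- function(mean_aai, condition = c("ART", "ALT"),
                           saturation = 0.6, base_max = 0.25, bonus = 0.25) {
  condition <- match.arg(condition)
  s <- if (condition == "ART") 1 else -1
  v <- s * mean_aai
  base_max * pmin(pmax(v, 0), saturation) / saturation +
    ifelse(v > saturation, bonus, 0)
}

#' Run the neurofeedback loop over a buffered EEG stream
#'
#' Causal re-enactment of the real-time engine: every 100 ms the trailing
#' 1,000 ms segment is analyzed with [compute_aai()], the raw series is
#' smoothed with [smooth_aai()], and the smoothed value is mapped to image
#' visibility. In sham (yoked) mode the emitted visibility is a supplied
#' replay trace instead of the live signal. The trial reward is computed
#' from the mean raw AAI.
#'
#' @param stream numeric matrix, channels x samples, at least 1,000 ms
#'   long; row names identify channels.
#' @param condition `"ART"` or `"ALT"`.
#' @param mode `"verum"` or `"sham"`.
#' @param replay numeric vector of visibilities replayed in sham mode
#'   (one per update step).
#' @param srate sampling rate in Hz (default 500).
#' @param step update interval in seconds (default 0.1).
#' @param delta_tau smoothing-kernel support in seconds (default 3).
#' @inheritParams visibility
#' @return list of class `feedback_run`: `trace` (an `aai_series` tibble
#'   with columns `t`, `aai`, `faai`, `c`), `reward` (euro), `condition`,
#'   `mode`.
#' @export
run_feedback_loop <- function(stream, condition = c("ART", "ALT"),
                              mode = c("verum", "sham"), replay = NULL,
                              srate = 500, step = 0.1, delta_tau = 3.0,
                              saturation = 0.6, floor = 0.2) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  stopifnot(is.matrix(stream))
  n <- ncol(stream)
  win <- as.integer(round(srate)) # 1,000 ms
  if (n < win) stop("stream shorter than one 1,000 ms analysis window")

  starts <- seq.int(0L, n - win, by = as.integer(round(step * srate)))
  times <- (starts + win) / srate
  aai <- batched_aai(stream, starts + 1L, win, srate)

  sm <- smooth_aai(tibble::tibble(t = times, aai = aai), delta_tau = delta_tau)
  if (mode == "sham") {
    if (is.null(replay)) stop("sham mode requires a replay trace")
    if (length(replay) != nrow(sm)) {
      stop("replay trace length (", length(replay),
        ") does not match number of update steps (", nrow(sm), ")")
    }
    cvis <- as.numeric(replay)
  } else {
    cvis <- visibility(sm$faai, condition, saturation = saturation, floor = floor)
  }
  trace <- tibble::new_tibble(
    tibble::tibble(t = sm$t, aai = sm$aai, faai = sm$faai, c = cvis),
    class = "aai_series"
  )
  structure(
    list(
      trace = trace,
      reward = compute_reward(mean(aai), condition,
        saturation = saturation, base_max = 0.25, bonus = 0.25
      ),
      condition = condition,
      mode = mode
    ),
    class = "feedback_run"
  )
}

#' @export
print.feedback_run <- function(x, ...) {
  cat(sprintf(
    "<feedback_run> %s/%s: %d update steps, mean AAI %.3f, reward %.2f EUR\n",
    x$condition, x$mode, nrow(x$trace), mean(x$trace$aai), x$reward
  ))
  invisible(x)
}
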