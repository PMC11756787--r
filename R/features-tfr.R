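#' Single-trial induced oscillatory responses
#'
#' Quantifies post-stimulus oscillatory power per trial with a
#' Hanning-tapered sliding-window Fourier approach. Trials are filtered
#' with a 1 Hz high-pass and a 41--51 Hz band-stop (4th-order
#' Butterworth, zero-phase). Alpha (8--12 Hz) and beta (14--30 Hz) use
#' 500 ms windows stepped by 20 ms, averaged over window centers in
#' 500--900 ms post stimulus and over channels Cz, CPz, C2, C4, CP2, CP4;
#' gamma (70--90 Hz) uses 250 ms windows stepped by 20 ms, averaged over
#' 150--350 ms at Cz.
#'
#' @param trials a `trial_set`.
#' @param alpha_band,beta_band,gamma_band frequency bands in Hz.
#' @param ab_window,gamma_window post-stimulus averaging windows in
#'   seconds (window centers).
#' @param ab_channels channels averaged for alpha/beta.
#' @return tibble with one row per trial: `alpha`, `beta`, `gamma`
#'   (microvolt-squared).
#' @export
quantify_oscillatory <- function(trials,
                                 alpha_band = c(8, 12),
                                 beta_band = c(14, 30),
                                 gamma_band = c(70, 90),
                                 ab_window = c(0.5, 0.9),
                                 gamma_window = c(0.15, 0.35),
                                 ab_channels = c("Cz", "CPz", "C2", "C4", "CP2", "CP4")) {
  stopifnot(inherits(trials, "trial_set"))
  srate <- attr(trials, "srate")
  t <- trial_time_axis(srate)
  if (max(t) < max(ab_window[2], gamma_window[2]) + 0.3) {
    stop("trial shorter than the oscillatory analysis span")
  }

  hp <- signal::butter(4, 1 / (srate / 2), type = "high")
  bs <- signal::butter(4, c(41, 51) / (srate / 2), type = "stop")
  need <- unique(c(ab_channels, "Cz"))

  rows <- purrr::map(trials$signal, function(sig) {
    f <- sig[need, , drop = FALSE]
    for (k in seq_len(nrow(f))) {
      f[k, ] <- signal::filtfilt(bs, signal::filtfilt(hp, f[k, ]))
    }
    c(
      alpha = sliding_band_power(
        f[ab_channels, , drop = FALSE], t, srate,
        win = 0.5, step = 0.02, band = alpha_band, centers = ab_window
      ),
      beta = sliding_band_power(
        f[ab_channels, , drop = FALSE], t, srate,
        win = 0.5, step = 0.02, band = beta_band, centers = ab_window
      ),
      gamma = sliding_band_power(
        f["Cz", , drop = FALSE], t, srate,
        win = 0.25, step = 0.02, band = gamma_band, centers = gamma_window
      )
    )
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# mean band power over sliding Hanning windows whose centers fall in a
# post-stimulus interval, averaged across channels
sliding_band_power <- function(mat, t, srate, win, step, band, centers) {
  nwin <- as.integer(round(win * srate))
  nstep <- as.integer(round(step * srate))
  starts <- seq.int(1L, ncol(mat) - nwin + 1L, by = nstep)
  ctr <- t[starts] + win / 2
  use <- starts[ctr >= centers[1] - 1e-9 & ctr <= centers[2] + 1e-9]
  if (!length(use)) stop("no analysis windows fall in the averaging interval")
  vals <- vapply(use, function(s0) {
    mean(window_band_power(mat[, s0:(s0 + nwin - 1L), drop = FALSE], srate, band))
  }, numeric(1))
  mean(vals)
}
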