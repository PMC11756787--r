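# Constructed EEG fixtures, built in code at test time.

aai_channels <- c("C3", "CP3", "CP5", "C4", "CP4", "CP6")
all_channels <- c(
  "C3", "C4", "CP3", "CP4", "CP5", "CP6", "Cz", "CPz", "C2", "CP2", "Fz"
)

# six-channel stream whose band-power asymmetry equals `aai` analytically:
# a pure 10 Hz tone with amplitude sqrt(1 +/- aai) per hemisphere group
lateralized_stream <- function(aai, duration = 15, srate = 500, freq = 10) {
  tt <- seq(0, duration - 1 / srate, by = 1 / srate)
  src <- sin(2 * pi * freq * tt)
  out <- rbind(
    matrix(rep(sqrt(1 - aai) * src, 3), 3, byrow = TRUE),
    matrix(rep(sqrt(1 + aai) * src, 3), 3, byrow = TRUE)
  )
  rownames(out) <- aai_channels
  out
}

# full-montage trial matrix over the [-18, 2) s axis, zeros by default
blank_trial_signal <- function(srate = 500) {
  n <- 20 * srate
  matrix(0, length(all_channels), n, dimnames = list(all_channels, NULL))
}

# wrap a list of signal matrices into a trial_set
make_trial_set <- function(signals, srate = 500,
                           side = "ART", arm = "verum",
                           rating = 50, subject = 1L) {
  n <- length(signals)
  df <- tibble::tibble(
    subject = rep_len(subject, n),
    side = rep_len(side, n),
    arm = rep_len(arm, n),
    session = 1L,
    trial = seq_len(n),
    half = ifelse(seq_len(n) <= ceiling(n / 2), 1L, 2L),
    aai_true = NA_real_,
    x = ifelse(rep_len(side, n) == "ART", -1, 1),
    rating = rep_len(rating, n),
    signal = signals,
    feedback = vector("list", n),
    reward = NA_real_
  )
  aaipipe:::new_trial_set(
    df,
    list(sampling_rate = srate, channel_names = all_channels)
  )
}

trial_t <- function(srate = 500) aaipipe:::trial_time_axis(srate)
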