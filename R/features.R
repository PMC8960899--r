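# Spectral features. Two consumers:
#  * the dialect classifier: summary statistics of log band energies per
#    1-s sliding window (50% overlap), and
#  * the motif-similarity scorer: short-frame feature trajectories.

stft_power <- function(wave, sr = DS_SR, win = 512L, hop = 256L) {
  n <- length(wave)
  ds_assert(n >= win, "waveform shorter than one analysis frame")
  starts <- seq(1L, n - win + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  nb <- win %/% 2L
  P <- matrix(0, nrow = length(starts), ncol = nb)
  for (i in seq_along(starts)) {
    seg <- wave[starts[i]:(starts[i] + win - 1L)] * hann
    sp <- Mod(fft(seg))[seq_len(nb)]^2
    P[i, ] <- sp
  }
  list(power = P, freq = (seq_len(nb) - 1L) * sr / win,
       t = (starts - 1L + win / 2) / sr)
}

# log-spaced band edges covering the synthesis band
band_edges <- function(n_bands = 24L, fmin = 400, fmax = 10000) {
  exp(seq(log(fmin), log(fmax), length.out = n_bands + 1L))
}

frame_band_energies <- function(stft, n_bands = 24L) {
  edges <- band_edges(n_bands)
  idx <- findInterval(stft$freq, edges, rightmost.closed = TRUE)
  E <- matrix(0, nrow = nrow(stft$power), ncol = n_bands)
  for (b in seq_len(n_bands)) {
    cols <- which(idx == b)
    E[, b] <- if (length(cols)) rowSums(stft$power[, cols, drop = FALSE]) else 0
  }
  log(E + 1e-8)
}

frame_shape_stats <- function(stft) {
  P <- stft$power + 1e-12
  f <- stft$freq
  tot <- rowSums(P)
  centroid <- as.vector(P %*% f) / tot
  m2 <- as.vector(P %*% f^2) / tot
  bw <- sqrt(pmax(0, m2 - centroid^2))
  cum <- t(apply(P, 1, cumsum))
  roll <- f[max.col(cum >= 0.85 * tot, ties.method = "first")]
  flat <- exp(rowMeans(log(P))) / rowMeans(P)
  cbind(centroid = centroid, bandwidth = bw, rolloff = roll, flatness = flat)
}

#' Extract per-window feature vectors from a recording
#'
#' Windows are 1 s long with a 0.5 s hop (50% overlap): a trimmed 4.5-s
#' recording yields 8 windows starting at 0.0, 0.5, ..., 3.5 s. Per window
#' the features are mean and SD of 24 log band energies, mean and SD of
#' spectral centroid/bandwidth/rolloff/flatness, and mean absolute frame-to-
#' frame change of each band energy (delta features): 80 dimensions.
#'
#' @param recording a `song_recording` (or list with `wave`, `sr`).
#' @return list with `window_start` (seconds) and `features`
#'   (matrix, one row per window).
#' @export
extract_windows <- function(recording) {
  wave <- recording$wave; sr <- recording$sr %||% DS_SR
  ds_assert(length(wave) >= sr, "recording shorter than 1 s")
  st <- stft_power(wave, sr)
  E <- frame_band_energies(st)
  S <- frame_shape_stats(st)
  n_sec <- length(wave) / sr
  starts <- seq(0, n_sec - 1, by = 0.5)
  starts <- starts[starts + 1 <= n_sec + 1e-9]
  feats <- matrix(NA_real_, nrow = length(starts),
                  ncol = 24L * 2L + 4L * 2L + 24L)
  for (i in seq_along(starts)) {
    sel <- st$t >= starts[i] & st$t < starts[i] + 1
    Ei <- E[sel, , drop = FALSE]; Si <- S[sel, , drop = FALSE]
    dE <- if (nrow(Ei) > 1) colMeans(abs(diff(Ei))) else numeric(24L)
    feats[i, ] <- c(colMeans(Ei), apply(Ei, 2, sd),
                    colMeans(Si), apply(Si, 2, sd), dE)
  }
  feats[!is.finite(feats)] <- 0
  list(window_start = starts, features = feats)
}

#' Per-frame feature trajectory for similarity scoring
#'
#' 20-ms analysis frames at a 10-ms step; per frame: dominant frequency
#' (pitch proxy), log amplitude, spectral entropy (Wiener-entropy proxy),
#' spectral centroid, and frequency modulation (frame-to-frame change of the
#' pitch proxy).
#'
#' @param wave numeric waveform.
#' @param sr sample rate.
#' @return matrix with one row per frame and 5 named columns.
#' @export
feature_trajectory <- function(wave, sr = DS_SR) {
  win <- round(0.020 * sr); hop <- round(0.010 * sr)
  ds_assert(length(wave) >= win, "waveform shorter than one frame")
  st <- stft_power(wave, sr, win = win, hop = hop)
  P <- st$power + 1e-12
  keep <- st$freq >= 300 & st$freq <= 10000
  P <- P[, keep, drop = FALSE]; f <- st$freq[keep]
  pitch <- f[max.col(P, ties.method = "first")]
  amp <- log(rowSums(P))
  Pn <- P / rowSums(P)
  entropy <- -rowSums(Pn * log(Pn)) / log(ncol(Pn))
  centroid <- as.vector(Pn %*% f)
  fm <- c(0, diff(log(pitch)))
  cbind(pitch = log(pitch), amplitude = amp, entropy = entropy,
        centroid = log(centroid), fm = fm)
}
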