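# Waveform synthesis: additive FM-harmonic syllables at 22,050 Hz mono.
# The goal is not acoustic realism but a rendering whose spectral content
# faithfully reflects the latent syllable parameters, so that dialect
# divergence in parameter space is (and only is) what classifiers can find.

render_syllable <- function(syl, sr = DS_SR, f_jitter = 1, d_jitter = 1) {
  dur <- syl$duration * d_jitter
  n <- max(16L, round(dur * sr))
  t <- seq_len(n) / sr
  f0s <- syl$f0_start * f_jitter
  f0e <- syl$f0_end * f_jitter
  f <- f0s * (f0e / f0s)^(t / dur)            # exponential sweep
  phase <- 2 * pi * cumsum(f) / sr
  w <- numeric(n)
  for (h in seq_along(syl$harmonic_weights)) {
    fh <- h * f
    keep <- fh < (sr / 2) * 0.95
    if (any(keep)) {
      comp <- syl$harmonic_weights[h] * sin(h * phase)
      comp[!keep] <- 0
      w <- w + comp
    }
  }
  if (syl$noise_fraction > 0) {
    w <- (1 - syl$noise_fraction) * w +
      syl$noise_fraction * stats::rnorm(n, sd = 0.5)
  }
  # attack / decay envelope
  env <- rep(1, n)
  na <- min(n, max(1L, round(syl$attack * sr)))
  nd <- min(n, max(1L, round(syl$decay * sr)))
  env[seq_len(na)] <- seq(0, 1, length.out = na)
  env[(n - nd + 1L):n] <- env[(n - nd + 1L):n] * seq(1, 0, length.out = nd)
  w <- w * env
  0.7 * w / max(abs(w), 1e-9)
}

render_motif_once <- function(motif, sr = DS_SR, gap = 0.015, jitter = 0) {
  parts <- list()
  for (syl in motif$syllables) {
    fj <- if (jitter > 0) exp(rnorm(1, 0, jitter / 2)) else 1
    dj <- if (jitter > 0) exp(rnorm(1, 0, jitter)) else 1
    parts[[length(parts) + 1L]] <- render_syllable(syl, sr, fj, dj)
    parts[[length(parts) + 1L]] <- numeric(round(gap * sr))
  }
  unlist(parts)
}

#' Render a single motif rendition as audio
#'
#' @param motif a `ds_motif`.
#' @param seed integer seed (noise components and jitter).
#' @param jitter per-rendition log-scale jitter SD on duration and pitch.
#' @return object of class `song_recording` (fields `wave`, `sr`, `bird_id`).
#' @export
render_motif <- function(motif, seed = 1L, jitter = 0) {
  wave <- withr::with_seed(seed, render_motif_once(motif, jitter = jitter))
  structure(list(wave = wave, sr = DS_SR, bird_id = motif$owner,
                 duration = length(wave) / DS_SR),
            class = "song_recording")
}

#' Render a full song recording (intro syllables + repeated motif)
#'
#' Deterministic given `seed`. The waveform concatenates short introductory
#' notes followed by motif renditions with small per-rendition jitter, then
#' is cut to exactly `target_duration` (the contract is within 0.25 s).
#'
#' @param motif a `ds_motif`.
#' @param target_duration seconds, within `[4.5, 10.2]` (the empirical
#'   recording-duration envelope being emulated).
#' @param seed integer seed.
#' @param jitter per-rendition jitter SD.
#' @return a `song_recording`.
#' @export
render_song <- function(motif, target_duration = 6.8, seed = 1L, jitter = 0.02) {
  ds_assert(target_duration >= 4.5 && target_duration <= 10.2,
            sprintf("target_duration %.2f outside [4.5, 10.2] s", target_duration))
  sr <- DS_SR
  wave <- withr::with_seed(seed, {
    intro_syl <- motif$syllables[[1]]
    intro_syl$duration <- max(0.04, intro_syl$duration * 0.6)
    parts <- list()
    for (i in 1:3) {
      parts[[length(parts) + 1L]] <- render_syllable(intro_syl, sr)
      parts[[length(parts) + 1L]] <- numeric(round(0.08 * sr))
    }
    target_n <- round(target_duration * sr)
    while (sum(lengths(parts)) < target_n) {
      parts[[length(parts) + 1L]] <- render_motif_once(motif, jitter = jitter)
      parts[[length(parts) + 1L]] <- numeric(round(0.1 * sr))
    }
    head(unlist(parts), target_n)
  })
  structure(list(wave = wave, sr = sr, bird_id = motif$owner,
                 duration = length(wave) / sr),
            class = "song_recording")
}

#' @export
print.song_recording <- function(x, ...) {
  cat(sprintf("<song_recording> bird=%s %.2f s @ %d Hz\n",
              x$bird_id %||% "?", x$duration, x$sr))
  invisible(x)
}

#' Record a set of songs for a cohort of males
#'
#' Renders `n_rec` recordings per motif with durations drawn from the
#' empirical envelope N(6.8, 1.6) s truncated to `[4.5, 10.2]` s.
#'
#' @param motifs named list of `ds_motif` (names = bird ids).
#' @param birds `data.table` of bird metadata (used for the sidecar).
#' @param n_rec recordings per male.
#' @param seed integer seed.
#' @return list with `recordings` (list of `song_recording`) and `meta`
#'   (`data.table`: bird_id, rec, genetic_pop, rearing_pop, rearing_aviary,
#'   generation, duration).
#' @export
record_songs <- function(motifs, birds, n_rec = 2L, seed = 1L) {
  recs <- list(); meta <- list()
  ids <- names(motifs)
  durs <- withr::with_seed(stage_seed(seed, "durations"), {
    pmin(10.2, pmax(4.5, rnorm(length(ids) * n_rec, 6.8, 1.6)))
  })
  k <- 0L
  for (id in ids) {
    for (r in seq_len(n_rec)) {
      k <- k + 1L
      rec <- render_song(motifs[[id]], target_duration = durs[k],
                         seed = stage_seed(seed, paste(id, r)))
      recs[[length(recs) + 1L]] <- rec
      b <- birds[bird_id == id]
      meta[[length(meta) + 1L]] <- data.table(
        bird_id = id, rec = r, genetic_pop = b$genetic_pop,
        rearing_pop = b$rearing_pop, rearing_aviary = b$rearing_aviary,
        generation = b$generation, duration = rec$duration)
    }
  }
  list(recordings = recs, meta = rbindlist(meta))
}

#' Write a recorded song set as WAV files plus a metadata sidecar CSV
#'
#' @param songset result of [record_songs()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_song_set <- function(songset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(songset$recordings)) {
    m <- songset$meta[i]
    p <- file.path(dir, sprintf("%s_%d.wav", m$bird_id, m$rec))
    write_wav(songset$recordings[[i]]$wave, p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "songs_meta.csv")
  write.csv(songset$meta, mp, row.names = FALSE)
  invisible(c(paths, mp))
}
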