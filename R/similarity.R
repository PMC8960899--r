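# Surrogate motif-similarity scorer (0-100). A documented replacement for
# proprietary pairwise song-similarity software: per-frame feature
# trajectories, per-feature z-scaling, banded DTW alignment, and a fixed
# exponential mapping from mean alignment cost to [0, 100]. Absolute values
# are comparable only within this package.

# cost -> score mapping constant, calibrated once on a frozen synthetic
# calibration set (see the methods vignette) so that identical motifs score
# 100 and a motif vs white noise of equal duration scores < 30.
DS_KAPPA <- 1.1
DS_BAND <- 0.10  # Sakoe-Chiba radius as a fraction of frames

as_wave <- function(x) {
  if (is.numeric(x)) return(list(wave = x, sr = DS_SR))
  ds_assert(!is.null(x$wave), "expected a waveform or recording object")
  x
}

scaled_trajectories <- function(a, b) {
  ta <- feature_trajectory(a$wave, a$sr %||% DS_SR)
  tb <- feature_trajectory(b$wave, b$sr %||% DS_SR)
  pooled <- rbind(ta, tb)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  scl[scl < 1e-8] <- 1
  list(a = scale(ta, ctr, scl), b = scale(tb, ctr, scl))
}

#' Pairwise motif similarity score (0-100)
#'
#' `100 * exp(-cost / kappa)` where cost is the mean per-step feature
#' distance along the optimal DTW path. Symmetric; identical inputs score
#' exactly 100. If either input is a super-motif (or `open_end = TRUE`), the
#' shorter input is aligned as a subsequence of the longer (open-end DTW).
#'
#' @param a,b waveforms, `song_recording`s, or `super_motif`s; must be
#'   non-silent.
#' @param open_end force open-end subsequence alignment.
#' @param kappa cost scale of the score mapping.
#' @return list of class `similarity_score`: `value` in `[0, 100]`, `mode`.
#' @export
pairwise_similarity <- function(a, b, open_end = NA, kappa = DS_KAPPA) {
  a <- as_wave(a); b <- as_wave(b)
  if (sd(a$wave) < 1e-7 || sd(b$wave) < 1e-7) {
    stop("silent input: similarity undefined (no pitch content)", call. = FALSE)
  }
  if (is.na(open_end)) {
    open_end <- inherits(a, "super_motif") || inherits(b, "super_motif")
  }
  tr <- scaled_trajectories(a, b)
  A <- tr$a; B <- tr$b
  # canonical order (shorter trajectory as query) guarantees exact symmetry
  if (nrow(A) > nrow(B)) { tmp <- A; A <- B; B <- tmp }
  cost <- dtw_cost_cpp(A, B, DS_BAND, as.integer(open_end))
  structure(list(value = 100 * exp(-cost / kappa), cost = cost,
                 mode = if (open_end) "to_supermotif" else "pairwise"),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity> %.1f / 100 (%s)\n", x$value, x$mode))
  invisible(x)
}

#' Concatenate recordings into a single super-motif
#'
#' @param recordings non-empty list of recordings / waveforms.
#' @return object of class `super_motif` with `wave`, `sr`, and `sources`
#'   (the input order, which is recorded as metadata).
#' @export
build_super_motif <- function(recordings) {
  ds_assert(length(recordings) >= 1, "need at least one recording")
  recs <- lapply(recordings, as_wave)
  structure(list(wave = unlist(lapply(recs, `[[`, "wave")),
                 sr = recs[[1]]$sr %||% DS_SR,
                 sources = vapply(recs, function(r) r$bird_id %||% NA_character_, "")),
            class = c("super_motif", "song_recording"))
}

#' Similarity of a male's motif to a female's rearing context
#'
#' Three contexts: `foster_father` (pairwise score against the female's
#' foster father's motif), `parents` (open-end score against the super-motif
#' of the adult males of her rearing aviary), `peers` (open-end score
#' against the super-motif of her same-generation male peers). The focal
#' male is always excluded from the cohort before concatenation.
#'
#' @param male_rec the focal male's motif recording.
#' @param cohort_recs named-or-not list of cohort motif recordings (each
#'   carrying `bird_id`).
#' @param mode one of `"foster_father"`, `"parents"`, `"peers"`.
#' @return a `similarity_score`.
#' @export
context_similarity <- function(male_rec, cohort_recs,
                               mode = c("peers", "parents", "foster_father")) {
  mode <- match.arg(mode)
  ds_assert(length(cohort_recs) >= 1, "cohort is empty")
  male_id <- male_rec$bird_id %||% NA_character_
  ids <- vapply(cohort_recs, function(r) r$bird_id %||% NA_character_, "")
  cohort_recs <- cohort_recs[is.na(ids) | ids != male_id]
  ds_assert(length(cohort_recs) >= 1,
            "cohort contains only the focal male himself")
  if (mode == "foster_father") {
    ds_assert(length(cohort_recs) == 1, "foster_father mode expects one tutor")
    pairwise_similarity(male_rec, cohort_recs[[1]])
  } else {
    pairwise_similarity(male_rec, build_super_motif(cohort_recs),
                        open_end = TRUE)
  }
}
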