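# Synthetic study populations.
#
# Each population carries a "dialect": a pool of syllable prototypes displaced
# from a shared global reference pool by `divergence_delta` in a standardized
# latent parameter space. Individual birds realize pool prototypes with
# individual dispersion, so songs are strongly individual (as in real zebra
# finches) while still carrying a population signature that vanishes exactly
# when delta = 0.

# latent -> natural parameter mapping constants (means on log / logit scales)
LAT_DIM <- 10L

latent_to_syllable <- function(z) {
  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
  dur <- min(0.25, max(0.04, exp(log(0.11) + 0.30 * z[1])))
  f0s <- min(6800, max(500, exp(log(1800) + 0.40 * z[2])))
  f0e <- min(6800, max(450, exp(log(1400) + 0.40 * z[3])))
  list(
    duration = dur,
    f0_start = f0s,
    f0_end = f0e,
    harmonic_weights = softmax(c(1.2, 0.6, 0.2, -0.2) + 0.5 * z[4:7]),
    noise_fraction = 0.4 * stats::plogis(-1.5 + 0.8 * z[8]),
    attack = min(0.03, max(0.004, exp(log(0.012) + 0.3 * z[9]))),
    decay = min(0.06, max(0.008, exp(log(0.025) + 0.3 * z[10])))
  )
}

# The global reference pool is a package constant: same for every population,
# so that divergence_delta = 0 populations have identical dialect centers.
reference_pool <- function(n_proto = 12L) {
  withr::with_seed(190462L, {
    matrix(rnorm(n_proto * LAT_DIM), nrow = n_proto)
  })
}

#' Define a synthetic population
#'
#' @param pop_id label, e.g. `"W1"` or `"D1"`.
#' @param type `"W"` (wild-derived, small) or `"D"` (domesticated, large);
#'   drives body size defaults and the lineage-code letter.
#' @param divergence_delta nonnegative displacement of this population's
#'   syllable-prototype pool from the global reference, in latent SD units.
#'   `0` means the dialect center is identical to the reference.
#' @param innovation_rho probability, in `[0, 1]`, that a pupil replaces a
#'   copied syllable with a fresh draw from the rearing population's pool.
#'   Observed innovation rates in song-learning finches span roughly 0.15-0.5.
#' @param dispersion individual deviation (latent SD units) around pool
#'   prototypes; this is what makes songs individual-specific.
#' @param body_size_mean,body_size_sd grams; defaults 16 g (D) vs 12 g (W).
#' @param n_proto number of syllable prototypes in the pool.
#' @param seed integer; fixes the (random) direction of the dialect
#'   displacement for this population.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(pop_id, type = substr(pop_id, 1, 1),
                            divergence_delta = 1.5, innovation_rho = 0.3,
                            dispersion = 0.6,
                            body_size_mean = if (type == "D") 16 else 12,
                            body_size_sd = if (type == "D") 1.1 else 0.9,
                            n_proto = 12L, seed = stage_seed(7L, pop_id)) {
  ds_assert(type %in% c("W", "D"), "population type must be 'W' or 'D'")
  ds_assert(divergence_delta >= 0, "divergence_delta must be nonnegative")
  ds_assert(innovation_rho >= 0 && innovation_rho <= 1,
            "innovation_rho must be in [0, 1]")
  ref <- reference_pool(n_proto)
  pool <- ref
  if (divergence_delta > 0) {
    withr::with_seed(seed, {
      for (k in seq_len(n_proto)) {
        u <- rnorm(LAT_DIM)
        pool[k, ] <- ref[k, ] + divergence_delta * u / sqrt(sum(u^2))
      }
    })
  }
  structure(list(pop_id = pop_id, type = type,
                 divergence_delta = divergence_delta,
                 innovation_rho = innovation_rho, dispersion = dispersion,
                 body_size_mean = body_size_mean, body_size_sd = body_size_sd,
                 pool = pool, n_proto = n_proto, seed = seed),
            class = "population_spec")
}

#' Default four-population design (two wild-derived, two domesticated)
#'
#' @param delta divergence applied to every population (each in its own random
#'   direction, so pairwise dialect distances are comparable).
#' @param rho innovation rate shared by all populations.
#' @return named list of [population_spec()] objects `W1, W2, D1, D2`.
#' @export
default_populations <- function(delta = 1.5, rho = 0.3) {
  ids <- c("W1", "W2", "D1", "D2")
  setNames(lapply(ids, function(id) {
    population_spec(id, divergence_delta = delta, innovation_rho = rho)
  }), ids)
}

# Draw one realized syllable (prototype k + individual dispersion).
draw_syllable <- function(pop, k = NULL, id_prefix = "s") {
  if (is.null(k)) k <- sample.int(pop$n_proto, 1L)
  z <- pop$pool[k, ] + pop$dispersion * rnorm(LAT_DIM)
  syl <- latent_to_syllable(z)
  syl$syl_id <- sprintf("%s_%d_%d", id_prefix, k, sample.int(.Machine$integer.max, 1L))
  syl$pool_index <- k
  syl
}

#' Sample a fresh motif from a population's dialect
#'
#' Motifs are ordered lists of 3-8 realized syllable prototypes. Each syllable
#' carries a provenance id so that cultural transmission can be audited
#' (shared ids = copied syllables).
#'
#' @param pop a [population_spec()].
#' @param owner bird id.
#' @param n_syl motif length; default drawn uniformly from 3:8.
#' @param seed optional integer seed.
#' @return object of class `ds_motif`.
#' @export
sample_motif <- function(pop, owner, n_syl = NULL, seed = NULL) {
  draw <- function() {
    if (is.null(n_syl)) n_syl <- sample(3:8, 1L)
    ds_assert(n_syl >= 1 && n_syl <= pop$n_proto, "motif length out of range")
    ks <- sample.int(pop$n_proto, n_syl, replace = FALSE)
    syls <- lapply(ks, function(k) draw_syllable(pop, k, id_prefix = owner))
    structure(list(owner = owner, tutor = NA_character_, pop = pop$pop_id,
                   syllables = syls), class = "ds_motif")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.ds_motif <- function(x, ...) {
  cat(sprintf("<motif> owner=%s tutor=%s pop=%s syllables=%d (%.2f s)\n",
              x$owner, x$tutor, x$pop, length(x$syllables),
              sum(vapply(x$syllables, `[[`, 0, "duration"))))
  invisible(x)
}

#' Founder (Generation 1) birds with motifs
#'
#' Creates one or more founder aviaries per population, each with equal
#' numbers of males and females; every male receives a motif sampled from his
#' population's dialect.
#'
#' @param pops named list of [population_spec()].
#' @param n_males,n_females per aviary.
#' @param aviaries named list mapping aviary label to pop_id; default one
#'   aviary `A_<pop>` per population.
#' @param seed integer seed.
#' @return list with `birds` (a `data.table`) and `motifs` (named list of
#'   `ds_motif`, males only).
#' @export
make_founders <- function(pops, n_males = 8L, n_females = 8L,
                          aviaries = NULL, seed = 1L) {
  if (is.null(aviaries)) {
    aviaries <- setNames(as.list(names(pops)), paste0("A_", names(pops)))
  }
  withr::with_seed(seed, {
    rows <- list(); motifs <- list()
    for (av in names(aviaries)) {
      pop <- pops[[aviaries[[av]]]]
      for (sex in c("M", "F")) {
        n <- if (sex == "M") n_males else n_females
        for (i in seq_len(n)) {
          id <- sprintf("G1_%s_%s%02d", av, sex, i)
          rows[[length(rows) + 1L]] <- data.table(
            bird_id = id, sex = sex, genetic_pop = pop$pop_id,
            rearing_pop = pop$pop_id, lineage_code = pop$type,
            rearing_aviary = av, generation = 1L,
            body_size = rnorm(1, pop$body_size_mean, pop$body_size_sd),
            foster_father = NA_character_)
          if (sex == "M") motifs[[id]] <- sample_motif(pop, id)
        }
      }
    }
    list(birds = rbindlist(rows), motifs = motifs)
  })
}
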