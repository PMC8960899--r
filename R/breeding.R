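# Cultural transmission across generations: sons copy the foster father's
# motif, replacing each syllable independently with probability rho by a
# fresh draw from the rearing population's prototype pool. Daughters do not
# sing; their latent "imprinted dialect" is their rearing population.

transmit_motif <- function(tutor_motif, rearing_pop, rho, owner) {
  syls <- lapply(tutor_motif$syllables, function(s) {
    if (runif(1) < rho) draw_syllable(rearing_pop, id_prefix = owner) else s
  })
  structure(list(owner = owner, tutor = tutor_motif$owner,
                 pop = rearing_pop$pop_id, syllables = syls),
            class = "ds_motif")
}

#' Fraction of a pupil's syllables copied from the tutor
#'
#' Counts shared syllable provenance ids; the expectation under the
#' transmission model is `1 - rho`.
#'
#' @param pupil,tutor `ds_motif` objects.
#' @return numeric in `[0, 1]`.
#' @export
motif_shared_fraction <- function(pupil, tutor) {
  tids <- vapply(tutor$syllables, `[[`, "", "syl_id")
  pids <- vapply(pupil$syllables, `[[`, "", "syl_id")
  mean(pids %in% tids)
}

#' Breed one generation with cross-fostering
#'
#' @param parents list with `birds` and `motifs` as returned by
#'   [make_founders()] or a previous call.
#' @param matings `data.frame`/`data.table` with columns `mother`, `father`
#'   (genetic parents), `rearing_aviary`, `rearing_pop`, `foster_father`
#'   (a male resident in the rearing aviary, must own a motif), `n_sons`,
#'   `n_daughters`.
#' @param pops named list of [population_spec()] covering all pops involved.
#' @param rho innovation rate in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `birds` (offspring `data.table`) and `motifs` (sons').
#' @export
breed_generation <- function(parents, matings, pops, rho, seed = 1L) {
  ds_assert(is.numeric(rho) && rho >= 0 && rho <= 1, "rho must be in [0, 1]")
  matings <- as.data.table(matings)
  pb <- parents$birds
  miss <- setdiff(matings$foster_father, names(parents$motifs))
  if (length(miss) > 0) {
    stop("foster father(s) without a motif: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    rows <- list(); motifs <- list(); n_born <- 0L
    gen <- max(pb$generation) + 1L
    for (m in seq_len(nrow(matings))) {
      mt <- matings[m]
      gfather <- pb[bird_id == mt$father]
      ds_assert(nrow(gfather) == 1, paste("unknown genetic father", mt$father))
      gpop <- pops[[gfather$genetic_pop]]
      rpop <- pops[[mt$rearing_pop]]
      ffcode <- pb[bird_id == mt$foster_father, lineage_code]
      code <- paste0(gpop$type, substr(ffcode, 1, 2))
      for (sex in c("M", "F")) {
        n <- if (sex == "M") mt$n_sons else mt$n_daughters
        for (i in seq_len(n)) {
          n_born <- n_born + 1L
          id <- sprintf("G%d_%s%04d", gen, sex, n_born)
          rows[[length(rows) + 1L]] <- data.table(
            bird_id = id, sex = sex, genetic_pop = gfather$genetic_pop,
            rearing_pop = mt$rearing_pop, lineage_code = code,
            rearing_aviary = mt$rearing_aviary, generation = gen,
            body_size = rnorm(1, gpop$body_size_mean, gpop$body_size_sd),
            foster_father = mt$foster_father)
          if (sex == "M") {
            motifs[[id]] <- transmit_motif(parents$motifs[[mt$foster_father]],
                                           rpop, rho, id)
          }
        }
      }
    }
    list(birds = rbindlist(rows), motifs = motifs)
  })
}

#' Build a full cross-fostered Generation-2 replicate
#'
#' Emulates one replicate of the cross-fostering design: four founder
#' aviaries (two per population) of `n_founder` breeding males (plus as many
#' females) each, whose eggs are exchanged within and between populations to
#' create the four lineages DD, DW, WD, WW (first letter genetic origin,
#' second rearing culture), each with `n_per_type` males and females.
#'
#' @param popW,popD [population_spec()] objects for the wild-derived and
#'   domesticated population of this replicate.
#' @param n_per_type Generation-2 males (= females) per lineage; 10 gives the
#'   80-bird aviary of the full design.
#' @param n_founder founder males (= females) per rearing aviary.
#' @param rho innovation rate; default taken from `popW`.
#' @param seed integer seed.
#' @return list with `founders`, `g2` (each `birds` + `motifs`), `birds`
#'   (all), `motifs` (all), and `aviary_pop` (named map).
#' @export
replicate_world <- function(popW, popD, n_per_type = 10L, n_founder = 8L,
                            rho = popW$innovation_rho, seed = 1L) {
  pops <- setNames(list(popW, popD), c(popW$pop_id, popD$pop_id))
  avmap <- setNames(list(popD$pop_id, popD$pop_id, popW$pop_id, popW$pop_id),
                    c("AD1", "AD2", "AW1", "AW2"))
  founders <- make_founders(pops, n_males = n_founder, n_females = n_founder,
                            aviaries = avmap, seed = stage_seed(seed, "founders"))
  fb <- founders$birds
  # lineage -> (genetic source aviary, rearing aviary); every clutch is
  # fostered away from its genetic aviary (within- or between-population)
  plan <- list(DD = c("AD1", "AD2"), DW = c("AD2", "AW1"),
               WD = c("AW2", "AD1"), WW = c("AW1", "AW2"))
  mat_rows <- list()
  withr::with_seed(stage_seed(seed, "matings"), {
    for (lin in names(plan)) {
      src <- plan[[lin]][1]; rear <- plan[[lin]][2]
      fathers <- fb[rearing_aviary == src & sex == "M", bird_id]
      mothers <- fb[rearing_aviary == src & sex == "F", bird_id]
      fosters <- fb[rearing_aviary == rear & sex == "M", bird_id]
      need <- n_per_type
      # spread clutches over genetic pairs and foster fathers round-robin
      idx <- (seq_len(need) - 1L) %% length(fathers) + 1L
      fidx <- (seq_len(need) - 1L) %% length(fosters) + 1L
      for (i in seq_len(need)) {
        mat_rows[[length(mat_rows) + 1L]] <- data.table(
          mother = mothers[idx[i]], father = fathers[idx[i]],
          rearing_aviary = rear, rearing_pop = avmap[[rear]],
          foster_father = fosters[fidx[i]], n_sons = 1L, n_daughters = 1L)
      }
    }
  })
  g2 <- breed_generation(founders, rbindlist(mat_rows), pops, rho,
                         seed = stage_seed(seed, "breed_g2"))
  list(founders = founders, g2 = g2,
       birds = rbind(founders$birds, g2$birds),
       motifs = c(founders$motifs, g2$motifs),
       aviary_pop = avmap, pops = pops)
}
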