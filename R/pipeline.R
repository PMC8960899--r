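# End-to-end orchestration: one reproducible run from synthetic colony to
# hypothesis comparison, with per-stage seeds derived from a single master
# seed and a manifest of outputs.

#' Pipeline configuration
#'
#' @param seed master seed; every stage seed is derived from it via
#'   [stage_seed()].
#' @param preset `"desk"` (tractable on one CPU in minutes) or `"full"`
#'   (the full-scale design: 80-bird aviaries, 30 days of 14.5 h).
#' @param n_per_type Generation-2 males (= females) per lineage.
#' @param n_founder founder males (= females) per rearing aviary.
#' @param delta dialect divergence of both populations.
#' @param rho innovation rate.
#' @param days,day_length_h,detection_prob tracking design knobs.
#' @param a_cult,a_pair,baseline_mixing,ramp_days preference model
#'   (defaults: pure song-imprinting mate choice expressed through
#'   rearing-assortative pair bonds, ramping in over the experiment).
#' @param background_lambda,bonded_lambda,zero_prob interaction-count model.
#' @param cutoff_override pair-bond cutoff (default 5; `NULL` = data-driven).
#' @param stages stages to run, in order.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, preset = c("desk", "full"),
                            n_per_type = NULL, n_founder = 8L, delta = 1.5,
                            rho = 0.3, days = NULL, day_length_h = NULL,
                            detection_prob = 0.9, a_cult = 0, a_pair = 6,
                            baseline_mixing = 0.02,
                            ramp_days = NULL, background_lambda = 1.2,
                            bonded_lambda = 20, zero_prob = 0.85,
                            cutoff_override = 5L,
                            stages = c("world", "songs", "tracking",
                                       "distances", "pairs", "hypotheses"),
                            out_dir = NULL) {
  preset <- match.arg(preset)
  full <- preset == "full"
  structure(list(
    seed = as.integer(seed), preset = preset,
    n_per_type = n_per_type %||% 10L, n_founder = n_founder,
    delta = delta, rho = rho,
    days = days %||% if (full) 30L else 15L,
    day_length_h = day_length_h %||% if (full) 14.5 else 0.5,
    detection_prob = detection_prob,
    a_cult = a_cult, a_pair = a_pair, baseline_mixing = baseline_mixing,
    ramp_days = ramp_days %||% if (full) 30L else 15L,
    background_lambda = background_lambda, bonded_lambda = bonded_lambda,
    zero_prob = zero_prob, cutoff_override = cutoff_override,
    stages = stages, out_dir = out_dir), class = "run_config")
}

#' Read a pipeline configuration from a JSON scenario file
#'
#' @param path JSON file whose fields override [pipeline_config()] defaults.
#' @return a `run_config`.
#' @export
pipeline_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  ds_assert(length(bad) == 0, paste("unknown config field(s):",
                                    paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

need_stage <- function(state, what, stage) {
  if (is.null(state[[what]])) {
    stop(sprintf("stage '%s' requires output of stage '%s', which did not run",
                 stage, what), call. = FALSE)
  }
}

#' Run the full analysis pipeline on a synthetic replicate
#'
#' Stages: `world` (colony + cross-fostering), `songs` (recordings),
#' `tracking` (fixes under the preference model), `distances` (dyadic
#' distances, daily assortment series, permutation test), `pairs`
#' (interaction counts and pair-bond calling), `hypotheses` (pair-type
#' matrices, correlations, mixture, dyadic distance model).
#'
#' @param config a `run_config` (or path to a JSON scenario).
#' @return list of class `run_result` with per-stage results and a
#'   `manifest` (config echo, stage seeds, file checksums).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config_from_json(config)
  st <- list()
  seeds <- list()
  sseed <- function(stage) { seeds[[stage]] <<- stage_seed(config$seed, stage); seeds[[stage]] }

  if ("world" %in% config$stages) {
    popW <- population_spec("W1", divergence_delta = config$delta,
                            innovation_rho = config$rho)
    popD <- population_spec("D1", divergence_delta = config$delta,
                            innovation_rho = config$rho)
    st$world <- replicate_world(popW, popD, n_per_type = config$n_per_type,
                                n_founder = config$n_founder, rho = config$rho,
                                seed = sseed("world"))
  }

  if ("songs" %in% config$stages) {
    need_stage(st, "world", "songs")
    st$songs <- record_songs(st$world$motifs, st$world$birds, n_rec = 2L,
                             seed = sseed("songs"))
  }

  if ("tracking" %in% config$stages) {
    need_stage(st, "world", "tracking")
    g2 <- st$world$g2$birds
    st$true_pairs <- sample_true_pairs(g2, rule = "rearing",
                                       seed = sseed("true_pairs"))
    des <- experiment_design(days = config$days,
                             day_length_h = config$day_length_h,
                             detection_prob = config$detection_prob)
    model <- preference_model(a_cult = config$a_cult, a_pair = config$a_pair,
                              ramp_days = config$ramp_days,
                              baseline_mixing = config$baseline_mixing)
    st$design <- des
    st$fixes <- simulate_tracking(g2, model, st$true_pairs, des,
                                  seed = sseed("tracking"))
  }

  if ("distances" %in% config$stages) {
    need_stage(st, "fixes", "distances")
    g2 <- st$world$g2$birds
    st$dyad_days <- dyad_daily_distances(st$fixes, g2, scope = "all")
    st$series_between <- daily_assortment_series(st$dyad_days, g2,
                                                 scope = "between_sex")
    st$series_same <- daily_assortment_series(st$dyad_days, g2,
                                              scope = "same_sex")
    agg <- aggregate_dyad_distances(st$dyad_days)
    net <- distance_network(agg[dyad_type == "FM"], g2)
    st$assort_perm <- permutation_test(net, "rearing_pop", n_perm = 10000L,
                                       seed = sseed("permutation"))
    st$nearest <- nearest_opposite_sex(st$dyad_days)
  }

  if ("pairs" %in% config$stages) {
    need_stage(st, "true_pairs", "pairs")
    g2 <- st$world$g2$birds
    st$interactions <- simulate_interactions(
      g2, st$true_pairs, background_lambda = config$background_lambda,
      bonded_lambda = config$bonded_lambda, zero_prob = config$zero_prob,
      seed = sseed("interactions"))
    obs_counts <- st$interactions[count > 0]
    st$cutoff <- choose_cutoff(obs_counts$count,
                               override = config$cutoff_override)
    st$pair_bonds <- call_pairs(obs_counts, st$cutoff %||% 5L, birds = g2)
    st$assortment <- assortment_test(st$pair_bonds, g2, "rearing_pop")
  }

  if ("hypotheses" %in% config$stages) {
    need_stage(st, "pair_bonds", "hypotheses")
    need_stage(st, "dyad_days", "hypotheses")
    g2 <- st$world$g2$birds
    comp <- g2[, .(n_female = sum(sex == "F"), n_male = sum(sex == "M")),
               by = .(type = substr(lineage_code, 1, 2))]
    n_pairs <- nrow(st$pair_bonds$pairs)
    hyps <- c("H1", "H2", "H3", "H1W")
    st$expected <- setNames(lapply(hyps, function(h) {
      expected_matrix(h, comp, n_pairs)
    }), hyps)
    st$observed <- observed_matrix(st$pair_bonds, g2)
    st$hyp_correlations <- vapply(st$expected, function(E) {
      matrix_correlation(E, st$observed)$r
    }, 0)
    st$mixture <- fit_mixture(st$observed, st$expected, grid_step = 0.02)
    dyads <- st$dyad_days[dyad_type == "FM",
                          .(female_id = id_a, male_id = id_b)][, unique(.SD)]
    preds <- dyad_predictors(dyads, g2)
    st$distance_model <- fit_distance_model(st$dyad_days, preds,
                                            fixed = c("H1W", "H2", "H3"))
  }

  manifest <- list(config = unclass(config)[setdiff(names(unclass(config)), "stages")],
                   stages = config$stages, stage_seeds = seeds,
                   versions = list(package = as.character(utils::packageVersion("dialectscope")),
                                   R = paste(R.version$major, R.version$minor, sep = ".")))
  if (!is.null(config$out_dir)) {
    manifest$files <- write_run_outputs(st, config$out_dir, manifest)
  }
  structure(c(st, list(manifest = manifest)), class = "run_result")
}

write_run_outputs <- function(st, dir, manifest) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put_csv <- function(x, name) {
    p <- file.path(dir, name); write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(st$world)) put_csv(st$world$birds, "birds.csv")
  if (!is.null(st$fixes)) put_csv(st$fixes, "fixes.csv")
  if (!is.null(st$dyad_days)) put_csv(st$dyad_days, "dyad_days.csv")
  if (!is.null(st$interactions)) put_csv(st$interactions, "interactions.csv")
  if (!is.null(st$pair_bonds)) put_csv(st$pair_bonds$pairs, "pairs.csv")
  if (!is.null(st$observed)) {
    put_csv(as.data.frame(as.table(unclass(st$observed))), "observed_matrix.csv")
  }
  report <- list()
  if (!is.null(st$assort_perm)) {
    report$assortativity <- st$assort_perm[c("r", "p_perm", "p_conservative", "n_perm")]
  }
  if (!is.null(st$assortment)) report$assortment <- unclass(st$assortment)
  if (!is.null(st$hyp_correlations)) report$hyp_correlations <- as.list(st$hyp_correlations)
  if (!is.null(st$mixture)) report$mixture <- list(weights = as.list(st$mixture$weights),
                                                   correlation = st$mixture$correlation)
  if (!is.null(st$distance_model)) {
    report$distance_model <- list(fixed = st$distance_model$fixed,
                                  varcomp = st$distance_model$varcomp,
                                  singular = st$distance_model$singular)
  }
  rp <- file.path(dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- c(paths, rp)
  mp <- file.path(dir, "manifest.json")
  manifest$files <- data.frame(path = basename(paths),
                               md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$files
}
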