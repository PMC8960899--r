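# Dyad-level predictors and the crossed-random-effects model of daily
# male-female distances: ln(mm) distance (centered and scaled within the
# dataset) explained by hypothesis indicators and song-similarity
# covariates, with random intercepts for pair, male, female, and the
# combination of the two rearing aviaries.

#' Dyad-level predictor table
#'
#' Builds, for every supplied male-female dyad, the hypothesis indicator
#' codings (coded so that the "match" level is predicted to reduce
#' distance, i.e. expected negative fixed effects), the absolute
#' male-female body-size difference, and z-scored continuous similarity
#' covariates.
#'
#' @param dyads `data.table` with `female_id`, `male_id`.
#' @param birds bird metadata (`lineage_code`, `body_size`,
#'   `rearing_aviary`).
#' @param scores optional `data.table` keyed by (`female_id`, `male_id`)
#'   with numeric similarity columns (e.g. `ml_peers`, `dtw_peers`); each
#'   is z-scored. A constant column is an error (degenerate predictor).
#' @return `data.table` with predictors plus grouping labels (`pair_id`,
#'   `aviary_pair`); the predictor correlation matrix is attached as
#'   attribute `"predictor_correlations"`.
#' @export
dyad_predictors <- function(dyads, birds, scores = NULL) {
  dy <- as.data.table(dyads)[, .(female_id, male_id)]
  code <- setNames(birds$lineage_code, birds$bird_id)
  size <- setNames(birds$body_size, birds$bird_id)
  avi <- setNames(birds$rearing_aviary, birds$bird_id)
  ft <- lineage_type(code[dy$female_id])
  mt <- lineage_type(code[dy$male_id])
  ind <- function(h) {
    al <- hypothesis_spec(h)$allowed
    as.numeric(al[cbind(ft, mt)])
  }
  dy[, `:=`(
    H1W = ind("H1W"), H2 = ind("H2"), H3 = ind("H3"),
    size_diff = abs(size[female_id] - size[male_id]),
    pair_id = paste(female_id, male_id, sep = ":"),
    aviary_pair = paste(avi[female_id], avi[male_id], sep = ":"))]
  if (!is.null(scores)) {
    scores <- as.data.table(scores)
    num_cols <- setdiff(names(scores), c("female_id", "male_id"))
    dy <- merge(dy, scores, by = c("female_id", "male_id"), all.x = TRUE)
    for (cl in num_cols) {
      if (anyNA(dy[[cl]])) stop("missing similarity scores for some dyads: ", cl,
                                call. = FALSE)
      s <- sd(dy[[cl]])
      if (s < 1e-12) stop("degenerate predictor (constant): ", cl, call. = FALSE)
      set(dy, j = cl, value = (dy[[cl]] - mean(dy[[cl]])) / s)
    }
  }
  pred_cols <- intersect(c("H1W", "H2", "H3", "size_diff",
                           if (!is.null(scores)) setdiff(names(scores),
                                                         c("female_id", "male_id"))),
                         names(dy))
  cm <- suppressWarnings(cor(as.matrix(dy[, ..pred_cols])))
  setattr(dy, "predictor_correlations", cm)
  dy[]
}

#' Fit the dyadic distance model with crossed random effects
#'
#' Linear mixed model (REML via lme4) of daily ln-distance with random
#' intercepts for pair, male, female, and rearing-aviary pair, and the
#' requested fixed effects. Confidence intervals are the normal
#' approximation `estimate +/- 1.96 SE`; p-values use the normal reference
#' (no df correction; a documented approximation). Singular fits are
#' flagged, not hidden.
#'
#' @param dyad_days between-sex dyad-day distances
#'   ([dyad_daily_distances()]; `id_a` = female).
#' @param predictors output of [dyad_predictors()].
#' @param fixed character vector of predictor columns to fit.
#' @param standardize center and scale the ln response within the dataset
#'   (default TRUE; the raw ln(mm) scale is available with FALSE).
#' @return list of class `distance_model_fit`: `fixed` (`data.table` of
#'   estimates, CI, t, p), `varcomp` (`data.table` of variance shares, in
#'   percent, summing to 100), `singular`, `n_obs`, `model`.
#' @export
fit_distance_model <- function(dyad_days, predictors,
                               fixed = c("H1W", "H2", "H3"),
                               standardize = TRUE) {
  dd <- as.data.table(dyad_days)
  dd <- dd[dyad_type == "FM" | !("dyad_type" %in% names(dd))]
  df <- merge(dd[, .(female_id = id_a, male_id = id_b, day_index, ln_distance)],
              predictors, by = c("female_id", "male_id"))
  ds_assert(nrow(df) > 0, "no dyad-days matched the predictor table")
  ds_assert(all(is.finite(df$ln_distance)), "non-finite response values")
  y <- df$ln_distance
  if (standardize) y <- (y - mean(y)) / sd(y)
  df$.y <- y
  fml <- stats::as.formula(paste(
    ".y ~", paste(fixed, collapse = " + "),
    "+ (1 | pair_id) + (1 | male_id) + (1 | female_id) + (1 | aviary_pair)"))
  fit <- lme4::lmer(fml, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vtot <- sum(vc$vcov)
  varcomp <- data.table(
    component = c("pair", "male", "female", "aviary_pair", "residual"),
    share_pct = 100 * c(
      vc$vcov[vc$grp == "pair_id"], vc$vcov[vc$grp == "male_id"],
      vc$vcov[vc$grp == "female_id"], vc$vcov[vc$grp == "aviary_pair"],
      vc$vcov[vc$grp == "Residual"]) / vtot)
  cf <- summary(fit)$coefficients
  fixed_dt <- data.table(
    term = rownames(cf), estimate = cf[, 1], se = cf[, 2], t = cf[, 3],
    ci_lower = cf[, 1] - qnorm(0.975) * cf[, 2],
    ci_upper = cf[, 1] + qnorm(0.975) * cf[, 2],
    p = 2 * pnorm(-abs(cf[, 3])))
  structure(list(fixed = fixed_dt, varcomp = varcomp, singular = singular,
                 n_obs = nrow(df), model = fit),
            class = "distance_model_fit")
}

#' @export
print.distance_model_fit <- function(x, ...) {
  cat(sprintf("dyadic distance model (N = %d obs%s)\n", x$n_obs,
              if (x$singular) ", SINGULAR FIT" else ""))
  cat("random effects (% variance):\n")
  for (i in seq_len(nrow(x$varcomp))) {
    cat(sprintf("  %-12s %5.1f%%\n", x$varcomp$component[i], x$varcomp$share_pct[i]))
  }
  cat("fixed effects:\n")
  print(x$fixed, digits = 3)
  invisible(x)
}
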