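# Dyadic distances from tracking fixes. Distances are computed only at
# timestamps where both members of a dyad are detected (simultaneity =
# exact shared tick, no interpolation); dyads with no co-detections on a
# day are absent from the output (missing, not zero).

#' Daily mean dyadic distances from tracking fixes
#'
#' @param fixes `data.table` of fixes as emitted by [simulate_tracking()].
#' @param birds `data.table` of birds (for sexes).
#' @param scope `"between_sex"` (male-female dyads; `id_a` is the female),
#'   `"same_sex"` (male-male and female-female), or `"all"`.
#' @return `data.table`: `id_a`, `id_b`, `dyad_type` (`"FM"`, `"MM"`,
#'   `"FF"`), `day_index`, `mean_distance_mm`, `ln_distance`,
#'   `n_simultaneous_fixes`.
#' @export
dyad_daily_distances <- function(fixes, birds,
                                 scope = c("between_sex", "same_sex", "all")) {
  scope <- match.arg(scope)
  fixes <- as.data.table(fixes)
  dup <- fixes[, .N, by = .(day_index, timestamp, bird_id)][N > 1]
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate fix: bird %s at day %d t=%s", dup$bird_id[1],
                 dup$day_index[1], format(dup$timestamp[1])), call. = FALSE)
  }
  sex <- setNames(birds$sex, birds$bird_id)
  out <- vector("list", 0)
  for (d in sort(unique(fixes$day_index))) {
    fd <- fixes[day_index == d]
    ts <- sort(unique(fd$timestamp))
    ids <- sort(unique(fd$bird_id))
    ti <- match(fd$timestamp, ts); bi <- match(fd$bird_id, ids)
    X <- matrix(NA_real_, length(ts), length(ids))
    Y <- X
    X[cbind(ti, bi)] <- fd$x_mm
    Y[cbind(ti, bi)] <- fd$y_mm
    sx <- sex[ids]
    pair_sets <- list()
    if (scope %in% c("between_sex", "all")) {
      pair_sets$FM <- list(a = which(sx == "F"), b = which(sx == "M"))
    }
    if (scope %in% c("same_sex", "all")) {
      pair_sets$MM <- list(a = which(sx == "M"), b = which(sx == "M"))
      pair_sets$FF <- list(a = which(sx == "F"), b = which(sx == "F"))
    }
    for (tp in names(pair_sets)) {
      ps <- pair_sets[[tp]]
      same <- tp != "FM"
      for (ai in ps$a) {
        bs <- if (same) ps$b[ps$b > ai] else ps$b
        if (length(bs) == 0) next
        dx <- X[, bs, drop = FALSE] - X[, ai]
        dy <- Y[, bs, drop = FALSE] - Y[, ai]
        dist <- sqrt(dx^2 + dy^2)
        ncd <- colSums(!is.na(dist))
        keep <- which(ncd > 0)
        if (length(keep) == 0) next
        md <- colMeans(dist[, keep, drop = FALSE], na.rm = TRUE)
        out[[length(out) + 1L]] <- data.table(
          id_a = ids[ai], id_b = ids[bs[keep]], dyad_type = tp,
          day_index = d, mean_distance_mm = md, ln_distance = log(md),
          n_simultaneous_fixes = ncd[keep])
      }
    }
  }
  rbindlist(out)
}

#' Aggregate dyad-day distances over the whole period
#'
#' Co-detection-weighted mean of the daily means, which equals the mean
#' over all co-detected ticks.
#'
#' @param dd output of [dyad_daily_distances()].
#' @return `data.table`: one row per dyad with `mean_distance_mm` and
#'   `n_simultaneous_fixes`.
#' @export
aggregate_dyad_distances <- function(dd) {
  dd[, .(mean_distance_mm = sum(mean_distance_mm * n_simultaneous_fixes) /
           sum(n_simultaneous_fixes),
         n_simultaneous_fixes = sum(n_simultaneous_fixes)),
     by = .(id_a, id_b, dyad_type)]
}

#' Nearest opposite-sex individual per bird
#'
#' @param dd between-sex dyad-day distances (or an already aggregated
#'   table from [aggregate_dyad_distances()]).
#' @param min_fixes minimum co-detections for a dyad to be eligible.
#' @return list with `assignments` (`data.table`: `bird_id`, `sex`,
#'   `nearest_id`, `mean_distance_mm`, `n_simultaneous_fixes`) and
#'   `reciprocity` (fraction of assignments that are mutual).
#' @export
nearest_opposite_sex <- function(dd, min_fixes = 1L) {
  agg <- if ("day_index" %in% names(dd)) aggregate_dyad_distances(dd) else as.data.table(dd)
  agg <- agg[dyad_type == "FM" & n_simultaneous_fixes >= min_fixes]
  ds_assert(nrow(agg) > 0, "no opposite-sex dyads with co-detections")
  long <- rbind(agg[, .(bird_id = id_a, sex = "F", partner = id_b,
                        mean_distance_mm, n_simultaneous_fixes)],
                agg[, .(bird_id = id_b, sex = "M", partner = id_a,
                        mean_distance_mm, n_simultaneous_fixes)])
  pick <- function(sub) {
    o <- order(sub$mean_distance_mm, -sub$n_simultaneous_fixes, sub$partner)
    if (nrow(sub) > 1 &&
        abs(sub$mean_distance_mm[o[1]] - sub$mean_distance_mm[o[2]]) < 1e-12) {
      warning("nearest-neighbour tie broken by co-detections then id")
    }
    sub[o[1]]
  }
  asg <- long[, pick(.SD), by = .(bird_id, sex)]
  asg <- asg[, .(bird_id, sex, nearest_id = partner, mean_distance_mm,
                 n_simultaneous_fixes)]
  nn <- setNames(asg$nearest_id, asg$bird_id)
  recip <- mean(nn[asg$nearest_id] == asg$bird_id, na.rm = TRUE)
  list(assignments = asg, reciprocity = recip)
}

#' Concordance between nearest neighbours and called pairs
#'
#' Fraction of focal birds whose nearest opposite-sex individual is among
#' their called partners, plus a distance-binned version of the same
#' proportion.
#'
#' @param nearest output of [nearest_opposite_sex()] (or its
#'   `assignments` table).
#' @param pairs `data.table` with `female_id`, `male_id`.
#' @param sex_focal restrict focal birds to one sex (`"F"`, `"M"`) or
#'   `"both"`.
#' @param n_bins distance bins for the binned proportion.
#' @return list: `n`, `n_matched`, `proportion`, `percentage` (rounded to
#'   integer), `by_distance` (`data.table`).
#' @export
concordance_with_pairs <- function(nearest, pairs, sex_focal = "both",
                                   n_bins = 4L) {
  asg <- if (is.list(nearest) && !is.data.frame(nearest)) nearest$assignments else as.data.table(nearest)
  ds_assert(nrow(asg) > 0, "empty nearest-neighbour assignments")
  ds_assert(nrow(pairs) > 0, "empty pair set")
  if (sex_focal != "both") asg <- asg[sex == sex_focal]
  pk <- paste(pairs$female_id, pairs$male_id)
  matched <- ifelse(asg$sex == "F", paste(asg$bird_id, asg$nearest_id),
                    paste(asg$nearest_id, asg$bird_id)) %in% pk
  n <- nrow(asg)
  bins <- cut(asg$mean_distance_mm,
              breaks = unique(quantile(asg$mean_distance_mm,
                                       probs = seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  byd <- data.table(bin = bins, matched = matched)[, .(
    n = .N, proportion = mean(matched)), by = bin][order(bin)]
  list(n = n, n_matched = sum(matched), proportion = sum(matched) / n,
       percentage = round(100 * sum(matched) / n), by_distance = byd)
}
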