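# Categorical (Newman) assortativity on weighted networks, with a
# node-label permutation test. r = (sum_i e_ii - sum_i a_i b_i) /
# (1 - sum_i a_i b_i), where e is the edge-weight mixing matrix with
# undirected edges counted once in each orientation (so a = b).

#' Build a proximity network from dyadic weights
#'
#' @param edges `data.frame` with columns `id_a`, `id_b`, `weight`
#'   (nonnegative; self-edges forbidden).
#' @param nodes `data.frame` of node attributes with `bird_id` plus any
#'   categorical columns.
#' @return list of class `proximity_network`.
#' @export
proximity_network <- function(edges, nodes) {
  edges <- as.data.table(edges)
  nodes <- as.data.table(nodes)
  ds_assert(all(c("id_a", "id_b", "weight") %in% names(edges)),
            "edges needs id_a, id_b, weight")
  ds_assert(all(edges$weight >= 0), "edge weights must be nonnegative")
  ds_assert(!any(edges$id_a == edges$id_b), "self-edges are not allowed")
  ds_assert(all(c(edges$id_a, edges$id_b) %in% nodes$bird_id),
            "edge endpoints missing from node table")
  structure(list(edges = edges, nodes = nodes), class = "proximity_network")
}

# fast core: r from integer endpoint labels
assort_r_core <- function(la, lb, w, n_levels) {
  W <- sum(w)
  eii <- sum(w[la == lb]) / W
  s <- numeric(n_levels)
  for (k in seq_len(n_levels)) s[k] <- (sum(w[la == k]) + sum(w[lb == k])) / (2 * W)
  sab <- sum(s^2)
  if (abs(1 - sab) < 1e-12) {
    if (eii < 1 - 1e-12) stop("degenerate margins (sum a_i b_i = 1) with imperfect mixing")
    return(1)
  }
  (eii - sab) / (1 - sab)
}

#' Categorical assortativity coefficient
#'
#' @param network a [proximity_network()].
#' @param attribute name of a categorical node column.
#' @return r in `[-1, 1]`.
#' @export
assortativity <- function(network, attribute) {
  nodes <- network$nodes; edges <- network$edges
  ds_assert(attribute %in% names(nodes), paste("unknown attribute", attribute))
  lab <- factor(nodes[[attribute]])
  ds_assert(nlevels(lab) >= 2 && length(unique(lab[match(
    unique(c(edges$id_a, edges$id_b)), nodes$bird_id)])) >= 2,
    "attribute has a single level on this network: assortativity undefined")
  ds_assert(sum(edges$weight) > 0, "total edge weight must be positive")
  la <- as.integer(lab[match(edges$id_a, nodes$bird_id)])
  lb <- as.integer(lab[match(edges$id_b, nodes$bird_id)])
  assort_r_core(la, lb, edges$weight, nlevels(lab))
}

#' Node-label permutation test for assortativity
#'
#' Labels are permuted uniformly across nodes (preserving label counts).
#' The literal p-value is the proportion of permuted coefficients strictly
#' larger than the observed one; the add-one conservative variant
#' `(1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` is co-reported.
#'
#' @param network a [proximity_network()].
#' @param attribute categorical node column.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `assortativity_result`: `r`, `p_perm`,
#'   `p_conservative`, `n_perm`, `attribute`, `seed`.
#' @export
permutation_test <- function(network, attribute, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is unstable")
  r_obs <- assortativity(network, attribute)
  nodes <- network$nodes; edges <- network$edges
  lab <- as.integer(factor(nodes[[attribute]]))
  K <- max(lab)
  ia <- match(edges$id_a, nodes$bird_id)
  ib <- match(edges$id_b, nodes$bird_id)
  w <- edges$weight
  W <- sum(w)
  # node strengths (each undirected edge contributes to both endpoints)
  s <- numeric(nrow(nodes))
  for (e in seq_along(w)) { s[ia[e]] <- s[ia[e]] + w[e]; s[ib[e]] <- s[ib[e]] + w[e] }
  r_perm <- numeric(n_perm)
  withr::with_seed(seed, {
    block <- 2000L
    done <- 0L
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      L <- vapply(seq_len(nb), function(i) sample(lab), integer(length(lab)))
      same <- L[ia, , drop = FALSE] == L[ib, , drop = FALSE]
      eii <- colSums(w * same) / W
      sab <- numeric(nb)
      for (k in seq_len(K)) sab <- sab + (colSums(s * (L == k)) / (2 * W))^2
      r_perm[done + seq_len(nb)] <- (eii - sab) / (1 - sab)
      done <- done + nb
    }
  })
  structure(list(r = r_obs, attribute = attribute, n_perm = n_perm,
                 p_perm = sum(r_perm > r_obs) / n_perm,
                 p_conservative = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
                 seed = seed),
            class = "assortativity_result")
}

#' @export
print.assortativity_result <- function(x, ...) {
  cat(sprintf("assortativity r = %.3f (%s), p_perm = %.4g (conservative %.4g, %d permutations)\n",
              x$r, x$attribute, x$p_perm, x$p_conservative, x$n_perm))
  invisible(x)
}

#' Export a proximity network as GraphML and weighted edge-list CSV
#'
#' @param network a [proximity_network()].
#' @param path_graphml,path_csv output paths (either may be `NULL` to skip).
#' @return written paths, invisibly.
#' @export
write_network <- function(network, path_graphml = NULL, path_csv = NULL) {
  written <- character(0)
  if (!is.null(path_csv)) {
    write.csv(network$edges, path_csv, row.names = FALSE)
    written <- c(written, path_csv)
  }
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(network$edges,
                                       directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path_graphml, format = "graphml")
    written <- c(written, path_graphml)
  }
  invisible(written)
}

#' Convert dyad-day distances to a one-day weighted network
#'
#' Edge weight is `1/mean_distance_mm` by default (declared convention), or
#' `max(d) - d` with `weight = "max_minus"`.
#'
#' @param dd_day dyad rows of a single day (or aggregated period).
#' @param nodes node attribute table.
#' @param weight `"inverse"` or `"max_minus"`.
#' @return a [proximity_network()].
#' @export
distance_network <- function(dd_day, nodes, weight = c("inverse", "max_minus")) {
  weight <- match.arg(weight)
  w <- if (weight == "inverse") 1 / dd_day$mean_distance_mm
       else max(dd_day$mean_distance_mm) - dd_day$mean_distance_mm
  proximity_network(data.table(id_a = dd_day$id_a, id_b = dd_day$id_b,
                               weight = w), nodes)
}

#' Daily assortment series and linear trends
#'
#' For each day, builds the weighted network from that day's dyadic
#' distances and computes the assortativity coefficient for each requested
#' attribute; returns per-day values and fitted linear slopes over days.
#' Days with fewer than 2 dyads are skipped with a warning.
#'
#' @param dd dyad-day distances ([dyad_daily_distances()]).
#' @param birds node attribute table.
#' @param attributes categorical columns to evaluate.
#' @param scope `"between_sex"` or `"same_sex"` (rows are filtered by
#'   `dyad_type`).
#' @param weight distance-to-weight convention, see [distance_network()].
#' @return list with `series` (`data.table`: day_index, attribute, r) and
#'   `slopes` (`data.table`: attribute, slope, se, p).
#' @export
daily_assortment_series <- function(dd, birds,
                                    attributes = c("rearing_pop", "genetic_pop"),
                                    scope = c("between_sex", "same_sex"),
                                    weight = "inverse") {
  scope <- match.arg(scope)
  dd <- as.data.table(dd)
  dd <- dd[dyad_type %in% if (scope == "between_sex") "FM" else c("MM", "FF")]
  ds_assert(length(unique(dd$day_index)) >= 2, "need at least 2 days of data")
  rows <- list()
  for (d in sort(unique(dd$day_index))) {
    sub <- dd[day_index == d]
    if (nrow(sub) < 2) { warning(sprintf("day %d has < 2 dyads; skipped", d)); next }
    net <- distance_network(sub, birds, weight)
    for (at in attributes) {
      rows[[length(rows) + 1L]] <- data.table(day_index = d, attribute = at,
                                              r = assortativity(net, at))
    }
  }
  series <- rbindlist(rows)
  slopes <- series[, {
    f <- lm(r ~ day_index, data = .SD)
    cf <- summary(f)$coefficients
    .(slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
  }, by = attribute]
  list(series = series, slopes = slopes)
}
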