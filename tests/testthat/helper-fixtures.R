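# Shared fixtures, built once per test run and cached.
library(data.table)

.fx <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# a small cross-fostered Generation-2 world (moderate divergence)
small_world <- function() cached("small_world", {
  replicate_world(population_spec("W1"), population_spec("D1"),
                  n_per_type = 10L, n_founder = 8L, seed = 5L)
})

# hand-built bird table with arbitrary attributes
toy_birds <- function(n_f = 2L, n_m = 2L, types = NULL) {
  ids_f <- sprintf("F%02d", seq_len(n_f))
  ids_m <- sprintf("M%02d", seq_len(n_m))
  if (is.null(types)) types <- rep("DW", n_f + n_m)
  data.table(bird_id = c(ids_f, ids_m),
             sex = rep(c("F", "M"), c(n_f, n_m)),
             genetic_pop = ifelse(substr(types, 1, 1) == "D", "D1", "W1"),
             rearing_pop = ifelse(substr(types, 2, 2) == "D", "D1", "W1"),
             lineage_code = types,
             rearing_aviary = "A1", generation = 2L,
             body_size = 14, foster_father = NA_character_)
}

# fixes table placing two birds at fixed coordinates for every tick
fixed_fixes <- function(coords, n_ticks = 5L, day = 1L) {
  rbindlist(lapply(seq_len(nrow(coords)), function(i) {
    data.table(timestamp = 2 * seq_len(n_ticks), day_index = day,
               bird_id = rownames(coords)[i],
               x_mm = coords[i, 1], y_mm = coords[i, 2], station_id = "P1")
  }))
}

# brute-force dyadic mean distance over co-detected ticks (oracle)
brute_dyad_distance <- function(fixes, a, b) {
  fa <- fixes[bird_id == a]; fb <- fixes[bird_id == b]
  m <- merge(fa, fb, by = c("day_index", "timestamp"))
  if (nrow(m) == 0) return(NULL)
  m[, d := sqrt((x_mm.x - x_mm.y)^2 + (y_mm.x - y_mm.y)^2)]
  m[, .(mean_d = mean(d), n = .N), by = day_index]
}

# weight-expanded Pearson correlation oracle for 2-level assortativity:
# every undirected edge contributes its weight to both orientations of the
# endpoint indicator pairs
pearson_assort_oracle <- function(edges, labels) {
  x <- c(labels[edges$id_a], labels[edges$id_b])
  y <- c(labels[edges$id_b], labels[edges$id_a])
  w <- rep(edges$weight, 2)
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  sum(w * (x - xm) * (y - ym)) /
    sqrt(sum(w * (x - xm)^2) * sum(w * (y - ym)^2))
}

# dyad-day generator with known variance components and an optional
# H3 fixed effect, used for mixed-model recovery tests
simulate_dyad_days <- function(shares = c(pair = 0.40, male = 0.03,
                                          female = 0.03, avi = 0.02,
                                          res = 0.52),
                               beta_H3 = 0, n_m = 15, n_f = 10, days = 30,
                               seed = 3) {
  withr::with_seed(seed, {
    mk <- function(n, sex) data.table(
      bird_id = sprintf("%s%02d", sex, 1:n), sex = sex,
      lineage_code = sample(c("DD", "DW", "WD", "WW"), n, TRUE),
      rearing_aviary = sample(paste0("A", 1:4), n, TRUE),
      body_size = rnorm(n, 14, 2), rearing_pop = "X", genetic_pop = "Y",
      generation = 2L, foster_father = NA_character_)
    birds <- rbind(mk(n_f, "F"), mk(n_m, "M"))
    dyads <- CJ(female_id = birds[sex == "F", bird_id],
                male_id = birds[sex == "M", bird_id])
    nd <- nrow(dyads)
    u_p <- rnorm(nd, 0, sqrt(shares["pair"]))
    u_m <- setNames(rnorm(n_m, 0, sqrt(shares["male"])), birds[sex == "M", bird_id])
    u_f <- setNames(rnorm(n_f, 0, sqrt(shares["female"])), birds[sex == "F", bird_id])
    fa <- setNames(birds$rearing_aviary, birds$bird_id)
    avl <- unique(paste(fa[dyads$female_id], fa[dyads$male_id], sep = ":"))
    u_a <- setNames(rnorm(length(avl), 0, sqrt(shares["avi"])), avl)
    code <- setNames(birds$lineage_code, birds$bird_id)
    h3 <- as.numeric(substr(code[dyads$female_id], 2, 2) ==
                     substr(code[dyads$male_id], 2, 2))
    dd <- dyads[rep(seq_len(nd), each = days)]
    dd[, day_index := rep(seq_len(days), times = nd)]
    base <- u_p[rep(seq_len(nd), each = days)] +
      u_m[dd$male_id] + u_f[dd$female_id] +
      u_a[paste(fa[dd$female_id], fa[dd$male_id], sep = ":")] +
      beta_H3 * h3[rep(seq_len(nd), each = days)] +
      rnorm(nrow(dd), 0, sqrt(shares["res"]))
    dd[, `:=`(ln_distance = 7 + base, mean_distance_mm = exp(7 + base),
              id_a = female_id, id_b = male_id, dyad_type = "FM",
              n_simultaneous_fixes = 10L)]
    list(birds = birds, dyads = dyads, dd = dd)
  })
}
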