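# Dyadic distances, nearest neighbours, assortativity, permutation test.

test_that("dyadic distance matches the 3-4-5 triangle and the brute force", {
  birds <- toy_birds(1, 1)
  coords <- rbind(F01 = c(0, 0), M01 = c(3000, 4000))
  dd <- dyad_daily_distances(fixed_fixes(coords), birds)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$mean_distance_mm, 5000)
  expect_equal(dd$ln_distance, log(5000))
  expect_equal(dd$n_simultaneous_fixes, 5L)

  # randomized fixture vs brute-force oracle, plus row-order invariance
  set.seed(9)
  birds4 <- toy_birds(2, 2)
  fx <- CJ(timestamp = 2 * (1:10), bird_id = birds4$bird_id)
  fx[, `:=`(day_index = 1L, x_mm = runif(.N, 0, 5000),
            y_mm = runif(.N, 0, 2000), station_id = "P1")]
  fx <- fx[runif(.N) < 0.8]   # random missing fixes
  dd <- dyad_daily_distances(fx, birds4, scope = "all")
  for (i in seq_len(nrow(dd))) {
    o <- brute_dyad_distance(fx, dd$id_a[i], dd$id_b[i])
    expect_equal(dd$mean_distance_mm[i], o$mean_d, tolerance = 1e-12)
    expect_equal(dd$n_simultaneous_fixes[i], o$n)
  }
  shuf <- fx[sample(.N)]
  dd2 <- dyad_daily_distances(shuf, birds4, scope = "all")
  setkey(dd, id_a, id_b); setkey(dd2, id_a, id_b)
  expect_equal(dd, dd2)
})

test_that("undetected birds yield missing dyads and duplicates error", {
  birds <- toy_birds(1, 2)
  coords <- rbind(F01 = c(0, 0), M01 = c(1000, 0))   # M02 never detected
  fx <- fixed_fixes(coords)
  dd <- dyad_daily_distances(fx, birds)
  expect_false("M02" %in% dd$id_b)
  dup <- rbind(fx, fx[1])
  expect_error(dyad_daily_distances(dup, birds), "duplicate fix")
})

test_that("nearest opposite-sex assignment, ties and reciprocity", {
  birds <- toy_birds(1, 2)
  coords <- rbind(F01 = c(0, 0), M01 = c(500, 0), M02 = c(4000, 0))
  no <- nearest_opposite_sex(dyad_daily_distances(fixed_fixes(coords), birds))
  asg <- no$assignments
  expect_equal(asg[bird_id == "F01", nearest_id], "M01")
  # two-bird case: perfectly reciprocal
  birds2 <- toy_birds(1, 1)
  no2 <- nearest_opposite_sex(
    dyad_daily_distances(fixed_fixes(rbind(F01 = c(0, 0), M01 = c(100, 0))), birds2))
  expect_equal(no2$reciprocity, 1)
  # exact tie -> warning, id-lexicographic winner
  birdsT <- toy_birds(1, 2)
  coordsT <- rbind(F01 = c(0, 0), M01 = c(1000, 0), M02 = c(-1000, 0))
  expect_warning(noT <- nearest_opposite_sex(
    dyad_daily_distances(fixed_fixes(coordsT), birdsT)), "tie")
  expect_equal(noT$assignments[bird_id == "F01", nearest_id], "M01")
})

test_that("assortativity matches hand values and the Pearson oracle", {
  nodes <- data.table(bird_id = c("f1", "f2", "m1", "m2"),
                      grp = c("D", "W", "D", "W"))
  within <- data.table(id_a = c("f1", "f2"), id_b = c("m1", "m2"), weight = 1)
  across <- data.table(id_a = c("f1", "f2"), id_b = c("m2", "m1"), weight = 1)
  expect_equal(assortativity(proximity_network(within, nodes), "grp"), 1)
  expect_equal(assortativity(proximity_network(across, nodes), "grp"), -1)
  both <- rbind(within, across)
  expect_equal(assortativity(proximity_network(both, nodes), "grp"), 0)
  mono <- copy(nodes)[, grp := "D"]
  expect_error(assortativity(proximity_network(within, mono), "grp"),
               "single level")

  # weight-expanded Pearson equivalence on random <= 6-node networks
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    nod <- data.table(bird_id = paste0("b", 1:n),
                      grp = sample(c(0, 1), n, replace = TRUE))
    if (length(unique(nod$grp)) < 2) next
    pr <- as.data.table(t(combn(n, 2)))
    ed <- data.table(id_a = paste0("b", pr$V1), id_b = paste0("b", pr$V2),
                     weight = sample(1:5, nrow(pr), replace = TRUE))
    ed <- ed[runif(.N) < 0.85]
    if (nrow(ed) < 1) next
    labs <- setNames(nod$grp, nod$bird_id)
    if (length(unique(c(labs[ed$id_a], labs[ed$id_b]))) < 2) next
    r <- assortativity(proximity_network(ed, nod), "grp")
    expect_equal(r, pearson_assort_oracle(ed, labs), tolerance = 1e-12)
  }
})

test_that("permutation test: literal rule, determinism, relabel invariance", {
  nodes <- data.table(bird_id = paste0("b", 1:8),
                      grp = rep(c("D", "W"), each = 4))
  within <- data.table(
    id_a = c("b1", "b2", "b5", "b6"), id_b = c("b3", "b4", "b7", "b8"),
    weight = 1)
  net <- proximity_network(within, nodes)
  res <- permutation_test(net, "grp", n_perm = 500, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p_perm, 0)               # nothing exceeds r = 1
  expect_gt(res$p_conservative, 0)
  res2 <- permutation_test(net, "grp", n_perm = 500, seed = 3)
  expect_identical(res$p_perm, res2$p_perm)
  # renaming the categories must not change p
  nodes2 <- copy(nodes)[, grp := ifelse(grp == "D", "xx", "yy")]
  res3 <- permutation_test(proximity_network(within, nodes2), "grp",
                           n_perm = 500, seed = 3)
  expect_identical(res$p_perm, res3$p_perm)
  expect_warning(permutation_test(net, "grp", n_perm = 50, seed = 1),
                 "unstable")
})

test_that("concordance proportions go through the real code path", {
  # constructed assignments: 74 of 151 females' nearest males are partners
  asg <- data.table(bird_id = sprintf("F%03d", 1:151), sex = "F",
                    nearest_id = sprintf("M%03d", 1:151),
                    mean_distance_mm = seq(100, 1600, length.out = 151),
                    n_simultaneous_fixes = 100L)
  pairs <- data.table(female_id = sprintf("F%03d", 1:74),
                      male_id = sprintf("M%03d", 1:74))
  cc <- concordance_with_pairs(asg, pairs)
  expect_equal(cc$n_matched, 74L)
  expect_equal(cc$percentage, 49)
  all_p <- data.table(female_id = asg$bird_id, male_id = asg$nearest_id)
  expect_equal(concordance_with_pairs(asg, all_p)$percentage, 100)
  none <- data.table(female_id = "F999", male_id = "M999")
  expect_equal(concordance_with_pairs(asg, none)$percentage, 0)
  expect_error(concordance_with_pairs(asg[0], pairs), "empty")
})

test_that("daily series: null is centred on zero, weight options agree in sign", {
  set.seed(2)
  birds <- toy_birds(8, 8, types = sample(rep(c("DD", "WW"), 8)))
  des <- experiment_design(days = 5, day_length_h = 0.05)
  fx <- simulate_tracking(birds, preference_model(), NULL, des, seed = 21)
  dd <- dyad_daily_distances(fx, birds, scope = "all")
  ser <- daily_assortment_series(dd, birds, attributes = "rearing_pop",
                                 scope = "between_sex")
  se <- sd(ser$series$r) / sqrt(nrow(ser$series))
  expect_lt(abs(mean(ser$series$r)), 3 * se + 0.05)
  # alternative weight transform gives sign-consistent daily coefficients
  ser2 <- daily_assortment_series(dd, birds, attributes = "rearing_pop",
                                  scope = "between_sex", weight = "max_minus")
  expect_gt(cor(ser$series$r, ser2$series$r), 0)
})
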