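# Hypothesis matrices, correlations, mixtures, dyad predictors, and the
# crossed-random-effects distance model.

balanced_comp <- data.frame(type = c("DD", "DW", "WD", "WW"),
                            n_female = 10, n_male = 10)

test_that("hypothesis cell codings match the hand enumeration", {
  h2 <- hypothesis_spec("H2")$allowed
  # mutual morphotype imprinting: partner's origin equals own rearing letter
  expect_true(h2["WD", "DW"])
  expect_true(h2["DW", "WD"])
  expect_true(h2["DD", "DD"])
  expect_true(h2["WW", "WW"])
  expect_false(h2["DD", "DW"])
  expect_false(h2["WD", "WD"])
  expect_equal(sum(h2), 4L)
  expect_equal(sum(hypothesis_spec("H1")$allowed), 8L)
  expect_equal(sum(hypothesis_spec("H3")$allowed), 8L)
  expect_equal(sum(hypothesis_spec("H1W")$allowed), 8L)
})

test_that("expected matrices allocate totals over allowed cells", {
  e3 <- expected_matrix("H3", balanced_comp, 40)
  expect_equal(sum(e3), 40, tolerance = 1e-9)
  expect_equal(sort(unique(as.vector(e3))), c(0, 5))
  expect_equal(sum(e3 > 0), 8L)
  e1 <- expected_matrix("H1", balanced_comp, 40)
  expect_equal(sort(unique(as.vector(e1))), c(0, 5))
  # structural symmetry: swapping the role of the two code letters maps
  # H1 onto H3 (reorder types so letters swap: DD, WD, DW, WW)
  sw <- c(1, 3, 2, 4)
  expect_equal(unclass(e1)[sw, sw], unclass(unname(e3))[,],
               ignore_attr = TRUE)
  # degenerate composition concentrates on the only possible cell
  dd_only <- data.frame(type = "DD", n_female = 5, n_male = 5)
  ed <- expected_matrix("H3", dd_only, 10)
  expect_equal(ed["DD", "DD"], 10)
  expect_equal(sum(ed), 10)
  expect_error(expected_matrix("H2", data.frame(type = "DD", n_female = 0,
                                                n_male = 5), 10), "allowed")
  # unbalanced composition shifts mass proportionally
  unb <- data.frame(type = c("DD", "DW", "WD", "WW"),
                    n_female = c(7, 8, 8, 8), n_male = c(7, 8, 8, 8))
  eu <- expected_matrix("H3", unb, 40)
  expect_equal(sum(eu), 40, tolerance = 1e-9)
  expect_lt(eu["DD", "DD"], eu["DW", "DW"])
})

test_that("observed matrices count pairs per 16 cells", {
  birds <- rbind(toy_birds(3, 0, types = rep("DD", 3)),
                 toy_birds(0, 3, types = rep("DW", 3)))
  pairs <- data.table(female_id = birds[sex == "F", bird_id],
                      male_id = birds[sex == "M", bird_id])
  M <- observed_matrix(pairs, birds)
  expect_equal(M["DD", "DW"], 3)
  expect_equal(sum(M), 3)
  expect_equal(sum(observed_matrix(pairs[0], birds)), 0)
  birds_bad <- copy(birds)[1, lineage_code := "QQ"]
  expect_error(observed_matrix(pairs, birds_bad), "unknown lineage")
})

test_that("matrix correlation matches hand values and the t-transform", {
  e3 <- expected_matrix("H3", balanced_comp, 40)
  expect_equal(matrix_correlation(e3, e3)$r, 1)
  # hand enumeration: H1 and H3 share exactly half of their allowed cells,
  # which makes the two balanced 0/5 patterns uncorrelated
  e1 <- expected_matrix("H1", balanced_comp, 40)
  expect_equal(matrix_correlation(e1, e3)$r, 0, tolerance = 1e-12)
  expect_error(matrix_correlation(e3, matrix(1, 4, 4)), "constant")
  # r = 0.95 at n = 16 cells -> p ~ 1e-8 two-tailed (the reference value
  # 1.3e-8 was computed from the unrounded r; at the printed precision of
  # r = 0.95 the transform gives 1.8e-8 -- same order of magnitude)
  t95 <- 0.95 * sqrt(14) / sqrt(1 - 0.95^2)
  p95 <- 2 * pt(-t95, 14)
  expect_gt(p95, 1.0e-8); expect_lt(p95, 2.0e-8)
})

test_that("mixture fitting recovers constructed weights", {
  hyps <- c("H1", "H2", "H3", "H1W")
  E <- setNames(lapply(hyps, expected_matrix, composition = balanced_comp,
                       total_pairs = 40), hyps)
  expect_error(fit_mixture(E$H3, E, grid_step = 0.7), "grid_step")
  # pure H3 observed
  fm <- fit_mixture(E$H3, E, grid_step = 0.05)
  expect_equal(unname(fm$weights["H3"]), 1)
  # single-hypothesis list
  f1 <- fit_mixture(E$H3, E["H3"])
  expect_equal(unname(f1$weights), 1)
  expect_equal(f1$correlation, 1)
  # half-half H3/H2 with small noise, recovered within +/- 0.1
  obs <- 0.5 * E$H3 + 0.5 * E$H2 +
    withr::with_seed(12, matrix(rnorm(16, 0, 0.15), 4))
  fm2 <- fit_mixture(obs, E[c("H2", "H3")], grid_step = 0.01)
  expect_lt(abs(fm2$weights[["H3"]] - 0.5), 0.1)
  expect_lt(abs(fm2$weights[["H2"]] - 0.5), 0.1)
})

test_that("replicate repeatability: identity, null, and H3-generated runs", {
  e3 <- expected_matrix("H3", balanced_comp, 40)
  expect_equal(replicate_repeatability(e3, e3)$r, 1)
  # iid random matrices are uncorrelated on average
  rs <- withr::with_seed(5, replicate(500, {
    replicate_repeatability(matrix(rpois(16, 5), 4),
                            matrix(rpois(16, 5), 4))$r
  }))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(500))
  # two independent rearing-assortative replicates agree strongly
  birds <- small_world()$g2$birds
  m1 <- observed_matrix(sample_true_pairs(birds, "rearing", seed = 1), birds)
  m2 <- observed_matrix(sample_true_pairs(birds, "rearing", seed = 2), birds)
  expect_gt(replicate_repeatability(m1, m2)$r, 0.8)
})

test_that("dyad predictors code the 16 type combinations correctly", {
  birds <- rbind(toy_birds(2, 0, types = c("DD", "WD")),
                 toy_birds(0, 2, types = c("DW", "DW")))
  dyads <- CJ(female_id = birds[sex == "F", bird_id],
              male_id = birds[sex == "M", bird_id])
  pr <- dyad_predictors(dyads, birds)
  dd_dw <- pr[female_id == "F01"][1]   # DD female x DW male
  expect_equal(dd_dw$H3, 0)            # rearing D vs W
  expect_equal(dd_dw$H1W, 0)           # both D origin
  expect_equal(dd_dw$H2, 0)
  wd_dw <- pr[female_id == "F02"][1]   # WD female x DW male
  expect_equal(wd_dw$H2, 1)            # mutual morphotype match
  expect_equal(wd_dw$H1W, 1)           # mixed origin
  expect_true(!is.null(attr(pr, "predictor_correlations")))
  scores <- data.table(dyads, ml_peers = 1)   # constant -> degenerate
  expect_error(dyad_predictors(dyads, birds, scores), "degenerate")
})


test_that("distance model recovers variance shares and fixed effects", {
  sim <- simulate_dyad_days(seed = 3)
  fit <- fit_distance_model(sim$dd, dyad_predictors(sim$dyads, sim$birds))
  truth <- c(pair = 40, male = 3, female = 3, aviary_pair = 2, residual = 52)
  expect_equal(sum(fit$varcomp$share_pct), 100, tolerance = 0.1)
  for (i in seq_len(5)) {
    expect_lt(abs(fit$varcomp$share_pct[i] - truth[[fit$varcomp$component[i]]]), 5)
  }
  # all-null fixed effects: CIs cover zero
  fx <- fit$fixed[term != "(Intercept)"]
  expect_true(all(fx$ci_lower <= 0 & fx$ci_upper >= 0))

  # a real negative H3 effect is detected; the others stay null
  sim2 <- simulate_dyad_days(beta_H3 = -0.6, seed = 8)
  fit2 <- fit_distance_model(sim2$dd, dyad_predictors(sim2$dyads, sim2$birds))
  h3 <- fit2$fixed[term == "H3"]
  expect_lt(h3$estimate, 0)
  expect_lt(h3$ci_upper, 0)
  oth <- fit2$fixed[term %in% c("H1W", "H2")]
  expect_true(all(oth$ci_lower <= 0 & oth$ci_upper >= 0))

  # permuted response: everything collapses to zero
  sim3 <- simulate_dyad_days(beta_H3 = -0.6, seed = 9)
  sim3$dd[, ln_distance := sample(ln_distance)]
  fit3 <- fit_distance_model(sim3$dd, dyad_predictors(sim3$dyads, sim3$birds))
  fx3 <- fit3$fixed[term != "(Intercept)"]
  expect_true(all(fx3$ci_lower <= 0 & fx3$ci_upper >= 0))
})
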