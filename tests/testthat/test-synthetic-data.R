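# Generators: populations, cultural transmission, song rendering,
# tracking and interaction simulators.

test_that("zero divergence means identical dialect pools", {
  a <- population_spec("W1", divergence_delta = 0)
  b <- population_spec("D1", divergence_delta = 0)
  expect_identical(a$pool, b$pool)
  c <- population_spec("D1", divergence_delta = 1)
  expect_false(identical(a$pool, c$pool))
  expect_error(population_spec("W1", innovation_rho = 1.2), "rho")
})

test_that("founder aviaries are balanced and males carry motifs", {
  w <- small_world()
  fb <- w$founders$birds
  expect_equal(fb[, .N, by = .(rearing_aviary, sex)][, unique(N)], 8L)
  males <- fb[sex == "M", bird_id]
  expect_setequal(names(w$founders$motifs), males)
  lens <- vapply(w$founders$motifs, function(m) length(m$syllables), 0L)
  expect_true(all(lens >= 3 & lens <= 8))
  # domesticated founders are distinctly larger (16 vs 12 g design)
  expect_gt(fb[genetic_pop == "D1", mean(body_size)],
            fb[genetic_pop == "W1", mean(body_size)] + 2)
})

test_that("cultural transmission respects the innovation rate", {
  w <- small_world()
  pops <- w$pops
  founders <- w$founders
  tutor_id <- founders$birds[rearing_aviary == "AW1" & sex == "M", bird_id][1]
  mating <- data.table(mother = founders$birds[sex == "F", bird_id][1],
                       father = founders$birds[rearing_aviary == "AW1" & sex == "M", bird_id][2],
                       rearing_aviary = "AW1", rearing_pop = "W1",
                       foster_father = tutor_id, n_sons = 1L, n_daughters = 1L)
  # rho = 0: son's motif is an exact copy
  off0 <- breed_generation(founders, mating, pops, rho = 0, seed = 2)
  son <- names(off0$motifs)[1]
  expect_equal(motif_shared_fraction(off0$motifs[[son]],
                                     founders$motifs[[tutor_id]]), 1)
  # rho = 1: nothing shared
  off1 <- breed_generation(founders, mating, pops, rho = 1, seed = 2)
  expect_equal(motif_shared_fraction(off1$motifs[[names(off1$motifs)[1]]],
                                     founders$motifs[[tutor_id]]), 0)
  # daughters carry no motif; codes follow the two-letter convention
  expect_equal(length(off0$motifs), 1L)
  expect_true(all(off0$birds$lineage_code == "WW"))
  expect_error(breed_generation(founders, mating, pops, rho = 1.5), "rho")
  bad <- copy(mating)[, foster_father := "nobody"]
  expect_error(breed_generation(founders, bad, pops, rho = 0.3), "nobody")
})

test_that("mean shared-syllable fraction matches 1 - rho (counting oracle)", {
  w <- small_world()
  founders <- w$founders
  tutors <- founders$birds[rearing_aviary == "AW1" & sex == "M", bird_id]
  # force 5-syllable tutor motifs for a clean binomial count
  founders2 <- founders
  founders2$motifs[[tutors[1]]] <- sample_motif(w$pops$W1, tutors[1],
                                                n_syl = 5L, seed = 99)
  matings <- data.table(mother = founders$birds[sex == "F", bird_id][1],
                        father = tutors[2], rearing_aviary = "AW1",
                        rearing_pop = "W1", foster_father = tutors[1],
                        n_sons = 300L, n_daughters = 0L)
  off <- breed_generation(founders2, matings, w$pops, rho = 0.3, seed = 7)
  shared <- vapply(off$motifs, motif_shared_fraction,
                   numeric(1), tutor = founders2$motifs[[tutors[1]]])
  se <- sqrt(0.3 * 0.7 / (300 * 5))
  expect_lt(abs(mean(shared) - 0.7), 3 * se)
})

test_that("lineage codes extend per generation (three letters in G3)", {
  w <- small_world()
  g2 <- w$g2
  expect_true(all(nchar(g2$birds$lineage_code) == 2))
  expect_setequal(unique(g2$birds$lineage_code), c("DD", "DW", "WD", "WW"))
  # first letter = genetic type, second = rearing type
  expect_true(all(substr(g2$birds$lineage_code, 1, 1) ==
                  substr(g2$birds$genetic_pop, 1, 1)))
  expect_true(all(substr(g2$birds$lineage_code, 2, 2) ==
                  substr(g2$birds$rearing_pop, 1, 1)))
  # breed a third generation from a G2 foster father
  parents <- list(birds = rbind(w$founders$birds, g2$birds),
                  motifs = w$motifs)
  g2m <- g2$birds[sex == "M"][1]
  mating <- data.table(mother = g2$birds[sex == "F", bird_id][1],
                       father = g2$birds[sex == "M", bird_id][2],
                       rearing_aviary = "AX", rearing_pop = g2m$rearing_pop,
                       foster_father = g2m$bird_id, n_sons = 1L,
                       n_daughters = 0L)
  g3 <- breed_generation(parents, mating, w$pops, rho = 0.3, seed = 3)
  expect_equal(nchar(g3$birds$lineage_code), 3L)
  expect_equal(substr(g3$birds$lineage_code, 2, 3), g2m$lineage_code)
})

test_that("render_song honours duration contract and determinism", {
  w <- small_world()
  m <- w$founders$motifs[[1]]
  s1 <- render_song(m, 6.8, seed = 4)
  s2 <- render_song(m, 6.8, seed = 4)
  expect_identical(s1$wave, s2$wave)          # bit-identical
  s3 <- render_song(m, 4.5, seed = 4)
  expect_true(s3$duration >= 4.25 && s3$duration <= 4.75)
  expect_error(render_song(m, 3.0, seed = 1), "4.5")
  expect_error(render_song(m, 11, seed = 1), "10.2")
  # a one-syllable change must alter the spectrogram (L2 oracle > 0)
  m2 <- m
  m2$syllables[[2]] <- w$founders$motifs[[3]]$syllables[[1]]
  s4 <- render_song(m2, 6.8, seed = 4)
  p1 <- dialectscope:::stft_power(s1$wave)$power
  p2 <- dialectscope:::stft_power(s4$wave)$power
  n <- min(nrow(p1), nrow(p2))
  expect_gt(sqrt(sum((log(p1[1:n, ] + 1e-8) - log(p2[1:n, ] + 1e-8))^2)), 0)
  expect_false(identical(s1$wave, s4$wave))
})

test_that("WAV round-trip preserves the waveform to 16-bit precision", {
  w <- small_world()
  rec <- render_motif(w$founders$motifs[[2]], seed = 1)
  path <- tempfile(fileext = ".wav")
  write_wav(rec$wave, path)
  back <- read_wav(path)
  expect_equal(back$sr, 22050L)
  expect_equal(back$wave, rec$wave, tolerance = 2 / 32767)
  unlink(path)
})

test_that("song-set sidecar carries the generator metadata", {
  w <- small_world()
  ids <- names(w$founders$motifs)[1:2]
  ss <- record_songs(w$motifs[ids], w$birds, n_rec = 2, seed = 3)
  expect_equal(nrow(ss$meta), 4L)
  expect_true(all(ss$meta$duration >= 4.5 & ss$meta$duration <= 10.2))
  dir <- tempfile()
  paths <- write_song_set(ss, dir)
  expect_true(file.exists(file.path(dir, sprintf("%s_1.wav", ids[1]))))
  expect_true(file.exists(file.path(dir, "songs_meta.csv")))
  unlink(dir, recursive = TRUE)
})

test_that("tracking fixes are reproducible and respect the design", {
  birds <- toy_birds(4, 4, types = rep(c("DD", "WW"), 4))
  des <- experiment_design(days = 2, day_length_h = 0.02)
  f1 <- simulate_tracking(birds, preference_model(), NULL, des, seed = 3)
  f2 <- simulate_tracking(birds, preference_model(), NULL, des, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1$day_index), 1:2)
  expect_true(all(f1$station_id %in% rownames(station_coords())))
  # detection drops about 10% of fixes
  expect_lt(nrow(f1), 2 * des$ticks_per_day * nrow(birds))
  expect_error(simulate_tracking(birds[0], preference_model(), NULL, des),
               "empty")
  expect_error(experiment_design(sample_interval = 0), "positive")
})

test_that("null preference model leaves dyad classes exchangeable", {
  set.seed(1)
  birds <- toy_birds(10, 10, types = sample(rep(c("DD", "WW"), 10)))
  des <- experiment_design(days = 4, day_length_h = 0.1)
  fx <- simulate_tracking(birds, preference_model(), NULL, des, seed = 11)
  dd <- aggregate_dyad_distances(dyad_daily_distances(fx, birds, "between_sex"))
  rp <- setNames(birds$rearing_pop, birds$bird_id)
  same <- dd[rp[id_a] == rp[id_b], mean_distance_mm]
  diff <- dd[rp[id_a] != rp[id_b], mean_distance_mm]
  se <- sqrt(var(same) / length(same) + var(diff) / length(diff))
  expect_lt(abs(mean(same) - mean(diff)), 3 * se)
})

test_that("interaction counts separate bonded from background dyads", {
  birds <- toy_birds(10, 10)
  tp <- data.table(female_id = birds[sex == "F", bird_id][1:5],
                   male_id = birds[sex == "M", bird_id][1:5])
  x1 <- simulate_interactions(birds, tp, seed = 5)
  x2 <- simulate_interactions(birds, tp, seed = 5)
  expect_identical(x1, x2)
  # Poisson tail oracle: P(count < 5 | bonded) = ppois(4, 20) ~ 1.7e-5
  expect_true(all(x1[bonded == TRUE, count] >= 5))
  expect_gt(mean(x1[bonded == FALSE, count] == 0), 0.5)
  expect_warning(simulate_interactions(birds, tp, background_lambda = 5,
                                       bonded_lambda = 4, seed = 1),
                 "unreliable")
})

test_that("background counts fit a zero-truncated Poisson (gof oracle)", {
  set.seed(20)
  counts <- dialectscope:::rztp(500, 1.2)
  fit <- fit_ztp(counts)
  obs <- tabulate(counts, nbins = max(counts))
  expb <- 500 * dztp(seq_len(max(counts)), fit$lambda_hat)
  # pool the tail so expected counts stay >= 5
  cutv <- max(which(expb >= 5))
  o <- c(obs[1:cutv], sum(obs[-(1:cutv)]))
  e <- c(expb[1:cutv], 500 - sum(expb[1:cutv]))
  stat <- sum((o - e)^2 / e)
  p <- pchisq(stat, df = length(o) - 2, lower.tail = FALSE)
  expect_gt(p, 0.01)
})
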