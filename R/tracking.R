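# Proximity-tracking simulator. Emulates a barcode-camera system: every
# `sample_interval` seconds each bird sits at one of eight stations (six
# perches, two feeders) on a 5 m x 2 m floor plan; a camera "fix" records
# its position (station coordinate + mm-scale jitter) with a detection
# probability per bird per tick. Mate preferences enter as attraction terms
# that raise the probability of choosing the station currently occupied by
# preferred partners; attraction ramps linearly from 0 to full strength over
# `ramp_days` days.

#' Station coordinates of the simulated aviary (mm)
#'
#' Eight stations on a 5 m x 2 m floor plan: six perches in two rows plus
#' two feeders at the ends. The true layout of the original system is not
#' published; this geometry is declared, not inferred.
#'
#' @return 8 x 2 matrix of x/y coordinates in mm.
#' @export
station_coords <- function() {
  m <- rbind(c(1250, 500), c(2500, 500), c(3750, 500),
             c(1250, 1500), c(2500, 1500), c(3750, 1500),
             c(400, 1000), c(4600, 1000))
  dimnames(m) <- list(c(paste0("P", 1:6), "F1", "F2"), c("x", "y"))
  m
}

#' Tracking experiment design
#'
#' @param days number of tracking days (full design: 30).
#' @param sample_interval seconds between camera snapshots (default 2).
#' @param day_length_h hours of lights-on per day. The full design is
#'   14.5 h; the desk-scale default of 0.5 h keeps simulations tractable
#'   while preserving per-day statistics.
#' @param detection_prob per-bird per-tick detection probability; missed
#'   detections are simply absent fixes (barcode misreads).
#' @param jitter_mm positional jitter SD around the station coordinate.
#' @return list of class `experiment_design`.
#' @export
experiment_design <- function(days = 30L, sample_interval = 2,
                              day_length_h = 0.5, detection_prob = 0.9,
                              jitter_mm = 30) {
  ds_assert(sample_interval > 0, "sample_interval must be positive")
  ds_assert(days >= 1, "need at least one day")
  structure(list(days = as.integer(days), sample_interval = sample_interval,
                 day_length_h = day_length_h, detection_prob = detection_prob,
                 jitter_mm = jitter_mm,
                 ticks_per_day = max(2L, floor(day_length_h * 3600 / sample_interval))),
            class = "experiment_design")
}

#' Mate-preference model for the tracking simulator
#'
#' All terms are attraction strengths on the station-choice log-scale; with
#' every term 0 the dyad distances are exchangeable across dyads.
#'
#' @param a_cult attraction between opposite-sex birds sharing the rearing
#'   population (the song-imprinting hypothesis).
#' @param a_morph attraction of a female to males whose genetic type matches
#'   her rearing type (imprinting on parental morphotype).
#' @param a_WprefD attraction of wild-origin birds to domesticated-origin
#'   opposite-sex partners.
#' @param a_pair extra mutual attraction within supplied true pairs.
#' @param ramp_days days over which attraction scales linearly from 0 to
#'   full strength.
#' @param baseline_mixing nonnegative weight of uniform station choice mixed
#'   into the preference-driven choice (larger = more random movement).
#' @param stay persistence bonus (log-scale) for remaining at the current
#'   station; not ramped and independent of partner identity, so it leaves
#'   dyad exchangeability intact when all attraction terms are 0. Without
#'   it, two mutually attracted birds chase each other's last position and
#'   never settle.
#' @return list of class `preference_model`.
#' @export
preference_model <- function(a_cult = 0, a_morph = 0, a_WprefD = 0,
                             a_pair = 0, ramp_days = 1L, baseline_mixing = 1,
                             stay = 2) {
  ds_assert(baseline_mixing >= 0, "baseline_mixing must be nonnegative")
  structure(list(a_cult = a_cult, a_morph = a_morph, a_WprefD = a_WprefD,
                 a_pair = a_pair, ramp_days = as.integer(ramp_days),
                 baseline_mixing = baseline_mixing, stay = stay),
            class = "preference_model")
}

# n x n attraction matrix at full strength (row = focal chooser)
attraction_matrix <- function(birds, model, true_pairs = NULL) {
  n <- nrow(birds)
  A <- matrix(0, n, n)
  sex <- birds$sex
  rear <- substr(birds$lineage_code, 2, 2)
  # founders have 1-letter codes: rearing type is the code itself
  rear[nchar(birds$lineage_code) == 1] <- substr(birds$lineage_code[nchar(birds$lineage_code) == 1], 1, 1)
  orig <- substr(birds$lineage_code, 1, 1)
  opp <- outer(sex, sex, "!=")
  if (model$a_cult != 0) {
    A <- A + model$a_cult * (outer(rear, rear, "==") & opp)
  }
  if (model$a_morph != 0) {
    # focal attracted to opposite-sex partners whose genetic type matches the
    # focal's rearing type (mutual imprinting on parental morphotype)
    morph <- outer(rear, orig, "==") & opp
    A <- A + model$a_morph * morph
  }
  if (model$a_WprefD != 0) {
    A <- A + model$a_WprefD * (outer(orig == "W", orig == "D", "&") & opp)
  }
  if (model$a_pair != 0 && !is.null(true_pairs) && nrow(true_pairs) > 0) {
    idx <- match(c(true_pairs$female_id, true_pairs$male_id), birds$bird_id)
    f <- idx[seq_len(nrow(true_pairs))]
    m <- idx[-seq_len(nrow(true_pairs))]
    A[cbind(f, m)] <- A[cbind(f, m)] + model$a_pair
    A[cbind(m, f)] <- A[cbind(m, f)] + model$a_pair
  }
  diag(A) <- 0
  A
}

#' Simulate tracking fixes
#'
#' @param birds `data.table` of birds (needs `bird_id`, `sex`,
#'   `lineage_code`).
#' @param model a [preference_model()].
#' @param true_pairs optional `data.table` with `female_id`, `male_id`
#'   (used by the `a_pair` term).
#' @param design an [experiment_design()].
#' @param seed integer seed; fixes are bit-reproducible.
#' @return `data.table` of fixes: `timestamp` (s since day start),
#'   `day_index`, `bird_id`, `x_mm`, `y_mm`, `station_id`.
#' @export
simulate_tracking <- function(birds, model = preference_model(),
                              true_pairs = NULL, design = experiment_design(),
                              seed = 1L) {
  ds_assert(nrow(birds) > 0, "empty bird list")
  n <- nrow(birds)
  st <- station_coords()
  K <- nrow(st)
  A_full <- attraction_matrix(birds, model, true_pairs)
  wmix <- model$baseline_mixing / (1 + model$baseline_mixing)
  U <- upper.tri(matrix(0, K, K), diag = TRUE) * 1  # cumsum operator
  out <- vector("list", design$days)
  withr::with_seed(seed, {
    s_now <- sample.int(K, n, replace = TRUE)
    for (day in seq_len(design$days)) {
      ramp <- if (model$ramp_days <= 0) 1 else min(1, day / model$ramp_days)
      A <- ramp * A_full
      use_pref <- any(A != 0) || model$stay != 0
      Tn <- design$ticks_per_day
      S <- matrix(0L, Tn, n)
      for (tk in seq_len(Tn)) {
        if (use_pref) {
          Sind <- matrix(0, n, K)
          Sind[cbind(seq_len(n), s_now)] <- 1
          sc <- A %*% Sind + model$stay * Sind
          sc <- sc - apply(sc, 1, max)
          P <- exp(sc)
          P <- P / rowSums(P)
          P <- (1 - wmix) * P + wmix / K
        } else {
          P <- matrix(1 / K, n, K)
        }
        cp <- P %*% U
        u <- runif(n)
        s_new <- 1L + as.integer(rowSums(cp < u))
        # asynchronous relocation: only a random subset moves each tick,
        # otherwise mutually attracted birds swap stations forever
        upd <- runif(n) < 0.5
        s_now[upd] <- s_new[upd]
        S[tk, ] <- s_now
      }
      det <- matrix(runif(Tn * n) < design$detection_prob, Tn, n)
      idx <- which(det)
      tick_i <- ((idx - 1L) %% Tn) + 1L
      bird_i <- ((idx - 1L) %/% Tn) + 1L
      sid <- S[idx]
      nfix <- length(idx)
      out[[day]] <- data.table(
        timestamp = tick_i * design$sample_interval,
        day_index = day,
        bird_id = birds$bird_id[bird_i],
        x_mm = st[sid, 1] + rnorm(nfix, 0, design$jitter_mm),
        y_mm = st[sid, 2] + rnorm(nfix, 0, design$jitter_mm),
        station_id = rownames(st)[sid])
    }
  })
  rbindlist(out)
}

# zero-truncated Poisson sampler (inverse cdf)
rztp <- function(n, lambda) {
  if (n == 0) return(integer(0))
  u <- runif(n, dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate dyadic pair-bonding interaction counts
#'
#' Non-bonded male-female dyads are observed 0 times with probability
#' `zero_prob` and otherwise draw a zero-truncated Poisson
#' (`background_lambda`) count; bonded dyads draw Poisson(`bonded_lambda`)
#' counts truncated to be at least 1.
#'
#' @param birds `data.table` of birds.
#' @param true_pairs `data.table` with `female_id`, `male_id` (the bonded
#'   dyads; may be empty).
#' @param background_lambda,bonded_lambda Poisson means.
#' @param zero_prob probability a non-bonded dyad is never observed.
#' @param seed integer seed.
#' @return `data.table`: `female_id`, `male_id`, `count`, `bonded` (truth).
#' @export
simulate_interactions <- function(birds, true_pairs,
                                  background_lambda = 1.2,
                                  bonded_lambda = 20, zero_prob = 0.85,
                                  seed = 1L) {
  if (bonded_lambda <= background_lambda) {
    warning("bonded_lambda <= background_lambda: pair calling will be unreliable")
  }
  fem <- birds[sex == "F", bird_id]
  mal <- birds[sex == "M", bird_id]
  dy <- CJ(female_id = fem, male_id = mal)
  key <- paste(dy$female_id, dy$male_id)
  bonded <- if (!is.null(true_pairs) && nrow(true_pairs) > 0) {
    key %in% paste(true_pairs$female_id, true_pairs$male_id)
  } else rep(FALSE, nrow(dy))
  withr::with_seed(seed, {
    cnt <- integer(nrow(dy))
    nb <- which(!bonded)
    obs <- nb[runif(length(nb)) >= zero_prob]
    cnt[obs] <- rztp(length(obs), background_lambda)
    bd <- which(bonded)
    cnt[bd] <- pmax(1L, rpois(length(bd), bonded_lambda))
    dy[, `:=`(count = cnt, bonded = bonded)]
  })
  dy[]
}

#' Sample ground-truth pairs under a mating rule
#'
#' Builds a perfect matching between males and females, either uniformly at
#' random or assortatively by rearing (or genetic) population: partners are
#' matched within attribute levels first, leftovers at random.
#'
#' @param birds `data.table` of birds.
#' @param rule `"rearing"`, `"genetic"`, or `"random"`.
#' @param seed integer seed.
#' @return `data.table`: `female_id`, `male_id`.
#' @export
sample_true_pairs <- function(birds, rule = c("rearing", "genetic", "random"),
                              seed = 1L) {
  rule <- match.arg(rule)
  attr_col <- switch(rule, rearing = "rearing_pop", genetic = "genetic_pop",
                     random = NULL)
  withr::with_seed(seed, {
    fem <- birds[sex == "F"]
    mal <- birds[sex == "M"]
    pairs <- list()
    if (is.null(attr_col)) {
      f <- sample(fem$bird_id); m <- sample(mal$bird_id)
      k <- min(length(f), length(m))
      pairs[[1]] <- data.table(female_id = f[seq_len(k)], male_id = m[seq_len(k)])
    } else {
      used_f <- character(0); used_m <- character(0)
      for (lev in unique(fem[[attr_col]])) {
        f <- sample(fem[get(attr_col) == lev, bird_id])
        m <- sample(mal[get(attr_col) == lev, bird_id])
        k <- min(length(f), length(m))
        if (k > 0) {
          pairs[[length(pairs) + 1L]] <- data.table(female_id = f[seq_len(k)],
                                                    male_id = m[seq_len(k)])
          used_f <- c(used_f, f[seq_len(k)]); used_m <- c(used_m, m[seq_len(k)])
        }
      }
      f <- sample(setdiff(fem$bird_id, used_f))
      m <- sample(setdiff(mal$bird_id, used_m))
      k <- min(length(f), length(m))
      if (k > 0) pairs[[length(pairs) + 1L]] <- data.table(female_id = f[seq_len(k)],
                                                           male_id = m[seq_len(k)])
    }
    rbindlist(pairs)
  })
}
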