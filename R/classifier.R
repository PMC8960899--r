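# Two-class dialect classifier. The protocol, not any proprietary model, is
# what is implemented: train on whole recordings of two classes, emit a
# per-1-s-window probability, average window confidences over a 4.5-s trim,
# and always evaluate on individuals absent from training. The model is a
# ridge-regularized logistic discriminant on window features: deterministic
# given the data, probability-calibrated enough for confidence averaging.

DS_LAMBDA <- 0.005  # ridge penalty, frozen after one-off calibration

rec_bird <- function(rec) rec$bird_id %||% NA_character_

stack_window_features <- function(recordings) {
  fl <- lapply(recordings, function(r) extract_windows(r)$features)
  list(x = do.call(rbind, fl), n_windows = vapply(fl, nrow, 0L))
}

#' Train a two-class dialect classifier
#'
#' @param class_a,class_b lists of `song_recording` (>= 2 each).
#' @param labels labels for the two classes (length 2).
#' @param seed integer seed (stored; the fit itself is deterministic).
#' @param lambda ridge penalty.
#' @return object of class `dialect_model`.
#' @export
train_classifier <- function(class_a, class_b, labels = c("A", "B"),
                             seed = 1L, lambda = DS_LAMBDA) {
  ds_assert(length(class_a) >= 2 && length(class_b) >= 2,
            "need at least 2 recordings per class")
  fa <- stack_window_features(class_a)
  fb <- stack_window_features(class_b)
  x <- rbind(fa$x, fb$x)
  y <- c(rep(1L, nrow(fa$x)), rep(0L, nrow(fb$x)))  # 1 = class A
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (all(scl < 1e-12)) {
    warning("all window features identical across classes; fit is degenerate")
  }
  scl[scl < 1e-8] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  model <- structure(list(fit = fit, center = ctr, scale = scl,
                          class_labels = labels,
                          train_birds = unique(c(vapply(class_a, rec_bird, ""),
                                                 vapply(class_b, rec_bird, ""))),
                          n_train = c(length(class_a), length(class_b)),
                          seed = seed, lambda = lambda),
                     class = "dialect_model")
  # internal validation: in-sample recording-level success (non-independent!)
  val <- mean(c(
    vapply(class_a, function(r) classify_recording(model, r, trim = NULL)$label == labels[1], TRUE),
    vapply(class_b, function(r) classify_recording(model, r, trim = NULL)$label == labels[2], TRUE)))
  model$validation_success <- val
  model
}

predict_window_prob <- function(model, features) {
  xs <- scale(features, center = model$center, scale = model$scale)
  as.vector(predict(model$fit, xs, type = "response"))
}

#' Classify one recording by averaged window confidence
#'
#' The recording is trimmed to `trim` seconds (the protocol trims, never
#' pads), per-window class-A probabilities are averaged, and the label is the
#' argmax. The two class confidences are complementary (sum to 1).
#'
#' @param model a `dialect_model`.
#' @param recording a `song_recording`.
#' @param trim trim length in seconds (default 4.5); `NULL` = no trim.
#' @return list with `label`, `confidence` (named, both classes), and
#'   `window_prob`.
#' @export
classify_recording <- function(model, recording, trim = 4.5) {
  sr <- recording$sr %||% DS_SR
  if (!is.null(trim)) {
    need <- round(trim * sr)
    if (length(recording$wave) < need) {
      stop(sprintf("recording is %.2f s but %.2f s are required for trimming",
                   length(recording$wave) / sr, trim), call. = FALSE)
    }
    recording$wave <- recording$wave[seq_len(need)]
  }
  w <- extract_windows(recording)
  p <- predict_window_prob(model, w$features)
  conf_a <- mean(p)
  if (abs(conf_a - 0.5) < 1e-12) {
    warning("confidence tie at exactly 0.5; assigning first class")
  }
  label <- if (conf_a >= 0.5) model$class_labels[1] else model$class_labels[2]
  list(label = label,
       confidence = setNames(c(conf_a, 1 - conf_a), model$class_labels),
       window_prob = p)
}

success_rate <- function(model, recordings, truth, trim = 4.5) {
  pred <- vapply(recordings, function(r) classify_recording(model, r, trim)$label, "")
  mean(pred == truth)
}

#' Pairwise population classification success (training validation vs test)
#'
#' For each population pair, trains on Generation-1 recordings and reports
#' the (non-independent) training validation success together with the
#' independent test success on later-generation individuals. Train and test
#' individuals must be disjoint.
#'
#' @param train_recs,test_recs lists of `song_recording`.
#' @param train_pops,test_pops population label per recording.
#' @param pop_pairs 2-column matrix/list of population pairs; default all
#'   pairwise combinations of the populations present in training.
#' @param trim trim length for test classification.
#' @param seed integer seed.
#' @return `data.table` with one row per pair: `pop_a`, `pop_b`,
#'   `validation_success`, `test_success`, `n_train_a/b`, `n_test_a/b`.
#' @export
population_classification_success <- function(train_recs, train_pops,
                                              test_recs, test_pops,
                                              pop_pairs = NULL, trim = 4.5,
                                              seed = 1L) {
  tb <- vapply(train_recs, rec_bird, "")
  sb <- vapply(test_recs, rec_bird, "")
  overlap <- intersect(tb, sb)
  if (length(overlap) > 0) {
    stop("train and test individuals overlap: ",
         paste(head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  pops <- sort(unique(train_pops))
  if (is.null(pop_pairs)) pop_pairs <- t(utils::combn(pops, 2))
  out <- list()
  for (i in seq_len(nrow(pop_pairs))) {
    pa <- pop_pairs[i, 1]; pb <- pop_pairs[i, 2]
    tr_a <- train_recs[train_pops == pa]; tr_b <- train_recs[train_pops == pb]
    te_a <- test_recs[test_pops == pa]; te_b <- test_recs[test_pops == pb]
    m <- train_classifier(tr_a, tr_b, labels = c(pa, pb),
                          seed = stage_seed(seed, paste(pa, pb)))
    test_succ <- success_rate(m, c(te_a, te_b),
                              c(rep(pa, length(te_a)), rep(pb, length(te_b))),
                              trim = trim)
    out[[i]] <- data.table(pop_a = pa, pop_b = pb,
                           validation_success = m$validation_success,
                           test_success = test_succ,
                           n_train_a = length(tr_a), n_train_b = length(tr_b),
                           n_test_a = length(te_a), n_test_b = length(te_b))
  }
  rbindlist(out)
}

#' Arrange pairwise successes as a matrix (validation below diagonal,
#' independent test above)
#'
#' @param report output of [population_classification_success()].
#' @return square character-labelled numeric matrix.
#' @export
classification_matrix <- function(report) {
  pops <- sort(unique(c(report$pop_a, report$pop_b)))
  M <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_len(nrow(report))) {
    a <- report$pop_a[i]; b <- report$pop_b[i]
    M[b, a] <- report$validation_success[i]  # below diagonal
    M[a, b] <- report$test_success[i]        # above diagonal
  }
  M
}

#' ML similarity scores of candidate males to a female's rearing aviary
#'
#' Trains the classifier to distinguish the songs of a female's tutor set
#' (the aviary's parental males, or her same-generation peer males) from a
#' contrast set of the other population type, then scores each candidate
#' male's recordings by the mean confidence of belonging to the tutor class,
#' averaged over his recordings. Candidates must be absent from training.
#'
#' @param tutor_recs recordings of the tutor set ("same dialect" class).
#' @param contrast_recs recordings of the contrast set ("different" class).
#' @param candidate_recs recordings of candidate males to score.
#' @param trim trim length in seconds.
#' @param seed integer seed.
#' @return `data.table`: `male_id`, `score` in `[0, 1]`,
#'   `n_recordings_averaged`.
#' @export
ml_similarity <- function(tutor_recs, contrast_recs, candidate_recs,
                          trim = 4.5, seed = 1L) {
  ds_assert(length(tutor_recs) > 0, "tutor set is empty")
  ds_assert(length(contrast_recs) > 0, "contrast set is empty")
  tr_birds <- unique(c(vapply(tutor_recs, rec_bird, ""),
                       vapply(contrast_recs, rec_bird, "")))
  cand_birds <- vapply(candidate_recs, rec_bird, "")
  bad <- intersect(unique(cand_birds), tr_birds)
  if (length(bad) > 0) {
    stop("candidate male(s) present in training set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- train_classifier(tutor_recs, contrast_recs, labels = c("same", "diff"),
                        seed = seed)
  sc <- vapply(candidate_recs, function(r) {
    classify_recording(m, r, trim = trim)$confidence[["same"]]
  }, 0)
  dt <- data.table(male_id = cand_birds, score = sc)
  dt[, .(score = mean(score), n_recordings_averaged = .N), by = male_id]
}
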