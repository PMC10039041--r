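# Two-stage decision model: cutoff, routing, integrator, final call.

# Brute-force oracle: best candidate threshold by exhaustive search over
# midpoints of sorted unique scores (plus outside candidates), same tie rule.
brute_cutoff <- function(scores, labels) {
  u <- sort(unique(scores))
  step <- if (length(u) > 1) min(diff(u)) else 1
  cand <- c(u[1] - step / 2,
            if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + step / 2)
  best <- NULL; bd <- Inf; bf <- Inf
  for (t in cand) {
    tpr <- sum(scores > t & labels == 1) / sum(labels == 1)
    fpr <- sum(scores > t & labels == 0) / sum(labels == 0)
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    if (d < bd - 1e-15 || (abs(d - bd) < 1e-15 && fpr < bf - 1e-15)) {
      bd <- d; bf <- fpr; best <- t
    }
  }
  best
}

test_that("choose_cutoff matches the exhaustive-threshold oracle", {
  # worked example: distance ties resolved toward higher specificity
  s <- c(0.1, 0.4, 0.35, 0.8); l <- c(0, 0, 1, 1)
  expect_equal(choose_cutoff(s, l), brute_cutoff(s, l))
  expect_equal(choose_cutoff(s, l), 0.6)

  # perfect separation: the midpoint of the separating gap
  expect_equal(choose_cutoff(c(0.1, 0.2, 0.7, 0.9), c(0, 0, 1, 1)), 0.45)

  # randomized cases, including ties
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    sc <- round(runif(n), sample(c(1, 2), 1))
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(choose_cutoff(sc, lb), brute_cutoff(sc, lb))
  }

  expect_warning(choose_cutoff(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_error(choose_cutoff(c(0.2, 0.4), c(1, 1)), "both classes")
  expect_error(choose_cutoff(c(0.2, 0.4), c(0, 1), split = c("train", "test")),
               "training-split")
})

test_that("positive-signal selection uses the threshold with a top-decile
           fallback", {
  grid <- seq(600, 1800, length.out = 120)
  cfg <- decision_config(presence_cutoff = 0.2,
                         spectrum_positive_threshold = 0.5)
  bag <- make_bag(matrix(seq_len(95 * 120) %% 7 + 1, 95, 120), grid,
                  class = "lung")
  # half high, half low: exactly the high half is selected
  sc <- c(rep(0.9, 48), rep(0.1, 47))
  sel <- sersmil:::positive_spectra(bag, sc, cfg)
  expect_equal(nrow(sel), 48L)
  expect_equal(sel, bag$intensities[1:48, , drop = FALSE])
  # all spectra qualify
  expect_equal(nrow(sersmil:::positive_spectra(bag, rep(1, 95), cfg)), 95L)
  # fallback: none qualify -> ceiling(0.1 * 95) = 10 top scorers
  expect_message(
    sel <- sersmil:::positive_spectra(bag, seq(0.001, 0.4, length.out = 95),
                                      cfg),
    "falling back")
  expect_equal(nrow(sel), 10L)

  # the exported contract form refuses gate-failing bags
  w <- small_world()
  m <- small_presence()
  hc <- w$test[vapply(w$test, function(b) b$true_class, "") == "HC"][[1]]
  high_cfg <- decision_config(presence_cutoff = 0.999)
  expect_error(select_positive_spectra(hc, m, high_cfg),
               "did not pass")
})

test_that("the MLP integrator learns separable score vectors and guards the
           split", {
  # one-hot vectors: recovered exactly
  V <- diag(6)[rep(1:6, each = 8), ]
  ty <- rep(cancer_types(), each = 8)
  integ <- train_integrator(V, ty, seed = 2L)
  pred <- cancer_types()[max.col(sersmil:::integrator_predict(integ, V))]
  expect_equal(pred, ty)

  # noisy vectors (true-type mean 0.8, others 0.3, sd 0.1): held-out > 0.9
  set.seed(6)
  mk <- function(n) {
    t(sapply(rep(1:6, each = n), function(k) {
      v <- rnorm(6, 0.3, 0.1); v[k] <- rnorm(1, 0.8, 0.1); pmin(pmax(v, 0), 1)
    }))
  }
  Vtr <- mk(20); Vte <- mk(10)
  ytr <- rep(cancer_types(), each = 20); yte <- rep(cancer_types(), each = 10)
  integ <- train_integrator(Vtr, ytr, seed = 3L)
  acc <- mean(cancer_types()[max.col(
    sersmil:::integrator_predict(integ, Vte))] == yte)
  expect_gt(acc, 0.9)

  # determinism
  i2 <- train_integrator(Vtr, ytr, seed = 3L)
  expect_identical(sersmil:::integrator_predict(integ, Vte),
                   sersmil:::integrator_predict(i2, Vte))

  # split guard
  expect_error(train_integrator(Vtr, ytr, split = rep("test", nrow(Vtr))),
               "training-split")
  expect_error(train_integrator(V, rep("lung", nrow(V))), "two types")
})

test_that("decide applies a strict gate and routes positives end to end", {
  w <- small_world()
  m <- small_presence()
  too <- small_too()
  cancer_train <- w$train[vapply(w$train, function(b) b$true_class, "") != "HC"]
  dcfg <- decision_config(presence_cutoff = 0.5)
  V <- t(vapply(cancer_train, function(b) {
    s <- score_spectra(m, b$intensities)
    unclass(score_too(too, sersmil:::positive_spectra(b, s, dcfg)))
  }, numeric(6)))
  dcfg$integrator <- train_integrator(
    V, vapply(cancer_train, function(b) b$true_class, ""), seed = 8L)

  # gate: non-cancer iff presence_score <= cutoff, exactly
  hc <- w$test[vapply(w$test, function(b) b$true_class, "") == "HC"][[1]]
  ps <- score_bag(m, hc)
  at_cutoff <- decision_config(presence_cutoff = ps,
                               integrator = dcfg$integrator)
  d <- decide(hc, m, too, at_cutoff)
  expect_false(d$positive)
  expect_equal(d$predicted_class, "non-cancer")
  expect_null(d$too_scores)

  just_below <- decision_config(presence_cutoff = ps - 1e-9,
                                integrator = dcfg$integrator)
  expect_true(decide(hc, m, too, just_below)$positive)

  # strong-effect stomach bag: positive and correctly typed
  st <- w$test[vapply(w$test, function(b) b$true_class, "") == "stomach"][[1]]
  d <- decide(st, m, too, dcfg)
  expect_true(d$positive)
  expect_equal(d$predicted_class, "stomach")
  expect_s3_class(d$too_scores, "too_score_vector")

  # unscorable: all spectra QC-removed
  empty <- sersmil:::subset_bag(hc, rep(FALSE, n_spectra(hc)))
  d0 <- decide(empty, m, too, dcfg)
  expect_equal(d0$status, "unscorable")
  expect_true(is.na(d0$predicted_class))
})
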