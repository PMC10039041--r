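# Integrated two-stage decision model: ROC-optimal presence cutoff, routing
# of positive spectra to the TOO ensemble, MLP integrator over the six scores.

#' Decision configuration
#'
#' @param presence_cutoff Bag-score cutoff; a sample is called positive iff
#'   its mean score strictly exceeds it (a score equal to the cutoff "did not
#'   exceed" it and is non-cancer).
#' @param spectrum_positive_threshold Per-spectrum score level (default 0.5)
#'   above which a spectrum counts as a positive signal for TOO routing.
#' @param integrator A trained [train_integrator()] network, or `NULL`.
#' @param tie_break Deterministic argmax tie-break; only
#'   `"alphabetical"` (lowest type index) is provided.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(presence_cutoff = 0.5,
                            spectrum_positive_threshold = 0.5,
                            integrator = NULL,
                            tie_break = "alphabetical") {
  for (v in c(presence_cutoff, spectrum_positive_threshold))
    if (v < 0 || v > 1) stop("cutoffs must lie in [0, 1]")
  structure(list(presence_cutoff = presence_cutoff,
                 spectrum_positive_threshold = spectrum_positive_threshold,
                 integrator = integrator, tie_break = tie_break),
            class = "decision_config")
}

#' ROC-optimal cutoff: closest point to the ideal corner
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores plus one candidate below the minimum and one above the maximum; the
#' returned threshold minimizes the Euclidean distance of its operating point
#' (FPR, TPR) to (0, 1), with ties broken toward higher specificity (lower
#' FPR) and then toward the lower threshold value. Positivity is strict:
#' score > cutoff.
#'
#' @param bag_scores Numeric sample-level scores.
#' @param labels Binary truth (0 control / 1 cancer), both classes present.
#' @param split Optional split labels; any `"test"` entry is refused so the
#'   cutoff can never be tuned on held-out data.
#' @return The chosen scalar threshold.
#' @export
choose_cutoff <- function(bag_scores, labels, split = NULL) {
  if (!is.null(split) && any(split == "test"))
    stop("choose_cutoff accepts training-split scores only")
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be represented")
  u <- sort(unique(bag_scores))
  if (length(u) == 1L) {
    warning("degenerate scores: all samples share one value")
    return(u)
  }
  gaps <- (u[-1] + u[-length(u)]) / 2
  step <- min(diff(u))
  cand <- c(u[1] - step / 2, gaps, u[length(u)] + step / 2)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tp <- vapply(cand, function(t) sum(bag_scores > t & labels == 1), 0)
  fp <- vapply(cand, function(t) sum(bag_scores > t & labels == 0), 0)
  # squared corner distance scaled by (n_pos * n_neg)^2: exact integer
  # arithmetic, so mathematically tied operating points are tied here too
  d2 <- (fp * n_pos)^2 + ((n_pos - tp) * n_neg)^2
  best <- which(d2 == min(d2))
  best <- best[fp[best] == min(fp[best])]
  cand[min(best)]
}

#' Select the positive signals of a gate-passing bag
#'
#' Spectra with per-spectrum presence score `>= spectrum_positive_threshold`.
#' If none qualify (a gate-passing bag whose individual spectra all sit below
#' the level), falls back to the top-scoring 10 % (`ceiling(0.1 n)`) with a
#' message.
#'
#' @param bag A preprocessed `sample_bag` whose bag score exceeds the cutoff.
#' @param presence_model Trained presence scorer.
#' @param cfg A [decision_config()].
#' @return Intensity matrix of the selected spectra.
#' @export
select_positive_spectra <- function(bag, presence_model, cfg) {
  s <- score_spectra(presence_model, bag$intensities)
  if (mean(s) <= cfg$presence_cutoff)
    stop("contract violation: bag did not pass the presence gate")
  positive_spectra(bag, s, cfg)
}

# Shared selection used both by decide() and by TOO evaluation of
# gate-negative cancer bags (where the gate contract does not apply).
positive_spectra <- function(bag, scores, cfg) {
  sel <- which(scores >= cfg$spectrum_positive_threshold)
  if (!length(sel)) {
    k <- ceiling(0.1 * length(scores))
    sel <- order(scores, decreasing = TRUE)[seq_len(k)]
    message("no spectrum reached the positive level; ",
            "falling back to the top ", k, " spectra")
  }
  bag$intensities[sel, , drop = FALSE]
}

#' Train the MLP integrator over TOO score vectors
#'
#' A small feed-forward network (one hidden layer, softmax output over the
#' six types) that turns a six-entry TOO score vector into a single class
#' call, absorbing the prediction error that makes several one-vs-rest models
#' fire at once. Trained exclusively on training-split vectors.
#'
#' @param train_too_vectors Matrix (samples x 6, columns in
#'   [cancer_types()] order) or list of `too_score_vector`s; an optional
#'   `split` attribute (or `split` argument) is checked and any test-split
#'   vector is refused.
#' @param true_types Character vector of true cancer types.
#' @param seed Training seed.
#' @param hidden Hidden-layer width (default 16).
#' @param split Optional split labels parallel to the vectors.
#' @return A `too_integrator`.
#' @export
train_integrator <- function(train_too_vectors, true_types, seed = 0L,
                             hidden = 16L, split = NULL) {
  if (is.list(train_too_vectors) && !is.data.frame(train_too_vectors))
    train_too_vectors <- do.call(rbind, lapply(train_too_vectors, unclass))
  V <- as.matrix(train_too_vectors)
  if (ncol(V) != 6L) stop("TOO vectors must have six entries")
  if (is.null(split)) split <- attr(train_too_vectors, "split")
  if (!is.null(split) && any(split == "test"))
    stop("train_integrator accepts training-split vectors only")
  y <- match(true_types, cancer_types())
  if (any(is.na(y))) stop("unknown cancer type in true_types")
  if (length(unique(y)) < 2L) stop("need at least two types to integrate")
  # Standardize the six scores on the training set: one-vs-rest outputs can
  # sit on a compressed scale, and the class information lives in their
  # relative pattern.
  mu <- colMeans(V)
  sg <- pmax(apply(V, 2L, sd), 1e-6)
  Vz <- sweep(sweep(V, 2L, mu), 2L, sg, "/")
  net <- nn_build(list(), n_channels = 6L, fcl_size = hidden,
                  dropout_rate = 0, n_out = 6L, output = "softmax",
                  seed = seed)
  res <- nn_train(net, Vz, y, epochs = 300L, batch_size = 32L, lr = 0.01,
                  validation_fraction = 0.15, seed = seed)
  structure(list(net = res$net, history = res$history, center = mu,
                 scale = sg),
            class = "too_integrator")
}

# Class probabilities for TOO score vectors.
integrator_predict <- function(integrator, V) {
  V <- matrix(as.numeric(V), ncol = 6L)
  Vz <- sweep(sweep(V, 2L, integrator$center), 2L, integrator$scale, "/")
  nn_predict(integrator$net, Vz)
}

#' Final two-stage decision for one sample
#'
#' Stage 1: the bag's mean presence score against the cutoff (strictly
#' greater to be positive). Stage 2, positives only: TOO score vector over
#' the selected positive spectra; predicted class is the integrator's argmax,
#' ties broken toward the alphabetically first type.
#'
#' @param bag Preprocessed `sample_bag` (possibly empty after QC).
#' @param presence_model Trained presence scorer.
#' @param too_models A `too_ensemble`.
#' @param cfg A [decision_config()] with a trained integrator.
#' @return A `decision_result`: `sample_id`, `presence_score`, `positive`,
#'   `too_scores` (or `NULL`), `predicted_class`
#'   (`"non-cancer"` or a cancer type), `status` (`"ok"`/`"unscorable"`).
#' @export
decide <- function(bag, presence_model, too_models, cfg) {
  if (n_spectra(bag) == 0L) {
    return(structure(list(sample_id = bag$sample_id, presence_score = NA_real_,
                          positive = NA, too_scores = NULL,
                          predicted_class = NA_character_,
                          status = "unscorable"),
                     class = "decision_result"))
  }
  s <- score_spectra(presence_model, bag$intensities)
  presence <- mean(s)
  if (presence <= cfg$presence_cutoff) {
    return(structure(list(sample_id = bag$sample_id,
                          presence_score = presence, positive = FALSE,
                          too_scores = NULL, predicted_class = "non-cancer",
                          status = "ok"),
                     class = "decision_result"))
  }
  pos <- positive_spectra(bag, s, cfg)
  ts <- score_too(too_models, pos)
  p <- integrator_predict(cfg$integrator, unclass(ts))[1L, ]
  best <- which(p == max(p))           # ties -> lowest (alphabetical) index
  structure(list(sample_id = bag$sample_id, presence_score = presence,
                 positive = TRUE, too_scores = ts,
                 predicted_class = cancer_types()[min(best)],
                 status = "ok"),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat(sprintf("<decision_result> %s: score %.3f -> %s (%s)\n", x$sample_id,
              x$presence_score, x$predicted_class, x$status))
  invisible(x)
}
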