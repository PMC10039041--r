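# One-vs-rest tissue-of-origin ensemble: six binary scorers, each separating
# one cancer type from the remaining cancer types.

#' Train the one-vs-rest tissue-of-origin ensemble
#'
#' Six binary scorers over cancer bags only: scorer k sees label 1 for
#' type-k spectra and 0 for every other cancer type's spectra (controls are
#' handled upstream by the presence gate, so they are not training negatives).
#'
#' @param train_bags Preprocessed cancer `sample_bag`s covering all six types.
#' @param arch An [arch_config()]; the same family as the presence model.
#' @param tcfg A [train_config()]; all six scorers share `tcfg$seed` (and
#'   initial weights), which makes training equivariant under permutations
#'   of the type labels.
#' @return Named list of `presence_model` scorers, class `too_ensemble`.
#' @export
train_one_vs_rest <- function(train_bags, arch = arch_config(),
                              tcfg = train_config()) {
  cls <- vapply(train_bags, `[[`, "", "true_class")
  if (any(cls == "HC"))
    stop("tissue-of-origin training takes cancer bags only")
  missing <- setdiff(cancer_types(), unique(cls))
  if (length(missing))
    stop("absent cancer classes: ", paste(missing, collapse = ", "))
  st <- stack_bags(train_bags)
  models <- list()
  for (k in seq_along(cancer_types())) {
    type <- cancer_types()[k]
    y <- as.numeric(st$class == type)
    w <- if (tcfg$class_weighting == "inverse_frequency") {
      tab <- table(y)
      as.numeric(length(y) / (2 * tab[as.character(y)]))
    } else rep(1, length(y))
    m <- build_presence_classifier(arch, ncol(st$X), seed = tcfg$seed)
    res <- nn_train(m$net, st$X, y, epochs = tcfg$epochs,
                    batch_size = tcfg$batch_size, lr = tcfg$learning_rate,
                    validation_fraction = tcfg$validation_fraction,
                    weights = w, seed = tcfg$seed)
    m$net <- res$net; m$history <- res$history; m$trained <- TRUE
    models[[type]] <- m
  }
  structure(models, class = "too_ensemble")
}

#' Tissue-of-origin score vector
#'
#' For each cancer type, the mean of that type's scorer over the supplied
#' positive spectra -- the per-sample six-entry score vector fed to the
#' decision integrator.
#'
#' @param models A `too_ensemble`.
#' @param positive_spectra Non-empty spectra (matrix or list) routed from the
#'   presence step.
#' @return A `too_score_vector`: named numeric of length 6 with attribute
#'   `n_spectra_used`.
#' @export
score_too <- function(models, positive_spectra) {
  X <- spectra_matrix(positive_spectra)
  if (nrow(X) == 0L)
    stop("no positive spectra to route to the tissue-of-origin ensemble")
  scores <- vapply(cancer_types(), function(type)
    mean(score_spectra(models[[type]], X)), 0)
  structure(scores, n_spectra_used = nrow(X), class = "too_score_vector")
}

#' @export
print.too_score_vector <- function(x, ...) {
  cat("<too_score_vector> over", attr(x, "n_spectra_used"), "spectra\n")
  print(round(unclass(x), 3))
  invisible(x)
}
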