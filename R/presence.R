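# MIL cancer-presence classifier: per-spectrum 1-D CNN scoring with
# bag-inherited labels; the bag diagnosis is the mean per-spectrum score.

#' Architecture configuration for the spectrum scorers
#'
#' Defaults are a compact member of the family supported by the structural
#' sweep findings (first-layer kernel below ~10 channels, later kernels ~5,
#' dropout under 0.5, fully-connected size insensitive), sized to train in
#' minutes on one CPU.
#'
#' @param conv_blocks List of blocks, each `list(filters, kernel, pool)`.
#' @param dropout_rate Dropout before the fully-connected layer, in `[0, 1)`.
#' @param fcl_size Hidden units of the fully-connected layer.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(conv_blocks = list(
                          list(filters = 8L, kernel = 9L, pool = 3L),
                          list(filters = 16L, kernel = 5L, pool = 3L),
                          list(filters = 16L, kernel = 5L, pool = 3L)),
                        dropout_rate = 0.3, fcl_size = 32L) {
  if (!length(conv_blocks)) stop("need at least one convolution block")
  for (b in conv_blocks) {
    if (!all(c("filters", "kernel", "pool") %in% names(b)))
      stop("each conv block needs filters, kernel, pool")
    if (b$kernel < 1L || b$filters < 1L || b$pool < 1L)
      stop("conv block sizes must be >= 1")
  }
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  structure(list(conv_blocks = conv_blocks, dropout_rate = dropout_rate,
                 fcl_size = as.integer(fcl_size)),
            class = "arch_config")
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param validation_fraction Fraction of training spectra held out
#'   (stratified by label) to monitor overfitting; default 0.2.
#' @param class_weighting `"inverse_frequency"` (default; balances the
#'   control/patient imbalance) or `"none"`.
#' @param seed Seed controlling shuffling, dropout and the validation split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 8L, batch_size = 128L,
                         learning_rate = 1e-3, validation_fraction = 0.2,
                         class_weighting = c("inverse_frequency", "none"),
                         seed = 0L) {
  class_weighting <- match.arg(class_weighting)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 class_weighting = class_weighting,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained presence classifier
#'
#' A serial 1-D convolutional network ending in a single sigmoid unit, so
#' every per-spectrum score lies in `[0, 1]`.
#'
#' @param arch An [arch_config()].
#' @param n_channels Number of wavenumber channels the model accepts.
#' @param seed Weight-initialization seed.
#' @return An object of class `presence_model`.
#' @export
build_presence_classifier <- function(arch = arch_config(), n_channels,
                                      seed = 0L) {
  net <- nn_build(arch$conv_blocks, n_channels, arch$fcl_size,
                  arch$dropout_rate, n_out = 1L, output = "sigmoid",
                  seed = seed)
  structure(list(net = net, arch = arch, n_channels = as.integer(n_channels),
                 trained = FALSE, history = NULL),
            class = "presence_model")
}

# Stack retained spectra of several bags into (X, bag labels, bag index).
stack_bags <- function(bags) {
  X <- do.call(rbind, lapply(bags, `[[`, "intensities"))
  cls <- rep(vapply(bags, `[[`, "", "true_class"),
             vapply(bags, n_spectra, 0L))
  list(X = X, class = cls,
       bag_index = rep(seq_along(bags), vapply(bags, n_spectra, 0L)))
}

#' Train the MIL presence classifier
#'
#' Every spectrum inherits its bag's binary label (0 control, 1 cancer), the
#' multiple-instance assumption; a stratified `validation_fraction` of spectra
#' monitors overfitting; per-epoch accuracies are recorded in `$history`.
#'
#' @param model An untrained [build_presence_classifier()] result.
#' @param train_bags Preprocessed `sample_bag` list containing both classes.
#' @param tcfg A [train_config()].
#' @return The trained `presence_model`.
#' @export
train_presence <- function(model, train_bags, tcfg = train_config()) {
  st <- stack_bags(train_bags)
  y <- as.numeric(st$class != "HC")
  if (length(unique(y)) < 2L)
    stop("training bags must include both control and cancer samples")
  if (ncol(st$X) != model$n_channels)
    stop("channel mismatch between bags and model")
  w <- if (tcfg$class_weighting == "inverse_frequency") {
    tab <- table(y)
    as.numeric(length(y) / (2 * tab[as.character(y)]))
  } else rep(1, length(y))
  res <- nn_train(model$net, st$X, y, epochs = tcfg$epochs,
                  batch_size = tcfg$batch_size, lr = tcfg$learning_rate,
                  validation_fraction = tcfg$validation_fraction,
                  weights = w, seed = tcfg$seed)
  model$net <- res$net
  model$history <- res$history
  model$trained <- TRUE
  model
}

#' Score spectra with a trained scorer
#'
#' One deterministic score in `[0, 1]` per spectrum, order preserved.
#'
#' @param model A `presence_model`, `dummy_scorer` or `svm_scorer`.
#' @param spectra Intensity matrix (spectra x channels), list of
#'   [raman_spectrum()], or a single spectrum.
#' @return Numeric vector of scores.
#' @export
score_spectra <- function(model, spectra) UseMethod("score_spectra")

#' @export
score_spectra.presence_model <- function(model, spectra) {
  X <- spectra_matrix(spectra)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != model$n_channels)
    stop("channel mismatch: model expects ", model$n_channels, " channels")
  nn_predict(model$net, X)
}

#' Bag-level diagnostic score
#'
#' The arithmetic mean of the per-spectrum scores over a bag's retained
#' spectra -- the MIL aggregation that yields the sample's diagnostic score.
#'
#' @param model A trained scorer.
#' @param bag A quality-controlled `sample_bag`.
#' @return Scalar in `[0, 1]`.
#' @export
score_bag <- function(model, bag) {
  if (n_spectra(bag) == 0L)
    stop("unscorable sample: no spectra left after quality control")
  mean(score_spectra(model, bag$intensities))
}

# baselines -------------------------------------------------------------------

#' Reference baseline scorers
#'
#' `"dummy"` ignores its input and scores every spectrum with the training
#' prevalence; `"svm"` is a linear max-margin classifier (Pegasos subgradient
#' training) with a logistic calibration mapping margins into `[0, 1]`.
#'
#' @param kind `"dummy"` or `"svm"`.
#' @param train_bags Preprocessed training bags (both classes).
#' @param seed Seed for the SVM's stochastic subgradient updates.
#' @return A scorer usable with [score_spectra()] / [score_bag()].
#' @export
train_baseline <- function(kind = c("dummy", "svm"), train_bags, seed = 0L) {
  kind <- match.arg(kind)
  st <- stack_bags(train_bags)
  y <- as.numeric(st$class != "HC")
  if (length(unique(y)) < 2L)
    stop("training bags must include both control and cancer samples")
  if (kind == "dummy") {
    return(structure(list(prevalence = mean(y),
                          n_channels = ncol(st$X)),
                     class = "dummy_scorer"))
  }
  set.seed(seed)
  X <- st$X; n <- nrow(X); d <- ncol(X)
  ys <- 2 * y - 1
  lambda <- 1e-4
  w <- numeric(d); b <- 0; t <- 0
  for (ep in 1:5) for (i in sample.int(n)) {
    t <- t + 1
    eta <- 1 / (lambda * t)
    margin <- ys[i] * (sum(X[i, ] * w) + b)
    w <- (1 - eta * lambda) * w
    if (margin < 1) {
      w <- w + eta * ys[i] * X[i, ]
      b <- b + eta * ys[i]
    }
  }
  m <- as.numeric(X %*% w + b)
  cal <- suppressWarnings(glm(y ~ m, family = binomial()))
  structure(list(w = w, b = b, calibration = coef(cal), n_channels = d),
            class = "svm_scorer")
}

#' @export
score_spectra.dummy_scorer <- function(model, spectra) {
  X <- spectra_matrix(spectra)
  rep(model$prevalence, nrow(X))
}

#' @export
score_spectra.svm_scorer <- function(model, spectra) {
  X <- spectra_matrix(spectra)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != model$n_channels) stop("channel mismatch")
  m <- as.numeric(X %*% model$w + model$b)
  plogis(model$calibration[1L] + model$calibration[2L] * m)
}

# ablation --------------------------------------------------------------------

#' Remove one architecture component
#'
#' Returns the architecture minus the named component, for ablation sweeps.
#' Components: `"conv1"`, `"conv2"`, ... (convolution blocks, first = input
#' side), `"dropout"`, `"fcl"`. The output unit cannot be removed and at
#' least one convolution block must remain.
#'
#' @param arch An [arch_config()].
#' @param removal Component id.
#' @return The reduced `arch_config`.
#' @export
ablate <- function(arch, removal) {
  if (removal == "output") stop("the output unit cannot be removed")
  if (removal == "dropout") {
    arch$dropout_rate <- 0
    return(arch)
  }
  if (removal == "fcl") {
    arch$fcl_size <- 0L
    return(arch)
  }
  m <- regmatches(removal, regexec("^conv([0-9]+)$", removal))[[1L]]
  if (length(m) == 2L) {
    i <- as.integer(m[2L])
    if (i < 1L || i > length(arch$conv_blocks))
      stop("no such convolution block: ", removal)
    if (length(arch$conv_blocks) == 1L)
      stop("at least one convolution block must remain")
    arch$conv_blocks[[i]] <- NULL
    return(arch)
  }
  stop("unknown component: ", removal)
}
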