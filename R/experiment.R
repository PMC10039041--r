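# Seeded end-to-end experiment runner: generate -> preprocess -> train
# (presence, TOO, integrator) on the training split -> evaluate on the
# untouched test split; plus learning-curve and ablation sweeps.

#' Experiment configuration
#'
#' One config object fully determines an end-to-end run. All stage seeds are
#' derived from `seed`. The default is the desk-scale cohort: 30 training and
#' 30 test bags per class, 100 spectra per bag, 900 channels.
#'
#' @param cohort A [cohort_config()]; its `n_per_class` are the *total*
#'   (train + test) bag counts and its `seed` is overwritten from `seed`.
#' @param split Named integer vector: training bags per class; must not
#'   exceed the cohort counts.
#' @param preprocess A [preprocess_config()].
#' @param arch An [arch_config()].
#' @param train A [train_config()] for the presence model.
#' @param too_train Optional [train_config()] for the one-vs-rest scorers
#'   (default: `train` with half the epochs, floor 3 -- they converge faster
#'   on the cancer-only subproblem).
#' @param spectrum_positive_threshold Per-spectrum routing level, see
#'   [decision_config()].
#' @param n_boot Bootstrap resamples for the report's AUC interval.
#' @param output_dir If non-`NULL`, report and tables are written there.
#' @param seed Mandatory integer master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(
                                n_per_class = stats::setNames(
                                  rep(60L, 7L), all_classes())),
                              split = stats::setNames(rep(30L, 7L),
                                                      all_classes()),
                              preprocess = preprocess_config(),
                              arch = arch_config(),
                              train = train_config(),
                              too_train = NULL,
                              spectrum_positive_threshold = 0.5,
                              n_boot = 200L,
                              output_dir = NULL,
                              seed = 1L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (!all(names(split) %in% names(cohort$n_per_class)))
    stop("split names must match cohort classes")
  if (any(split > cohort$n_per_class[names(split)]))
    stop("split counts exceed cohort counts")
  cohort$seed <- as.integer(seed)
  if (is.null(too_train)) {
    too_train <- train
    too_train$epochs <- max(3L, train$epochs %/% 2L)
  }
  structure(list(cohort = cohort, split = split, preprocess = preprocess,
                 arch = arch, train = train, too_train = too_train,
                 spectrum_positive_threshold = spectrum_positive_threshold,
                 n_boot = as.integer(n_boot), output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

assign_splits <- function(bags, split, seed) {
  set.seed(seed + 7L)
  cls <- vapply(bags, `[[`, "", "true_class")
  for (cl in unique(cls)) {
    ix <- which(cls == cl)
    n_train <- if (cl %in% names(split)) split[[cl]] else 0L
    tr <- sample(ix, min(n_train, length(ix)))
    for (i in ix) bags[[i]]$split <- if (i %in% tr) "train" else "test"
  }
  bags
}

bag_field <- function(bags, f) vapply(bags, `[[`, "", f)

#' Run a full end-to-end experiment
#'
#' Strict split hygiene: the QC threshold, the presence cutoff and the
#' integrator are fitted on the training split only (audited; overlap
#' aborts). Rerunning with an identical config reproduces the report.
#'
#' @param cfg An [experiment_config()].
#' @return List with `report` (metrics), `decisions`, `confusion`, `cutoff`,
#'   `qc_threshold`, `models`, `qc`, and the `config` echo.
#' @export
run_experiment <- function(cfg) {
  bags <- generate_cohort(cfg$cohort)
  bags <- assign_splits(bags, cfg$split, cfg$seed)
  pp <- preprocess_cohort(bags, cfg$preprocess)
  bags <- pp$bags
  is_train <- bag_field(bags, "split") == "train"
  train_bags <- bags[is_train]
  test_bags <- bags[!is_train]
  if (length(intersect(bag_field(train_bags, "sample_id"),
                       bag_field(test_bags, "sample_id"))))
    stop("split overlap detected; aborting")

  # Stage 1: presence model + ROC-optimal cutoff on training bags.
  tcfg <- cfg$train; tcfg$seed <- cfg$seed + 1L
  presence <- build_presence_classifier(cfg$arch,
                                        n_channels = cfg$cohort$grid[3],
                                        seed = cfg$seed + 1L)
  presence <- train_presence(presence, train_bags, tcfg)
  train_scores <- vapply(train_bags, function(b) score_bag(presence, b), 0)
  train_labels <- as.numeric(bag_field(train_bags, "true_class") != "HC")
  cutoff <- choose_cutoff(train_scores, train_labels,
                          split = bag_field(train_bags, "split"))

  # Stage 2: one-vs-rest TOO ensemble + MLP integrator, training split only.
  ttcfg <- cfg$too_train; ttcfg$seed <- cfg$seed + 10L
  train_cancer <- train_bags[bag_field(train_bags, "true_class") != "HC"]
  too <- train_one_vs_rest(train_cancer, cfg$arch, ttcfg)
  dcfg <- decision_config(presence_cutoff = cutoff,
                          spectrum_positive_threshold =
                            cfg$spectrum_positive_threshold)
  train_vecs <- t(vapply(train_cancer, function(b) {
    s <- score_spectra(presence, b$intensities)
    unclass(score_too(too, positive_spectra(b, s, dcfg)))
  }, numeric(6L)))
  dcfg$integrator <- train_integrator(
    train_vecs, bag_field(train_cancer, "true_class"),
    seed = cfg$seed + 20L, split = bag_field(train_cancer, "split"))

  # Evaluation on the untouched test split.
  decisions <- lapply(test_bags, decide, presence_model = presence,
                      too_models = too, cfg = dcfg)
  test_cls <- bag_field(test_bags, "true_class")
  test_labels <- as.numeric(test_cls != "HC")
  test_scores <- vapply(decisions, `[[`, 0, "presence_score")
  roc <- roc_auc(test_scores, test_labels)
  op <- operating_points(test_scores, test_labels)
  pr <- pr_metrics(test_scores, test_labels)
  auc_ci <- bootstrap_ci(test_scores, test_labels, "auc",
                         n_boot = max(100L, cfg$n_boot),
                         seed = cfg$seed + 30L)
  pred_pos <- vapply(decisions, `[[`, TRUE, "positive")
  sens <- sum(pred_pos & test_labels == 1) / sum(test_labels == 1)
  spec <- sum(!pred_pos & test_labels == 0) / sum(test_labels == 0)
  # Per-type presence AUC (type bags vs all HC bags).
  per_type_auc <- sapply(cancer_types(), function(ty) {
    sel <- test_cls %in% c("HC", ty)
    if (length(unique(test_labels[sel])) < 2L) return(NA_real_)
    roc_auc(test_scores[sel], test_labels[sel])$auc
  })
  # One-vs-rest TOO AUCs over test cancer bags (routed positive spectra; the
  # same selection decide() uses, applied regardless of the gate so that
  # gate-negative cancer bags still contribute a score).
  cancer_ix <- which(test_labels == 1)
  test_vecs <- t(vapply(test_bags[cancer_ix], function(b) {
    s <- score_spectra(presence, b$intensities)
    unclass(score_too(too, positive_spectra(b, s, dcfg)))
  }, numeric(6L)))
  too_auc <- sapply(cancer_types(), function(ty) {
    y <- as.numeric(test_cls[cancer_ix] == ty)
    if (length(unique(y)) < 2L) return(NA_real_)
    roc_auc(test_vecs[, ty], y)$auc
  })
  # Integrated TOO accuracy among gate-positive cancer bags.
  tp_ix <- which(test_labels == 1 & pred_pos)
  too_acc <- if (length(tp_ix))
    mean(vapply(decisions[tp_ix], `[[`, "", "predicted_class") ==
           test_cls[tp_ix]) else NA_real_
  truth <- stats::setNames(test_cls, bag_field(test_bags, "sample_id"))
  conf <- confusion_matrix(decisions, truth)
  # Stage subgroups.
  stage <- bag_field(test_bags, "stage")
  subgroup <- lapply(c(early = "early", advanced = "advanced"), function(sg) {
    ix <- which(stage == sg)
    if (!length(ix)) return(NULL)
    ok_too <- which(stage == sg & pred_pos & test_labels == 1)
    list(sensitivity = mean(pred_pos[ix]),
         too_accuracy = if (length(ok_too))
           mean(vapply(decisions[ok_too], `[[`, "", "predicted_class") ==
                  test_cls[ok_too]) else NA_real_)
  })
  qc <- list(
    n_input = sum(vapply(pp$reports, `[[`, 0, "n_input")),
    n_removed_anomalous = sum(vapply(pp$reports, `[[`, 0,
                                     "n_removed_anomalous")),
    n_despiked = sum(vapply(pp$reports, `[[`, 0, "n_despiked")),
    threshold = pp$threshold)
  report <- list(
    n_train = length(train_bags), n_test = length(test_bags),
    cutoff = cutoff,
    presence = list(auc = roc$auc, auc_ci = auc_ci,
                    sensitivity = sens, specificity = spec,
                    optimal = op$optimal, sens_at_99spec = op$sens_at_spec,
                    spec_at_99sens = op$spec_at_sens,
                    auprc = pr$auprc, f1 = pr$f1,
                    per_type_auc = as.list(per_type_auc)),
    too = list(one_vs_rest_auc = as.list(too_auc), mean_auc = mean(too_auc),
               integrated_accuracy = too_acc),
    subgroup = subgroup,
    qc = qc, seed = cfg$seed)
  out <- list(report = report, decisions = decisions, confusion = conf,
              cutoff = cutoff, qc_threshold = pp$threshold,
              models = list(presence = presence, too = too,
                            integrator = dcfg$integrator),
              test_scores = test_scores, test_labels = test_labels,
              qc = qc, config = cfg)
  if (!is.null(cfg$output_dir)) write_experiment(out, cfg$output_dir)
  out
}

write_experiment <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dec <- data.frame(
    sample_id = vapply(out$decisions, `[[`, "", "sample_id"),
    presence_score = vapply(out$decisions, `[[`, 0, "presence_score"),
    positive = vapply(out$decisions, `[[`, TRUE, "positive"),
    predicted_class = vapply(out$decisions, `[[`, "", "predicted_class"),
    status = vapply(out$decisions, `[[`, "", "status"))
  write.csv(dec, file.path(dir, "decisions.csv"), row.names = FALSE)
  write.csv(as.data.frame(out$confusion),
            file.path(dir, "confusion_matrix.csv"))
  write.csv(out$models$presence$history,
            file.path(dir, "presence_history.csv"), row.names = FALSE)
  invisible(dir)
}

#' Learning curve over training-set size
#'
#' Retrains the presence stage with increasing numbers of training bags per
#' class and reports held-out bag-level accuracy (at each run's own
#' ROC-optimal cutoff) and AUC on the fixed test split.
#'
#' @param cfg An [experiment_config()].
#' @param sizes Integer vector of per-class training bag counts.
#' @return Data frame `size`, `accuracy`, `auc`.
#' @export
learning_curve <- function(cfg, sizes) {
  if (any(sizes > min(cfg$split)))
    stop("requested size exceeds the available training bags per class")
  bags <- generate_cohort(cfg$cohort)
  bags <- assign_splits(bags, cfg$split, cfg$seed)
  pp <- preprocess_cohort(bags, cfg$preprocess)
  bags <- pp$bags
  cls <- bag_field(bags, "true_class")
  is_train <- bag_field(bags, "split") == "train"
  test_bags <- bags[!is_train]
  test_labels <- as.numeric(bag_field(test_bags, "true_class") != "HC")
  res <- lapply(sizes, function(sz) {
    sub <- unlist(lapply(unique(cls), function(cl) {
      ix <- which(is_train & cls == cl)
      head(ix, sz)
    }))
    tcfg <- cfg$train; tcfg$seed <- cfg$seed + 1L
    m <- build_presence_classifier(cfg$arch, cfg$cohort$grid[3],
                                   seed = cfg$seed + 1L)
    m <- train_presence(m, bags[sub], tcfg)
    tr_scores <- vapply(bags[sub], function(b) score_bag(m, b), 0)
    tr_labels <- as.numeric(cls[sub] != "HC")
    cut <- choose_cutoff(tr_scores, tr_labels)
    te_scores <- vapply(test_bags, function(b) score_bag(m, b), 0)
    data.frame(size = sz,
               accuracy = mean((te_scores > cut) == test_labels),
               auc = roc_auc(te_scores, test_labels)$auc)
  })
  do.call(rbind, res)
}

#' Ablation sweep over architecture components
#'
#' Retrains the presence stage with one component removed at a time and
#' tabulates held-out bag AUC and accuracy against the full model.
#'
#' @param cfg An [experiment_config()].
#' @param removals Component ids accepted by [ablate()].
#' @return Data frame `component`, `accuracy`, `auc` (first row `"full"`).
#' @export
ablation_sweep <- function(cfg, removals = c("conv1", "conv2", "conv3",
                                             "dropout", "fcl")) {
  bags <- generate_cohort(cfg$cohort)
  bags <- assign_splits(bags, cfg$split, cfg$seed)
  pp <- preprocess_cohort(bags, cfg$preprocess)
  bags <- pp$bags
  is_train <- bag_field(bags, "split") == "train"
  train_bags <- bags[is_train]
  test_bags <- bags[!is_train]
  test_labels <- as.numeric(bag_field(test_bags, "true_class") != "HC")
  eval_arch <- function(arch, label) {
    tcfg <- cfg$train; tcfg$seed <- cfg$seed + 1L
    m <- build_presence_classifier(arch, cfg$cohort$grid[3],
                                   seed = cfg$seed + 1L)
    m <- train_presence(m, train_bags, tcfg)
    tr <- vapply(train_bags, function(b) score_bag(m, b), 0)
    cut <- choose_cutoff(tr, as.numeric(bag_field(train_bags,
                                                  "true_class") != "HC"))
    te <- vapply(test_bags, function(b) score_bag(m, b), 0)
    data.frame(component = label,
               accuracy = mean((te > cut) == test_labels),
               auc = roc_auc(te, test_labels)$auc)
  }
  out <- list(eval_arch(cfg$arch, "full"))
  for (r in removals)
    out[[length(out) + 1L]] <- eval_arch(ablate(cfg$arch, r), r)
  do.call(rbind, out)
}
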