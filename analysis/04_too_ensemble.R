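# Train the one-vs-rest tissue-of-origin ensemble and its MLP integrator on
# the training split; evaluate per-type discrimination on the test split.
#
# Output: results/too_metrics.csv.

source("analysis/00_config.R")

pp <- readRDS(cache_path("cohort_preprocessed"))
pres <- readRDS(cache_path("presence"))
split <- vapply(pp$bags, function(b) b$split, "")
cls <- vapply(pp$bags, function(b) b$true_class, "")
train_cancer <- pp$bags[split == "train" & cls != "HC"]
test_cancer <- pp$bags[split == "test" & cls != "HC"]

ttcfg <- cfg$too_train; ttcfg$seed <- cfg$seed + 10L
too <- train_one_vs_rest(train_cancer, cfg$arch, ttcfg)

dcfg <- decision_config(presence_cutoff = pres$cutoff,
                        spectrum_positive_threshold =
                          cfg$spectrum_positive_threshold)
vec_for <- function(b) {
  s <- score_spectra(pres$model, b$intensities)
  unclass(score_too(too, sersmil:::positive_spectra(b, s, dcfg)))
}
train_vecs <- t(vapply(train_cancer, vec_for, numeric(6)))
integ <- train_integrator(train_vecs,
                          vapply(train_cancer, function(b) b$true_class, ""),
                          seed = cfg$seed + 20L,
                          split = vapply(train_cancer,
                                         function(b) b$split, ""))
saveRDS(list(too = too, integrator = integ), cache_path("too"))

test_vecs <- t(vapply(test_cancer, vec_for, numeric(6)))
test_cls <- vapply(test_cancer, function(b) b$true_class, "")
tab <- do.call(rbind, lapply(cancer_types(), function(ty) {
  y <- as.numeric(test_cls == ty)
  r <- roc_auc(test_vecs[, ty], y)
  op <- operating_points(test_vecs[, ty], y)
  data.frame(type = ty, n_pos = sum(y), n_neg = sum(1 - y), auc = r$auc,
             sensitivity = op$optimal$sensitivity,
             specificity = op$optimal$specificity)
}))
write.csv(tab, "results/too_metrics.csv", row.names = FALSE)
cat("one-vs-rest AUCs:\n")
print(tab, row.names = FALSE)
cat(sprintf("mean AUC %.3f\n", mean(tab$auc)))
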