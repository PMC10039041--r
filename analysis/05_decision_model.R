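# Integrated two-stage decision model on the untouched test split: presence
# gate at the training-chosen cutoff, TOO routing, MLP integration.
#
# Outputs: results/decisions.csv, results/confusion_matrix.csv,
# results/decision_metrics.csv.

source("analysis/00_config.R")

pp <- readRDS(cache_path("cohort_preprocessed"))
pres <- readRDS(cache_path("presence"))
tm <- readRDS(cache_path("too"))
split <- vapply(pp$bags, function(b) b$split, "")
test <- pp$bags[split == "test"]

dcfg <- decision_config(presence_cutoff = pres$cutoff,
                        spectrum_positive_threshold =
                          cfg$spectrum_positive_threshold,
                        integrator = tm$integrator)
decisions <- lapply(test, decide, presence_model = pres$model,
                    too_models = tm$too, cfg = dcfg)

truth <- stats::setNames(vapply(test, function(b) b$true_class, ""),
                         vapply(test, function(b) b$sample_id, ""))
conf <- confusion_matrix(decisions, truth)
write.csv(as.data.frame(conf), "results/confusion_matrix.csv")

dec <- data.frame(
  sample_id = vapply(decisions, function(d) d$sample_id, ""),
  true_class = unname(truth),
  stage = vapply(test, function(b) b$stage, ""),
  presence_score = vapply(decisions, function(d) d$presence_score, 0),
  predicted_class = vapply(decisions, function(d) d$predicted_class, ""))
write.csv(dec, "results/decisions.csv", row.names = FALSE)

is_cancer <- dec$true_class != "HC"
positive <- dec$predicted_class != "non-cancer"
sens <- mean(positive[is_cancer])
spec <- mean(!positive[!is_cancer])
too_acc <- mean(dec$predicted_class[is_cancer & positive] ==
                  dec$true_class[is_cancer & positive])
early <- dec$stage == "early"
metrics <- data.frame(
  sensitivity = sens, specificity = spec, too_accuracy = too_acc,
  sensitivity_early = mean(positive[early]),
  sensitivity_advanced = mean(positive[dec$stage == "advanced"]),
  too_accuracy_early = mean(dec$predicted_class[early & positive] ==
                              dec$true_class[early & positive]))
write.csv(metrics, "results/decision_metrics.csv", row.names = FALSE)

cat(sprintf("sensitivity %.3f at specificity %.3f; TOO accuracy %.3f\n",
            sens, spec, too_acc))
print(conf)
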