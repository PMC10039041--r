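# Train the MIL cancer-presence classifier on the training split, choose the
# ROC-optimal cutoff, and evaluate presence detection on the test split.
#
# Outputs: results/presence_metrics.csv, results/presence_history.csv,
# results/presence_roc.csv.

source("analysis/00_config.R")

pp <- readRDS(cache_path("cohort_preprocessed"))
split <- vapply(pp$bags, function(b) b$split, "")
train <- pp$bags[split == "train"]
test <- pp$bags[split == "test"]

tcfg <- cfg$train; tcfg$seed <- cfg$seed + 1L
model <- build_presence_classifier(cfg$arch, cfg$cohort$grid[3],
                                   seed = cfg$seed + 1L)
model <- train_presence(model, train, tcfg)
write.csv(model$history, "results/presence_history.csv", row.names = FALSE)

tr_scores <- vapply(train, function(b) score_bag(model, b), 0)
tr_labels <- as.numeric(vapply(train, function(b) b$true_class, "") != "HC")
cutoff <- choose_cutoff(tr_scores, tr_labels,
                        split = vapply(train, function(b) b$split, ""))

te_scores <- vapply(test, function(b) score_bag(model, b), 0)
te_labels <- as.numeric(vapply(test, function(b) b$true_class, "") != "HC")
roc <- roc_auc(te_scores, te_labels)
op <- operating_points(te_scores, te_labels)
pr <- pr_metrics(te_scores, te_labels)
ci <- bootstrap_ci(te_scores, te_labels, "auc", n_boot = 500L,
                   seed = cfg$seed + 30L)

write.csv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                     tpr = roc$tpr),
          "results/presence_roc.csv", row.names = FALSE)
metrics <- data.frame(
  auc = roc$auc, auc_lo = ci[1], auc_hi = ci[2], cutoff = cutoff,
  sensitivity = mean(te_scores[te_labels == 1] > cutoff),
  specificity = mean(te_scores[te_labels == 0] <= cutoff),
  sens_at_99spec = op$sens_at_spec, spec_at_99sens = op$spec_at_sens,
  auprc = pr$auprc, f1 = pr$f1)
write.csv(metrics, "results/presence_metrics.csv", row.names = FALSE)
saveRDS(list(model = model, cutoff = cutoff), cache_path("presence"))

cat(sprintf("presence AUC %.3f (%.3f-%.3f), cutoff %.3f\n",
            roc$auc, ci[1], ci[2], cutoff))
cat(sprintf("sens %.3f / spec %.3f at the training-chosen cutoff\n",
            metrics$sensitivity, metrics$specificity))
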