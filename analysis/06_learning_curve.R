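# How many training bags per class does presence detection need?
# Retrains the presence stage at increasing training-set sizes and records
# held-out accuracy/AUC; accuracy is expected to saturate by a few tens of
# bags per class.
#
# Output: results/learning_curve.csv.

source("analysis/00_config.R")

sizes <- c(2L, 5L, 10L, 20L, 30L)
lc <- learning_curve(cfg, sizes)
write.csv(lc, "results/learning_curve.csv", row.names = FALSE)
print(lc, row.names = FALSE)
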