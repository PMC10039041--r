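# Which architecture components carry the presence performance?
# Removes one component at a time (convolution blocks, dropout, the
# fully-connected layer) and retrains.
#
# Output: results/ablation.csv.

source("analysis/00_config.R")

tab <- ablation_sweep(cfg, removals = c("conv1", "conv2", "conv3",
                                        "dropout", "fcl"))
write.csv(tab, "results/ablation.csv", row.names = FALSE)
print(tab, row.names = FALSE)
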