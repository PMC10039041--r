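# Shared configuration for the analysis drivers.
#
# The desk-scale cohort: 30 training + 30 test bags for each of the seven
# classes (healthy control + six cancer types), 100 spectra per bag on a
# 600-1800 cm^-1 grid with 900 channels. Intermediate model objects are
# cached under scratch/ so the numbered scripts can be run in sequence
# without retraining; tables land under results/.

library(sersmil)

analysis_seed <- 1L
cfg <- experiment_config(seed = analysis_seed)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cache_path <- function(name) file.path("scratch", paste0(name, ".rds"))
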