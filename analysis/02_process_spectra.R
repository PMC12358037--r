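#!/usr/bin/env Rscript
# Stage 2: spectral processing.
#
# Local-regression smoothing (span 0.20) followed by the additive
# negative-value correction, mirroring standard reflectance processing. The
# processed set is what every downstream stage consumes.

library(florivis)

ss <- read_spectra("results/data/spectra.tsv")
groups <- read.table("results/data/groups.tsv", header = TRUE, sep = "\t")
ss$groups <- setNames(groups$group, groups$label)[labels(ss)]

n_negative <- sum(apply(ss$refl, 2, min) < 0)
proc <- fix_negative(smooth_spectra(ss, span = 0.20))
validate_spectra(proc)
write_spectra(proc, "results/data/spectra_processed.tsv")

cat(sprintf("processed %d spectra: loess span 0.20, %d needed the negative-value shift\n",
            length(proc), n_negative))
cat(sprintf("reflectance range after processing: %.2f-%.2f %%\n",
            min(proc$refl), max(proc$refl)))
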