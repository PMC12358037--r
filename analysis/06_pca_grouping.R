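#!/usr/bin/env Rscript
# Stage 6: PCA grouping check.
#
# Principal component analysis of the raw 300-700 nm reflectance matrix,
# used to confirm that the green / green-yellow split (and the comparison
# classes) form coherent clusters in spectral space.

library(florivis)

proc <- read_spectra("results/data/spectra_processed.tsv")
groups <- read.table("results/data/groups.tsv", header = TRUE, sep = "\t")
proc$groups <- setNames(groups$group, groups$label)[labels(proc)]

scores <- validate_grouping_pca(proc)
write.table(scores, "results/pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

ev <- attr(scores, "explained")
cat(sprintf("PC1 explains %.1f %%, PC2 %.1f %% of reflectance variance\n",
            100 * ev[1], 100 * ev[2]))
gg <- scores[scores$group %in% c("green", "green_yellow"), ]
cat("PC1 class means (green vs green-yellow subset):\n")
print(round(tapply(gg$PC1, gg$group, mean), 2))
cat("wrote results/pca_scores.tsv\n")
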