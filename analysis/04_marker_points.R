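#!/usr/bin/env Rscript
# Stage 4: spectral marker points.
#
# Detects sharp reflectance transitions in the green, green-yellow and
# blue-violet classes (>=10 percentage points over 50 nm, +/-10-point
# smoothing, 5-point lookahead), bins them in 10 nm classes, and scores
# each spectrum's fit to the bee discrimination optima (400 and 500 nm)
# with MAD and minAD.

library(florivis)

proc <- read_spectra("results/data/spectra_processed.tsv")
groups <- read.table("results/data/groups.tsv", header = TRUE, sep = "\t")
proc$groups <- setNames(groups$group, groups$label)[labels(proc)]

classes <- c("green", "green_yellow", "blue_violet")
mss <- proc[labels(proc)[proc$groups %in% classes]]
mps <- detect_marker_points(mss, marker_settings())

bins <- bin_marker_points(mps, binwidth = 10, groups = mss$groups)
metrics <- marker_metrics(mps, optima = c(400, 500))
metrics$group <- unname(mss$groups[metrics$label])
write.table(bins, "results/marker_bins.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(metrics, "results/marker_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

excluded <- attr(metrics, "excluded")
cat(sprintf("%d of %d spectra produced no marker points%s\n",
            length(excluded), length(mss),
            if (length(excluded)) paste0(" (", paste(excluded, collapse = ", "), ")")
            else ""))
for (cls in classes) {
  b <- bins[bins$group == cls, ]
  share500 <- sum(b$rel_freq[b$bin_lo >= 480 & b$bin_lo < 520])
  share_long <- sum(b$rel_freq[b$bin_lo >= 560])
  cat(sprintf("%-13s: %4.1f %% of marker points in 480-520 nm, %4.1f %% above 560 nm\n",
              cls, 100 * share500, 100 * share_long))
}
ok <- !is.na(metrics$MAD)
cat("\nMAD / minAD_400 / minAD_500 class means (nm):\n")
print(round(sapply(c("MAD", "minAD_400", "minAD_500"), function(m)
  tapply(metrics[[m]][ok], metrics$group[ok], mean)), 1))
cat("\nwrote results/marker_bins.tsv, results/marker_metrics.tsv\n")
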