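#!/usr/bin/env Rscript
# Stage 3: pollinator colour-vision modelling.
#
# Maps every processed spectrum into the honeybee colour hexagon and the
# tetravariant fly colour space (von Kries adaptation to the foliage
# background, D65 illuminant), then summarizes chromatic/achromatic
# contrasts and discriminability-threshold flags per colour class.

library(florivis)

proc <- read_spectra("results/data/spectra_processed.tsv")
groups <- read.table("results/data/groups.tsv", header = TRUE, sep = "\t")
proc$groups <- setNames(groups$group, groups$label)[labels(proc)]

loci <- rbind(colour_loci(proc, viewing_context("hexagon")),
              colour_loci(proc, viewing_context("fly")))
write.table(loci, "results/contrasts.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

for (m in c("hexagon", "fly")) {
  sub <- loci[loci$model == m, ]
  cat(sprintf("\n-- %s model (threshold %.3f EU) --\n", m,
              default_thresholds[[if (m == "fly") "fly" else "hexagon"]]))
  means <- tapply(sub$chromatic_EU, sub$group, mean)
  print(round(means, 3))
  below <- tapply(!sub$above_threshold, sub$group, sum)
  cat("below threshold:",
      paste(sprintf("%s %d/%d", names(below), below,
                    table(sub$group)[names(below)]), collapse = ", "), "\n")
}
hex <- loci[loci$model == "hexagon", ]
cat("\nachromatic (green-receptor) contrast, bee model:\n")
print(round(tapply(hex$achromatic_EU, hex$group, mean), 3))
cat("\nwrote results/contrasts.tsv\n")
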