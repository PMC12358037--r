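#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# The study design this emulates: 30 focal species with green (n = 19) or
# green-yellow (n = 11) flowers, compared against four common flower-colour
# classes (yellow 38, blue-violet 28, pink 25, white 9), all viewed against
# a green-foliage background, with an ultrametric phylogeny over the full
# species set. Everything is written as plain delimited text / Newick so
# later stages can re-read their inputs.

library(florivis)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ss <- make_study_set(seed = seed)
write_spectra(ss, file.path(out, "spectra.tsv"))
write.table(data.frame(label = labels(ss), group = unname(ss$groups)),
            file.path(out, "groups.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

tree <- make_yule_tree(length(ss), seed = seed + 1000L, labels = labels(ss))
ape::write.tree(tree, file.path(out, "tree.nwk"))

write_spectra(foliage_background(), file.path(out, "background.tsv"))

cat(sprintf("simulated %d spectra (seed %d):\n", length(ss), seed))
print(table(ss$groups))
cat(sprintf("tree: %d tips, depth %.3f\n", length(tree$tip.label),
            max(ape::node.depth.edgelength(tree))))
cat("wrote spectra.tsv, groups.tsv, tree.nwk, background.tsv to", out, "\n")
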