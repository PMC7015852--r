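#!/usr/bin/env Rscript
# Stage 4: collinear blocks and anchor pairs in the focal genome.
#
# Chains within-family homologous pairs into collinear blocks (rank gap
# <= 20, >= 4 pairs per block), screens them to a one-to-one tiling,
# extracts anchor pairs, removes those with Ks > 5, and scores recall
# and precision against the simulated truth.

library(wgdlens)

ds <- load_inputs("results/dataset")
fams <- read.delim("results/families.tsv")
ks_table <- read_ks_table("results/paranome_ks.tsv")
family_of <- setNames(fams$family_id, fams$gene_id)
focal <- "Nymphaea_colorata"

orders <- gene_order(ds$orders)
foc <- orders[orders$species == focal, ]
pairs <- do.call(rbind, lapply(split(fams$gene_id, fams$family_id), function(g) {
  g <- intersect(g, foc$gene_id)
  if (length(g) < 2) return(NULL)
  p <- combn(g, 2)
  data.frame(gene_a = p[1, ], gene_b = p[2, ])
}))
cat("intra-genomic homologous pairs:", nrow(pairs), "\n")

blocks <- chain_collinear_blocks(foc, pairs, max_gap = 20, min_len = 4,
                                 self = TRUE, family_of = family_of)
blocks11 <- screen_one_to_one(blocks)
cat("collinear blocks:", nrow(blocks), "| after 1:1 screening:",
    nrow(blocks11), "\n")
write.table(blocks11, "results/blocks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

anchors <- extract_anchor_pairs(blocks11, ks_table, ks_cap = 5)
cat("anchor pairs:", attr(anchors, "n_total"), "total;",
    attr(anchors, "n_removed"), "removed at Ks > 5;",
    attr(anchors, "n_kept"), "kept\n")
write.table(anchors, "results/anchor_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- ds$anchors[ds$anchors$species == focal, ]
key <- function(a, b) paste(pmin(a, b), pmax(a, b))
tk <- key(truth$gene_a, truth$gene_b)
dk <- key(anchors$gene_a, anchors$gene_b)
cat(sprintf("recall %.3f (of %d true), precision %.3f\n",
            mean(tk %in% dk), length(tk), mean(dk %in% tk)))
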