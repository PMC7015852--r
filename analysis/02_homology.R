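#!/usr/bin/env Rscript
# Stage 2: build the similarity graph, gene families and LCN set.
#
# All-against-all protein scoring (significance cutoff 1e-10), Markov
# clustering into families, per-species copy numbers, and a low-copy
# selection in the spirit of the single-copy filter used for deep
# phylogeny: here strictly single-copy in the focal species, Amborella
# and the outgroup, and single-copy in at least 3 of the 5 remaining
# species.

library(wgdlens)

ds <- load_inputs("results/dataset")
edges <- pairwise_similarity(ds$proteins)
cat("similarity edges kept at 1e-10:", nrow(edges), "\n")
write_hits(edges, "results/similarity_hits.tsv")

fams <- cluster_families(edges, genes = names(ds$proteins))
cat("families (incl. singletons):", length(unique(fams$family_id)), "\n")
write.table(fams, "results/families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

species_of <- setNames(ds$orders$species, ds$orders$gene_id)
cn <- family_copy_number(fams, species_of, species = ds$species_tree$tip.label)
focal <- c("Nymphaea_colorata", "Amborella_trichopoda", "Ginkgo_biloba")
panel <- setdiff(colnames(cn), focal)
lcn <- select_lcn_families(cn, focal_single = focal, panel = panel,
                           min_single_in_panel = 3)
cat("low-copy nuclear families:", length(lcn), "\n")
writeLines(lcn, "results/lcn_families.txt")
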