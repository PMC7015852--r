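# Chromosome layout of simulated gene families.
#
# Each family occupies one locus in an ancestral gene order shared by all
# species (contiguous runs of loci per chromosome). Species descending
# from the WGD branch carry two copies of every chromosome: copy "A"
# segments (chr1, chr2, ...) hold the A-copy genes and copy "B" segments
# (chr1b, ...) hold the retained duplicates, preserving locus order, with
# each B gene independently deleted with fractionation_prob. Background
# duplicates are inserted next to their parent locus with probability 0.5
# (tandem-like), otherwise at a random position on the same chromosome.

#' Lay out simulated genomes and derive anchor-pair truth
#'
#' @param families list of truth records from [simulate_gene_trees()].
#' @param species_tree the species tree ([make_species_tree()]).
#' @param config a [sim_config()].
#' @param seed optional seed (default: substream of `config$seed`).
#' @return list with `orders` (data.frame gene_id, species, chromosome,
#'   rank, strand), `anchors` (data.frame species, gene_a, gene_b,
#'   family_id: surviving true collinear WGD pairs), and `removed`
#'   (character vector of fractionated-out gene ids, to be pruned from
#'   sequences and trees).
#' @export
layout_genomes <- function(families, species_tree, config, seed = NULL) {
  seed <- seed %||% substream_seed(config$seed, "layout")
  species <- species_tree$tip.label
  wgd_species <- character(0)
  if (!is.na(config$wgd_branch %||% NA) && !is.null(config$wgd_branch)) {
    labs <- c(species_tree$tip.label, species_tree$node.label)
    w <- match(config$wgd_branch, labs)
    if (is.na(w)) stop("wgd_branch not in species tree")
    tips <- phangorn::Descendants(species_tree, w, type = "tips")[[1]]
    wgd_species <- species_tree$tip.label[tips]
  }

  n_fam <- length(families)
  chrom_of <- rep(seq_len(config$n_chromosomes),
                  each = ceiling(n_fam / config$n_chromosomes))[seq_len(n_fam)]

  leaves <- do.call(rbind, lapply(families, function(f) {
    if (is.null(f$leaves)) return(NULL)
    cbind(f$leaves, family_id = f$family_id, fam_idx = match(f$family_id, vapply(families, `[[`, "", "family_id")))
  }))
  with_seed(seed, {
    orders <- list(); anchors <- list(); removed <- character(0)
    for (sp in species) {
      lv <- leaves[leaves$species == sp, , drop = FALSE]
      if (nrow(lv) == 0) next
      is_wgd_sp <- sp %in% wgd_species
      for (chr in seq_len(config$n_chromosomes)) {
        fams_here <- which(chrom_of == chr)
        copies <- if (is_wgd_sp) c("A", "B") else "A"
        for (cp in copies) {
          chrom_name <- if (cp == "A") paste0("chr", chr) else paste0("chr", chr, "b")
          main <- character(0); extras <- list()
          for (fi in fams_here) {
            fam_id <- families[[fi]]$family_id
            g <- lv[lv$fam_idx == fi, , drop = FALSE]
            if (nrow(g) == 0) next
            g_cp <- if (is_wgd_sp) g[!is.na(g$wgd_copy) & g$wgd_copy == cp, , drop = FALSE] else g
            if (nrow(g_cp) == 0) next
            if (cp == "B" && runif(1) < config$fractionation_prob) {
              removed <- c(removed, g_cp$gene_id)
              next
            }
            prim <- g_cp$gene_id[!g_cp$bg]
            if (length(prim) == 0) prim <- g_cp$gene_id[1]
            locus_gene <- prim[1]
            main <- c(main, locus_gene)
            for (ex in setdiff(g_cp$gene_id, locus_gene)) {
              extras[[length(extras) + 1L]] <- list(gene = ex, parent = locus_gene,
                                                    tandem = runif(1) < config$tandem_prob)
            }
          }
          for (ex in extras) {
            pos <- match(ex$parent, main)
            at <- if (!is.na(pos) && ex$tandem) pos else sample.int(length(main) + 1L, 1L) - 1L
            main <- append(main, ex$gene, after = at)
          }
          if (length(main) > 0)
            orders[[length(orders) + 1L]] <- data.frame(
              gene_id = main, species = sp, chromosome = chrom_name,
              rank = seq_along(main) - 1L, strand = "+", stringsAsFactors = FALSE)
        }
      }
      # surviving anchor truth: loci with both copies placed
      if (is_wgd_sp) {
        placed <- do.call(rbind, orders)
        placed <- placed[placed$species == sp, , drop = FALSE]
        for (fi in which(vapply(families, function(f) !is.null(f$leaves), logical(1)))) {
          g <- lv[lv$fam_idx == fi, , drop = FALSE]
          if (nrow(g) == 0) next
          a_main <- g$gene_id[!is.na(g$wgd_copy) & g$wgd_copy == "A" & !g$bg]
          b_main <- g$gene_id[!is.na(g$wgd_copy) & g$wgd_copy == "B" & !g$bg]
          a_main <- a_main[a_main %in% placed$gene_id]
          b_main <- b_main[b_main %in% placed$gene_id]
          if (length(a_main) >= 1 && length(b_main) >= 1)
            anchors[[length(anchors) + 1L]] <- data.frame(
              species = sp, gene_a = a_main[1], gene_b = b_main[1],
              family_id = families[[fi]]$family_id, stringsAsFactors = FALSE)
        }
      }
    }
    orders <- do.call(rbind, orders)
    rownames(orders) <- NULL
    anchors <- if (length(anchors)) do.call(rbind, anchors) else
      data.frame(species = character(0), gene_a = character(0),
                 gene_b = character(0), family_id = character(0))
    list(orders = orders, anchors = anchors, removed = unique(removed))
  })
}
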