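# Self-contained simulation experiments: each runs the generative model
# under stated conditions and measures how well an inference stage
# recovers the truth. Used by the validation suite and the analysis
# drivers; every experiment is deterministic given its seed.

#' Paranome peak recovery experiment
#'
#' Simulates a dataset with a WGD, builds the focal species' paranome
#' from protein similarity (clustering, pairwise Ks, subfamily splitting,
#' node weighting), and locates the weighted Ks peak.
#'
#' @param seed integer seed.
#' @param n_families,codon_length,retention_prob simulation conditions
#'   (defaults: 300 families of 500 codons, retention 0.3).
#' @param wgd_ks true pairwise WGD age (default 0.9).
#' @param focal_species species whose paranome is analysed.
#' @return list: `peak` (a `ks_peak`), `n_values`, `config`.
#' @export
paranome_peak_experiment <- function(seed, n_families = 300, codon_length = 500,
                                     retention_prob = 0.3, wgd_ks = 0.9,
                                     focal_species = "Nymphaea_colorata") {
  cfg <- sim_config(seed = seed, n_families = n_families,
                    codon_length = codon_length,
                    retention_prob = retention_prob, wgd_ks = wgd_ks)
  ds <- simulate_dataset(cfg)
  sp <- setNames(ds$orders$species, ds$orders$gene_id)
  prots <- ds$proteins[sp[names(ds$proteins)] == focal_species]
  edges <- pairwise_similarity(prots)
  fams <- cluster_families(edges, genes = names(prots))
  mats <- list()
  for (g in split(fams$gene_id, fams$family_id)) {
    if (length(g) < 2) next
    cds <- ds$cds[g]
    cds <- cds[nchar(cds) == stats::median(nchar(cds))]
    if (length(cds) < 2) next
    fid <- fams$family_id[match(g[1], fams$gene_id)]
    mats[[fid]] <- family_ks_matrix(cds)$ks
  }
  wd <- weighted_paranome_distribution(mats)
  peak <- kde_peak_ci(wd, seed = substream_seed(seed, "peak"))
  list(peak = peak, n_values = nrow(wd), config = cfg)
}

#' Duplication placement recovery experiment
#'
#' Runs the full pipeline (similarity, clustering, Ks, synteny,
#' gene trees, circumscription) on a simulated WGD dataset and measures
#' the fraction of confidently supported anchor events whose
#' circumscribed interval contains the true WGD branch.
#'
#' @param seed integer seed.
#' @param n_families families to simulate (default 200).
#' @param support_threshold bootstrap threshold (default 80).
#' @return list: `rate` (fraction of high-support events containing the
#'   true branch), `n_events`, `tally`, `report`.
#' @export
placement_recovery_experiment <- function(seed, n_families = 200,
                                          support_threshold = 80) {
  sim <- sim_config(seed = seed, n_families = n_families,
                    retention_prob = 0.4, fractionation_prob = 0.1)
  pc <- pipeline_config(sim = sim,
                        stages = c("simulate", "homology", "ks", "synteny",
                                   "phylodup"))
  run <- run_pipeline(pc)
  ev <- run$artifacts$events
  if (is.null(ev)) return(list(rate = NA_real_, n_events = 0L))
  ev <- ev[ev$placed & !is.na(ev$support) & ev$support >= support_threshold, ,
           drop = FALSE]
  sptr <- run$artifacts$dataset$species_tree
  hit <- vapply(seq_len(nrow(ev)), function(i)
    event_contains_branch(sptr, ev$lower[i], ev$upper[i], sim$wgd_branch),
    logical(1))
  list(rate = mean(hit), n_events = nrow(ev),
       tally = run$artifacts$event_tally, report = run$report)
}

#' Relative WGD timing experiment
#'
#' Simulates a WGD postdating the split between the focal species and a
#' comparison lineage, then asks whether the paralogue peak is younger
#' (smaller Ks) than the orthologue divergence mode, as expected.
#'
#' @param seed integer seed.
#' @param n_families families (default 100).
#' @param other comparison species (default the Cabombaceae lineage,
#'   whose split predates the default WGD).
#' @return list: `paralog_mode`, `ortholog_mode`, `wgd_younger`.
#' @export
relative_timing_experiment <- function(seed, n_families = 100,
                                       other = "Cabomba_caroliniana") {
  focal <- "Nymphaea_colorata"
  cfg <- sim_config(seed = seed, n_families = n_families,
                    retention_prob = 0.5, fractionation_prob = 0.1)
  ds <- simulate_dataset(cfg)
  sp <- setNames(ds$orders$species, ds$orders$gene_id)
  keep <- sp[names(ds$proteins)] %in% c(focal, other)
  edges <- pairwise_similarity(ds$proteins[keep])
  fams <- cluster_families(edges, genes = names(ds$proteins)[keep])
  mats <- list()
  for (g in split(fams$gene_id, fams$family_id)) {
    g <- g[sp[g] == focal]
    if (length(g) < 2) next
    cds <- ds$cds[g]
    cds <- cds[nchar(cds) == stats::median(nchar(cds))]
    if (length(cds) < 2) next
    mats[[g[1]]] <- family_ks_matrix(cds)$ks
  }
  wd <- weighted_paranome_distribution(mats)
  peak <- kde_peak_ci(wd, seed = substream_seed(seed, "peak"))
  rb <- reciprocal_best_orthologs(edges, sp, focal, other)
  kv <- numeric(0)
  for (r in seq_len(nrow(rb))) {
    a <- ds$cds[[rb$gene_a[r]]]; b <- ds$cds[[rb$gene_b[r]]]
    if (nchar(a) != nchar(b)) next
    est <- ks_pair_ng86(dna_to_codons(a), dna_to_codons(b))
    if (!est$saturated) kv <- c(kv, est$Ks)
  }
  cmp <- compare_ortholog_ks(setNames(list(kv), paste0(focal, "~", other)), peak)
  list(paralog_mode = peak$mode, ortholog_mode = cmp$mode[1],
       wgd_younger = cmp$wgd_younger[1])
}

#' NG86 estimator bias experiment
#'
#' Simulates two-taxon families at fixed true synonymous distances and
#' reports the median relative bias of the NG86 estimate per level.
#'
#' @param seed integer seed.
#' @param levels true pairwise Ks levels.
#' @param n_rep replicates per level (default 100).
#' @param codon_length codons per gene (default 500).
#' @return data.frame true_ks, median_ks, median_rel_bias.
#' @export
ng86_bias_experiment <- function(seed, levels = c(0.1, 0.3, 0.5, 0.9, 1.2),
                                 n_rep = 100, codon_length = 500) {
  cfg <- sim_config(seed = seed, codon_length = codon_length, wgd_branch = NA)
  rows <- lapply(levels, function(t) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t / 2, t / 2))
    ks <- vapply(seq_len(n_rep), function(i) {
      s <- evolve_cds(tr, cfg, seed = substream_seed(seed, sprintf("ng86_%g_%d", t, i)))
      ks_pair_ng86(dna_to_codons(s[["a"]]), dna_to_codons(s[["b"]]))$Ks
    }, numeric(1))
    data.frame(true_ks = t, median_ks = median(ks),
               median_rel_bias = (median(ks) - t) / t)
  })
  do.call(rbind, rows)
}
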