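# End-to-end orchestration: simulate (or load) -> homology -> Ks ->
# synteny -> distributions -> duplication mapping, with one master seed,
# per-stage logging, and a JSON run report.

#' Pipeline configuration
#'
#' Defaults correspond to the analysis constants used throughout the
#' package: similarity cutoff 1e-10, subfamily/anchor Ks cap 5, chaining
#' max_gap 20 and min_len 4, WGD peak window [0.7, 1.2], bootstrap
#' thresholds 50 and 80, alignment coverage 0.9, LCN panel rule 5 of the
#' panel species.
#'
#' @param sim a [sim_config()] (simulation input), or `NULL` when loading
#'   from `input_dir`.
#' @param input_dir dataset directory (from [emit_dataset()]) when not
#'   simulating.
#' @param stages character vector of stages to run, in dependency order.
#' @param focal_species species whose paranome/anchors are analysed.
#' @param outgroup_species gene-tree rooting outgroup.
#' @param rate_outgroup outgroup for relative-rate comparisons.
#' @param similarity_threshold,ks_cap,max_gap,min_len,peak_window,bs_thresholds,coverage,min_peak_values,lcn_min_single,max_family_genes
#'   stage parameters (see module functions).
#' @param seed master seed (default: the simulation seed).
#' @param output_dir where artifacts are written (`NULL`: nothing written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            stages = c("simulate", "homology", "ks", "synteny",
                                       "ksdist", "phylodup"),
                            focal_species = "Nymphaea_colorata",
                            outgroup_species = "Ginkgo_biloba",
                            rate_outgroup = "Illicium_henryi",
                            similarity_threshold = 1e-10,
                            ks_cap = 5,
                            max_gap = 20,
                            min_len = 4,
                            peak_window = c(0.7, 1.2),
                            bs_thresholds = c(50, 80),
                            coverage = 0.9,
                            min_peak_values = 30,
                            lcn_min_single = 5,
                            max_family_genes = 200,
                            seed = NULL,
                            output_dir = NULL) {
  cfg <- as.list(environment())
  cfg$seed <- seed %||% (if (!is.null(sim)) sim$seed else 1L)
  structure(cfg, class = "pipeline_config")
}

#' Load and cross-validate an emitted dataset
#'
#' @param paths list with `dataset_dir` (a directory written by
#'   [emit_dataset()]).
#' @return a validated `wgd_dataset`.
#' @export
load_inputs <- function(paths) {
  dir <- if (is.character(paths)) paths else paths$dataset_dir
  ds <- load_dataset(dir)
  missing_seq <- setdiff(ds$orders$gene_id, names(ds$cds))
  if (length(missing_seq))
    stop("gene(s) in order table without a sequence: ",
         paste(head(missing_seq, 10), collapse = ", "))
  bad_sp <- setdiff(unique(ds$orders$species), ds$species_tree$tip.label)
  if (length(bad_sp))
    stop("species in order table absent from species tree: ",
         paste(head(bad_sp, 10), collapse = ", "))
  ds
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated or
#' loaded dataset and returns a run report (per-stage counts, peak
#' estimates, warnings). With `output_dir` set, tables, the report and
#' the resolved configuration are written to disk. Identical config and
#' seed reproduce identical results.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  report <- list(seed = config$seed, stages = st, counts = list(), warnings = character(0))
  art <- list()

  if ("simulate" %in% st) {
    wgd_log("simulate: ", config$sim$n_families, " families")
    ds <- simulate_dataset(config$sim)
  } else {
    if (is.null(config$input_dir)) stop("no simulation stage and no input_dir")
    ds <- load_inputs(config$input_dir)
  }
  art$dataset <- ds
  report$counts$genes <- length(ds$cds)
  report$counts$true_anchors <- nrow(ds$anchors)
  species_of <- setNames(ds$orders$species, ds$orders$gene_id)

  if ("homology" %in% st) {
    edges <- pairwise_similarity(ds$proteins, mode = "builtin",
                                 threshold = config$similarity_threshold)
    fams <- cluster_families(edges, genes = names(ds$proteins))
    art$edges <- edges
    art$families <- fams
    report$counts$similarity_edges <- nrow(edges)
    report$counts$families <- length(unique(fams$family_id))
    wgd_log("homology: ", nrow(edges), " edges -> ",
            report$counts$families, " families")
  }

  if ("ks" %in% st) {
    stopifnot(!is.null(art$families))
    fam_split <- split(art$families$gene_id, art$families$family_id)
    mats <- list(); tabs <- list()
    for (fid in names(fam_split)) {
      members <- fam_split[[fid]]
      members <- members[!is.na(nchar(ds$cds[members]))]
      if (length(members) < 2) next
      lens <- nchar(ds$cds[members])
      members <- members[lens == stats::median(lens)]
      if (length(members) < 2) next
      fk <- family_ks_matrix(ds$cds[members])
      mats[[fid]] <- fk$ks
      tabs[[fid]] <- fk$table
    }
    art$ks_matrices <- mats
    art$ks_table <- do.call(rbind, unname(tabs))
    report$counts$ks_pairs <- nrow(art$ks_table) %||% 0L
    wgd_log("ks: ", report$counts$ks_pairs, " pairwise estimates")
  }

  if ("synteny" %in% st) {
    stopifnot(!is.null(art$families))
    family_of <- setNames(art$families$family_id, art$families$gene_id)
    fam_split <- split(art$families$gene_id, art$families$family_id)
    focal <- config$focal_species
    orders <- gene_order(ds$orders)
    foc_genes <- orders$gene_id[orders$species == focal]
    pairs <- do.call(rbind, lapply(fam_split, function(g) {
      g <- intersect(g, foc_genes)
      if (length(g) < 2) return(NULL)
      p <- utils::combn(g, 2)
      data.frame(gene_a = p[1, ], gene_b = p[2, ], stringsAsFactors = FALSE)
    }))
    if (is.null(pairs) || nrow(pairs) == 0) {
      report$counts$blocks <- 0L
      report$counts$anchors_detected <- 0L
      art$anchors <- data.frame()
    } else {
      blocks <- chain_collinear_blocks(orders[orders$species == focal, ], pairs,
                                       max_gap = config$max_gap,
                                       min_len = config$min_len,
                                       self = TRUE, family_of = family_of)
      blocks11 <- screen_one_to_one(blocks)
      anchors <- extract_anchor_pairs(blocks11, art$ks_table, ks_cap = config$ks_cap)
      art$blocks <- blocks11
      art$anchors <- anchors
      report$counts$blocks <- nrow(blocks11)
      report$counts$anchor_pairs_total <- attr(anchors, "n_total")
      report$counts$anchor_pairs_removed_ks <- attr(anchors, "n_removed")
      report$counts$anchors_detected <- attr(anchors, "n_kept")
    }
    wgd_log("synteny: ", report$counts$blocks %||% 0, " blocks, ",
            report$counts$anchors_detected %||% 0, " anchor pairs")
  }

  if ("ksdist" %in% st) {
    stopifnot(!is.null(art$ks_matrices))
    focal <- config$focal_species
    foc_mats <- lapply(art$ks_matrices, function(m) {
      mem <- rownames(m)[species_of[rownames(m)] == focal]
      if (length(mem) < 2) return(NULL)
      m[mem, mem, drop = FALSE]
    })
    foc_mats <- Filter(Negate(is.null), foc_mats)
    wd <- weighted_paranome_distribution(foc_mats, threshold = config$ks_cap)
    art$weighted_ks <- wd
    report$counts$weighted_values <- nrow(wd)
    peak <- tryCatch(
      kde_peak_ci(wd, ks_range = c(0.05, config$ks_cap),
                  seed = substream_seed(config$seed, "peak"),
                  min_values = config$min_peak_values),
      error = function(e) { report$warnings <<- c(report$warnings, conditionMessage(e)); NULL })
    art$paranome_peak <- peak
    if (!is.null(peak))
      report$paranome_peak <- list(mode = peak$mode, ci = c(peak$ci_low, peak$ci_high),
                                   n = peak$n_values)
    # orthologue comparisons vs the focal species
    ortho <- list()
    others <- setdiff(ds$species_tree$tip.label, focal)
    for (sp in others) {
      rb <- reciprocal_best_orthologs(art$edges, species_of, focal, sp)
      if (nrow(rb) == 0) next
      kv <- ortholog_pair_ks(ds, rb)
      if (length(kv)) ortho[[paste0(focal, "~", sp)]] <- kv
    }
    art$ortholog_ks <- ortho
    if (!is.null(peak) && length(ortho)) {
      art$timing <- tryCatch(
        compare_ortholog_ks(ortho, peak, ks_range = c(0.05, config$ks_cap),
                            min_values = config$min_peak_values),
        warning = function(w) suppressWarnings(
          compare_ortholog_ks(ortho, peak, ks_range = c(0.05, config$ks_cap),
                              min_values = config$min_peak_values)))
      report$relative_timing <- art$timing
    }
    wgd_log("ksdist: ", nrow(wd), " weighted values",
            if (!is.null(peak)) paste0(", peak at ", round(peak$mode, 3)))
  }

  if ("phylodup" %in% st) {
    stopifnot(!is.null(art$families), !is.null(art$anchors))
    family_of <- setNames(art$families$family_id, art$families$gene_id)
    fam_split <- split(art$families$gene_id, art$families$family_id)
    anchors <- art$anchors
    if (nrow(anchors)) {
      anchors$family <- family_of[anchors$gene_a]
      events <- list(); calls <- list()
      for (fid in unique(anchors$family)) {
        members <- fam_split[[fid]]
        if (length(members) > config$max_family_genes) next
        og <- members[species_of[members] %in% config$outgroup_species]
        if (length(og) == 0) next
        cds <- ds$cds[members]
        cds <- cds[nchar(cds) == stats::median(nchar(cds))]
        if (length(cds) < 4) next
        tr <- build_gene_tree(cds, n_boot = 100,
                              seed = substream_seed(config$seed, paste0("bt_", fid)))
        tr <- root_gene_tree(tr, config$outgroup_species, species_of)
        cl <- classify_nodes(tr, ds$species_tree, species_of)
        ap <- anchors[anchors$family == fid & anchors$gene_a %in% tr$tip.label &
                        anchors$gene_b %in% tr$tip.label, , drop = FALSE]
        if (nrow(ap) == 0) next
        ev <- circumscribe_duplications(tr, cl, ds$species_tree, ap)
        ev$family <- fid
        events[[length(events) + 1L]] <- ev
      }
      art$events <- if (length(events)) do.call(rbind, events) else NULL
      if (!is.null(art$events)) {
        art$event_tally <- tally_duplications(art$events, config$bs_thresholds)
        report$counts$events_placed <- sum(art$events$placed)
        report$counts$events_unplaced <- sum(!art$events$placed)
        report$event_tally <- art$event_tally
      }
    }
    wgd_log("phylodup: ", report$counts$events_placed %||% 0, " placed events")
  }

  report$config_digest <- config_digest(config)
  out <- structure(list(report = report, artifacts = art), class = "run_report")
  if (!is.null(config$output_dir)) write_run_artifacts(out, config)
  out
}

# Ks values for RBH pairs (positionally aligned pairs only).
ortholog_pair_ks <- function(ds, rb) {
  out <- numeric(0)
  for (r in seq_len(nrow(rb))) {
    a <- ds$cds[[rb$gene_a[r]]]; b <- ds$cds[[rb$gene_b[r]]]
    if (is.null(a) || is.null(b) || nchar(a) != nchar(b)) next
    est <- ks_pair_ng86(dna_to_codons(a), dna_to_codons(b))
    if (!est$saturated) out <- c(out, est$Ks)
  }
  out
}

config_digest <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  paste0(format(sum(utf8ToInt(paste(deparse(x), collapse = "")) *
                      seq_along(utf8ToInt(paste(deparse(x), collapse = "")))) %% 1e9))
}

write_run_artifacts <- function(run, config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  art <- run$artifacts
  if (!is.null(art$weighted_ks))
    write_tsv_hash(art$weighted_ks, file.path(dir, "weighted_ks.tsv"))
  if (!is.null(art$ks_table))
    write_ks_table(art$ks_table, file.path(dir, "ks_pairs.tsv"))
  if (!is.null(art$anchors) && nrow(art$anchors))
    write_tsv_hash(art$anchors, file.path(dir, "anchor_pairs.tsv"))
  if (!is.null(art$events))
    write_tsv_hash(art$events, file.path(dir, "duplication_events.tsv"))
  rep2 <- run$report
  rep2$relative_timing <- if (!is.null(rep2$relative_timing)) as.list(rep2$relative_timing)
  jsonlite::write_json(rep2, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  yaml::write_yaml(cfg, file.path(dir, "resolved_config.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report: stages", paste(x$report$stages, collapse = " -> "), "\n")
  for (nm in names(x$report$counts))
    cat(" ", nm, "=", x$report$counts[[nm]], "\n")
  if (!is.null(x$report$paranome_peak))
    cat("  paranome peak:", round(x$report$paranome_peak$mode, 3), "\n")
  invisible(x)
}
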