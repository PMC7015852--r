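#' Simulate a complete dataset
#'
#' Runs the full generative model: species tree, gene trees with WGD and
#' birth/death, chromosome layout with fractionation (fractionated genes
#' are pruned from trees and never receive sequences), and codon sequence
#' evolution. Everything is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `wgd_dataset`: list with `config`,
#'   `species_tree`, `families` (truth records), `orders`, `anchors`,
#'   `removed`, `cds`, `proteins`.
#' @export
simulate_dataset <- function(config) {
  tr <- make_species_tree(config)
  fams <- simulate_gene_trees(tr, config)
  lay <- layout_genomes(fams, tr, config)
  if (length(lay$removed)) {
    fams <- lapply(fams, function(f) {
      if (is.null(f$leaves)) return(f)
      gone <- intersect(f$leaves$gene_id, lay$removed)
      if (length(gone) == 0) return(f)
      f$leaves <- f$leaves[!f$leaves$gene_id %in% gone, , drop = FALSE]
      if (!is.null(f$tree)) {
        keep <- setdiff(f$tree$tip.label, gone)
        f$tree <- if (length(keep) >= 2) ape::keep.tip(f$tree, keep) else NULL
      }
      f$retained_wgd <- !is.null(f$tree) && any(grepl("^W", f$tree$node.label))
      f
    })
  }
  cds <- list()
  for (f in fams) {
    if (is.null(f$leaves) || nrow(f$leaves) == 0) next
    s <- substream_seed(config$seed, paste0("cds_", f$family_id))
    if (!is.null(f$tree)) {
      cds[[f$family_id]] <- evolve_cds(f$tree, config, seed = s)
    } else {
      cds[[f$family_id]] <- with_seed(s, setNames(random_cds(config), f$leaves$gene_id[1]))
    }
  }
  cds <- unlist(unname(cds))
  structure(list(config = config, species_tree = tr, families = fams,
                 orders = lay$orders, anchors = lay$anchors,
                 removed = lay$removed, cds = cds,
                 proteins = translate_cds(cds)),
            class = "wgd_dataset")
}

#' @export
print.wgd_dataset <- function(x, ...) {
  cat("wgd_dataset:", length(x$families), "families,", length(x$cds), "genes,",
      nrow(x$anchors), "true anchor pairs\n")
  invisible(x)
}

fasta_id <- function(dataset, gene_id) {
  o <- dataset$orders
  i <- match(gene_id, o$gene_id)
  paste0(o$species[i], "|", o$chromosome[i], "|", o$rank[i], "|", gene_id)
}

write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) write.table(df, con, sep = "\t", quote = FALSE,
                            row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_hash <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t")[[1]]
  first <- readLines(path)
  if (length(first) <= 1)
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  read.delim(path, header = FALSE, skip = 1, col.names = cols,
             stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Emits CDS and protein FASTA per species (ids formatted
#' `species|chromosome|rank|gene_id`), the gene-order table, the true
#' species tree (Newick), truth tables (anchors, leaves, family trees),
#' the YAML config, and a manifest with md5 checksums of every file.
#'
#' @param dataset a `wgd_dataset`.
#' @param output_dir directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
emit_dataset <- function(dataset, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  if (file.access(output_dir, 2) != 0) stop("output directory not writable: ", output_dir)
  files <- character(0)
  emit <- function(name) { files <<- c(files, name); file.path(output_dir, name) }

  ape::write.tree(dataset$species_tree, emit("species_tree.nwk"))
  write_tsv_hash(dataset$orders, emit("gene_orders.tsv"))
  write_tsv_hash(dataset$anchors, emit("truth_anchors.tsv"))

  leaves <- do.call(rbind, lapply(dataset$families, function(f) {
    if (is.null(f$leaves) || nrow(f$leaves) == 0) return(NULL)
    data.frame(gene_id = f$leaves$gene_id, species = f$leaves$species,
               family_id = f$family_id, wgd_copy = f$leaves$wgd_copy,
               bg = f$leaves$bg, stringsAsFactors = FALSE)
  }))
  write_tsv_hash(leaves, emit("truth_leaves.tsv"))
  famtab <- do.call(rbind, lapply(dataset$families, function(f) data.frame(
    family_id = f$family_id,
    newick = if (!is.null(f$tree)) ape::write.tree(f$tree) else NA_character_,
    crossed_wgd = f$crossed_wgd, retained_wgd = f$retained_wgd,
    stringsAsFactors = FALSE)))
  write_tsv_hash(famtab, emit("truth_families.tsv"))

  for (sp in dataset$species_tree$tip.label) {
    ids <- dataset$orders$gene_id[dataset$orders$species == sp]
    if (length(ids) == 0) next
    dna <- Biostrings::DNAStringSet(dataset$cds[ids])
    names(dna) <- fasta_id(dataset, ids)
    Biostrings::writeXStringSet(dna, emit(paste0("cds_", sp, ".fasta")))
    aa <- Biostrings::AAStringSet(dataset$proteins[ids])
    names(aa) <- fasta_id(dataset, ids)
    Biostrings::writeXStringSet(aa, emit(paste0("prot_", sp, ".fasta")))
  }
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, emit("config.yaml"))

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(output_dir, files))),
                         stringsAsFactors = FALSE)
  write_tsv_hash(manifest, file.path(output_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load a dataset emitted by [emit_dataset()]
#'
#' @param dir dataset directory.
#' @return a `wgd_dataset` (sequences keyed by bare gene ids).
#' @export
load_dataset <- function(dir) {
  manifest <- read_tsv_hash(file.path(dir, "manifest.tsv"))
  missing <- manifest$file[!file.exists(file.path(dir, manifest$file))]
  if (length(missing)) stop("manifest lists missing files: ", paste(missing, collapse = ", "))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$branch_rates <- if (!is.null(cfg$branch_rates)) unlist(cfg$branch_rates)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  tr <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  orders <- read_tsv_hash(file.path(dir, "gene_orders.tsv"))
  anchors <- read_tsv_hash(file.path(dir, "truth_anchors.tsv"))
  leaves <- read_tsv_hash(file.path(dir, "truth_leaves.tsv"))
  famtab <- read_tsv_hash(file.path(dir, "truth_families.tsv"))
  families <- lapply(seq_len(nrow(famtab)), function(i) {
    fid <- famtab$family_id[i]
    lv <- leaves[leaves$family_id == fid, c("gene_id", "species", "wgd_copy", "bg")]
    rownames(lv) <- NULL
    tree <- if (!is.na(famtab$newick[i])) ape::read.tree(text = famtab$newick[i]) else NULL
    events <- character(0)
    if (!is.null(tree)) {
      kinds <- c(S = "speciation", W = "wgd", B = "bgdup")
      events <- setNames(unname(kinds[substr(tree$node.label, 1, 1)]), tree$node.label)
    }
    list(family_id = fid, newick = famtab$newick[i], tree = tree,
         leaves = if (nrow(lv)) lv else NULL, events = events,
         crossed_wgd = famtab$crossed_wgd[i], retained_wgd = famtab$retained_wgd[i])
  })
  cds <- list(); prot <- list()
  for (sp in tr$tip.label) {
    f <- file.path(dir, paste0("cds_", sp, ".fasta"))
    if (!file.exists(f)) next
    dna <- Biostrings::readDNAStringSet(f)
    ids <- vapply(strsplit(names(dna), "|", fixed = TRUE), function(x) x[[4]], character(1))
    cds[[sp]] <- setNames(as.character(dna), ids)
    aa <- Biostrings::readAAStringSet(file.path(dir, paste0("prot_", sp, ".fasta")))
    prot[[sp]] <- setNames(as.character(aa), ids)
  }
  structure(list(config = config, species_tree = tr, families = families,
                 orders = orders, anchors = anchors, removed = character(0),
                 cds = unlist(unname(cds)), proteins = unlist(unname(prot))),
            class = "wgd_dataset")
}
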