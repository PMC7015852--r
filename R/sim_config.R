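# Default Nymphaeales-like species topology. Branch lengths are per-lineage
# synonymous distances (Ks units); the tree is ultrametric before
# branch-rate multipliers are applied, so the pairwise Ks between two
# species equals twice the depth of their split. Internal nodes are
# labelled so that branches can be addressed by their child node.
DEFAULT_TOPOLOGY <- paste0(
  "((((((Nymphaea_colorata:0.2,(Victoria_cruziana:0.15,Euryale_ferox:0.15)",
  "victoria_euryale:0.05)nymphaea_clade:0.1,Nuphar_advena:0.3)nymphaeaceae:0.3,",
  "Cabomba_caroliniana:0.6)nymphaeales:0.4,Illicium_henryi:1.0)",
  "austrobaileyales:0.2,Amborella_trichopoda:1.2)angiosperms:0.3,",
  "Ginkgo_biloba:1.5)root;"
)

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic genome-evolution scenario:
#' a species tree with per-lineage branch lengths in Ks units, one optional
#' WGD event, gene-family birth/death, duplicate retention and segment
#' fractionation, and a codon-level sequence process.
#'
#' The WGD age `wgd_ks` is expressed on the pairwise Ks scale (the expected
#' synonymous distance *between* the two retained duplicates): each
#' descendant lineage contributes `wgd_ks/2`, which must fall inside the
#' branch named by `wgd_branch`.
#'
#' All simulator parameters are artifact choices: the scenario they encode
#' (a Nymphaeales-like tree, a single WGD on the Nymphaeaceae stem at
#' pairwise Ks 0.9, partial duplicate retention eroded by fractionation)
#' mirrors the inference problem, not any measured dataset.
#'
#' @param seed integer master seed; every stream derives from it.
#' @param species_topology rooted binary Newick string with branch lengths
#'   (per-lineage Ks) and labelled internal nodes.
#' @param branch_rates named numeric vector of rate multipliers applied to
#'   the branch above the named node/leaf (default: all 1).
#' @param wgd_branch name of the species-tree node whose stem branch
#'   carries the WGD, or `NA` for no WGD.
#' @param wgd_ks pairwise synonymous distance from the present to the WGD.
#' @param retention_prob probability that the WGD duplicate of a family
#'   survives to the present, in [0,1].
#' @param birth_rate,loss_rate background gene birth/death rates per gene
#'   lineage per (per-lineage) Ks unit.
#' @param n_families number of gene families to simulate.
#' @param codon_length codons per gene.
#' @param kappa transition/transversion ratio of the synonymous channel.
#' @param omega relative rate of the nonsynonymous channel.
#' @param n_chromosomes chromosomes per (pre-WGD) genome.
#' @param fractionation_prob probability that a retained WGD duplicate is
#'   deleted from its duplicated segment, in [0,1].
#' @param tandem_prob probability that a background duplicate is placed
#'   adjacent to its parent gene (tandem-like) rather than at a random
#'   position, in [0,1].
#' @param allopolyploid if `TRUE`, the second homoeologue's stem is
#'   lengthened by `allo_extra_ks/2`, emulating an allotetraploid whose
#'   second parent diverged earlier than the WGD.
#' @param allo_extra_ks extra pairwise Ks separating the two homoeologue
#'   parents under `allopolyploid = TRUE`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species_topology = DEFAULT_TOPOLOGY,
                       branch_rates = NULL,
                       wgd_branch = "nymphaeaceae",
                       wgd_ks = 0.9,
                       retention_prob = 0.3,
                       birth_rate = 0.05,
                       loss_rate = 0.05,
                       n_families = 200L,
                       codon_length = 300L,
                       kappa = 2,
                       omega = 0.15,
                       n_chromosomes = 4L,
                       fractionation_prob = 0.2,
                       tandem_prob = 0.5,
                       allopolyploid = FALSE,
                       allo_extra_ks = 0.3) {
  cfg <- list(seed = as.integer(seed), species_topology = species_topology,
              branch_rates = branch_rates, wgd_branch = wgd_branch,
              wgd_ks = wgd_ks, retention_prob = retention_prob,
              birth_rate = birth_rate, loss_rate = loss_rate,
              n_families = as.integer(n_families),
              codon_length = as.integer(codon_length),
              kappa = kappa, omega = omega,
              n_chromosomes = as.integer(n_chromosomes),
              fractionation_prob = fractionation_prob,
              tandem_prob = tandem_prob,
              allopolyploid = isTRUE(allopolyploid),
              allo_extra_ks = allo_extra_ks)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(retention_prob = cfg$retention_prob,
             fractionation_prob = cfg$fractionation_prob,
             tandem_prob = cfg$tandem_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop(names(probs)[bad][1], " must be in [0,1]")
  rates <- c(birth_rate = cfg$birth_rate, loss_rate = cfg$loss_rate,
             wgd_ks = cfg$wgd_ks, kappa = cfg$kappa, omega = cfg$omega)
  bad <- rates < 0
  if (any(bad)) stop(names(rates)[bad][1], " must be nonnegative")
  if (!is.null(cfg$branch_rates) && any(cfg$branch_rates < 0))
    stop("branch rate multipliers must be nonnegative")
  if (cfg$n_families < 1 || cfg$codon_length < 1 || cfg$n_chromosomes < 1)
    stop("counts must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_families, "families x",
      x$codon_length, "codons |")
  if (!is.na(x$wgd_branch %||% NA))
    cat(" WGD on", x$wgd_branch, "at pairwise Ks", x$wgd_ks,
        "(retention", x$retention_prob, ", fractionation", x$fractionation_prob, ")")
  else cat(" no WGD")
  cat("\n")
  invisible(x)
}

#' Build the species tree of a simulation
#'
#' Parses the configured Newick topology, checks that it is a rooted binary
#' tree with unique leaf names and nonnegative branch lengths, and applies
#' per-branch rate multipliers (`branch_rates`, keyed by the child node or
#' leaf name of each branch).
#'
#' @param config a [sim_config()].
#' @return an [ape::phylo] tree with internal node labels.
#' @export
make_species_tree <- function(config) {
  tr <- tryCatch(ape::read.tree(text = config$species_topology),
                 error = function(e) stop("could not parse species topology: ", conditionMessage(e)))
  if (is.null(tr) || !inherits(tr, "phylo")) stop("could not parse species topology")
  if (ape::Ntip(tr) < 2) stop("species tree must have >= 2 leaves")
  if (!ape::is.rooted(tr)) stop("species tree must be rooted")
  if (!ape::is.binary(tr)) stop("species tree must be binary")
  if (anyDuplicated(tr$tip.label)) stop("species tree leaf names must be unique")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) stop("every branch needs a Ks length")
  if (any(tr$edge.length < 0)) stop("branch Ks lengths must be nonnegative")
  if (is.null(tr$node.label) || any(tr$node.label == ""))
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
  rates <- config$branch_rates
  if (!is.null(rates)) {
    if (any(rates < 0)) stop("negative branch rate")
    labs <- c(tr$tip.label, tr$node.label)
    child_lab <- labs[tr$edge[, 2]]
    unknown <- setdiff(names(rates), labs)
    if (length(unknown)) stop("branch_rates names not in tree: ", paste(unknown, collapse = ", "))
    m <- rates[child_lab]
    m[is.na(m)] <- 1
    tr$edge.length <- tr$edge.length * unname(m)
  }
  tr
}

# Node heights (mean distance to descendant tips) for every node; used to
# place the WGD point on its branch.
node_heights <- function(tr) {
  n_tip <- ape::Ntip(tr)
  depth <- ape::node.depth.edgelength(tr)      # distance from root
  labs <- c(tr$tip.label, tr$node.label)
  h <- numeric(length(labs))
  desc <- phangorn::Descendants(tr, seq_along(labs), type = "tips")
  for (i in seq_along(labs)) {
    tips <- desc[[i]]
    h[i] <- mean(depth[tips]) - depth[i]
  }
  names(h) <- labs
  h
}
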