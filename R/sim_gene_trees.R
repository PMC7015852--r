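# Gene-family simulation along the species tree: background birth/death of
# gene lineages, and a single WGD event at a fixed point on one branch.
# When a lineage crosses the WGD point it duplicates; the original copy is
# labelled "A", and the new copy ("B") is retained with probability
# retention_prob (otherwise the duplication leaves no trace). Internal
# nodes of the resulting gene trees are event-labelled: S* speciation,
# W* WGD duplication, B* background duplication.

# Nested species-tree representation with the WGD point attached.
species_tree_nested <- function(tr, config) {
  n_tip <- ape::Ntip(tr)
  labs <- c(tr$tip.label, tr$node.label)
  children <- vector("list", length(labs))
  elen <- numeric(length(labs))
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    children[[p]] <- c(children[[p]], ch)
    elen[ch] <- tr$edge.length[k]
  }
  wgd_node <- NA_integer_; wgd_rem <- NA_real_
  if (!is.na(config$wgd_branch %||% NA) && !is.null(config$wgd_branch)) {
    wgd_node <- match(config$wgd_branch, labs)
    if (is.na(wgd_node)) stop("wgd_branch '", config$wgd_branch, "' not found in species tree")
    h <- node_heights(tr)
    h_child <- h[wgd_node]
    L <- elen[wgd_node]
    h_wgd <- config$wgd_ks / 2
    if (h_wgd < h_child - 1e-9 || h_wgd > h_child + L + 1e-9)
      stop("wgd_ks/2 = ", h_wgd, " does not fall on branch '", config$wgd_branch,
           "' (heights ", round(h_child, 4), " .. ", round(h_child + L, 4), ")")
    wgd_rem <- max(0, min(L, h_wgd - h_child))  # distance from WGD point down to child node
  }
  build <- function(i) {
    list(idx = i, name = labs[i], len = elen[i],
         is_tip = i <= n_tip,
         wgd_rem = if (!is.na(wgd_node) && i == wgd_node) wgd_rem else NULL,
         children = lapply(children[[i]], build))
  }
  root <- which(tabulate(tr$edge[, 2], nbins = length(labs)) == 0)[1]
  build(root)
}

# Simulate one gene family; returns nested gene-tree node or NULL (extinct).
# A node: list(kind, blen, children | species/wgd_copy/bg for leaves).
sim_family_tree <- function(sproot, cfg) {
  crossed <- FALSE
  descend <- function(spn, t_rem, acc, wgd_copy, bg) {
    repeat {
      rate <- cfg$birth_rate + cfg$loss_rate
      d_wgd <- if (!is.null(spn$wgd_rem) && t_rem > spn$wgd_rem) t_rem - spn$wgd_rem else Inf
      wait <- if (rate > 0) rexp(1, rate) else Inf
      if (t_rem <= min(wait, d_wgd)) {
        acc <- acc + t_rem
        if (spn$is_tip)
          return(list(kind = "leaf", blen = acc, species = spn$name,
                      wgd_copy = wgd_copy, bg = bg))
        kids <- lapply(spn$children, function(ch) descend(ch, ch$len, 0, wgd_copy, bg))
        kids <- kids[!vapply(kids, is.null, logical(1))]
        if (length(kids) == 0) return(NULL)
        if (length(kids) == 1) { kids[[1]]$blen <- kids[[1]]$blen + acc; return(kids[[1]]) }
        return(list(kind = "speciation", blen = acc, children = kids))
      }
      if (d_wgd <= wait) {
        # hit the WGD point
        acc <- acc + d_wgd
        t_rem <- t_rem - d_wgd    # == spn$wgd_rem, strict '>' prevents re-trigger
        crossed <<- TRUE
        retained <- runif(1) < cfg$retention_prob
        if (!retained) { wgd_copy <- "A"; next }
        a <- descend(spn, t_rem, 0, "A", bg)
        extra <- if (cfg$allopolyploid) cfg$allo_extra_ks / 2 else 0
        b <- descend(spn, t_rem, extra, "B", bg)
        kids <- Filter(Negate(is.null), list(a, b))
        if (length(kids) == 0) return(NULL)
        if (length(kids) == 1) { kids[[1]]$blen <- kids[[1]]$blen + acc; return(kids[[1]]) }
        return(list(kind = "wgd", blen = acc, children = kids))
      }
      # birth or death
      acc <- acc + wait
      t_rem <- t_rem - wait
      if (runif(1) < cfg$loss_rate / rate) return(NULL)
      o <- descend(spn, t_rem, 0, wgd_copy, bg)
      n <- descend(spn, t_rem, 0, wgd_copy, TRUE)
      kids <- Filter(Negate(is.null), list(o, n))
      if (length(kids) == 0) return(NULL)
      if (length(kids) == 1) { kids[[1]]$blen <- kids[[1]]$blen + acc; return(kids[[1]]) }
      return(list(kind = "bgdup", blen = acc, children = kids))
    }
  }
  tree <- descend_root(sproot, descend)
  list(tree = tree, crossed_wgd = crossed)
}

descend_root <- function(sproot, descend) {
  kids <- lapply(sproot$children, function(ch) descend(ch, ch$len, 0, NA_character_, FALSE))
  kids <- Filter(Negate(is.null), kids)
  if (length(kids) == 0) return(NULL)
  if (length(kids) == 1) return(kids[[1]])
  list(kind = "speciation", blen = 0, children = kids)
}

# Flatten a nested gene tree: assign gene ids, collect leaves and events,
# and produce a Newick string with event-coded internal labels.
finalize_gene_tree <- function(nested, family_id) {
  if (is.null(nested)) return(NULL)
  leaves <- list(); counters <- new.env(parent = emptyenv())
  n_int <- 0L
  kind_code <- c(speciation = "S", wgd = "W", bgdup = "B")
  events <- character(0)
  walk <- function(nd) {
    if (nd$kind == "leaf") {
      k <- (get0(nd$species, envir = counters) %||% 0L) + 1L
      assign(nd$species, k, envir = counters)
      gid <- paste0(nd$species, "_", family_id, "_g", k)
      leaves[[length(leaves) + 1L]] <<- data.frame(
        gene_id = gid, species = nd$species,
        wgd_copy = nd$wgd_copy %||% NA_character_, bg = nd$bg,
        stringsAsFactors = FALSE)
      return(paste0(gid, ":", format(nd$blen, digits = 10)))
    }
    n_int <<- n_int + 1L
    lab <- paste0(kind_code[[nd$kind]], n_int)
    events[lab] <<- nd$kind
    paste0("(", paste(vapply(nd$children, walk, character(1)), collapse = ","),
           ")", lab, ":", format(nd$blen, digits = 10))
  }
  nwk <- paste0(walk(nested), ";")
  # single-leaf families produce "gid:len;" which ape cannot parse; keep string only
  leaves <- do.call(rbind, leaves)
  phy <- if (nrow(leaves) >= 2) ape::read.tree(text = nwk) else NULL
  list(family_id = family_id, newick = nwk, tree = phy,
       leaves = leaves, events = events)
}

#' Simulate gene trees along the species tree
#'
#' Runs the birth/death + WGD lineage process for `n_families` independent
#' families and records full ground truth: the event-labelled gene tree
#' (speciation / wgd_duplication / background_duplication nodes), which
#' WGD copy every gene descends from, and whether the family's lineage
#' crossed the WGD point at all.
#'
#' @param species_tree [ape::phylo] from [make_species_tree()].
#' @param config a [sim_config()].
#' @param seed optional seed override (default `config$seed` substream).
#' @return list of truth records; each has `family_id`, `tree`
#'   ([ape::phylo] with event-coded node labels, `NULL` if < 2 genes
#'   survive), `newick`, `leaves` (data.frame gene_id/species/wgd_copy/bg),
#'   `events` (label -> kind), `crossed_wgd`, `retained_wgd` flags.
#' @export
simulate_gene_trees <- function(species_tree, config, seed = NULL) {
  sproot <- species_tree_nested(species_tree, config)
  seed <- seed %||% substream_seed(config$seed, "gene_trees")
  with_seed(seed, {
    lapply(seq_len(config$n_families), function(i) {
      fid <- sprintf("f%04d", i)
      sim <- sim_family_tree(sproot, config)
      rec <- finalize_gene_tree(sim$tree, fid)
      if (is.null(rec))
        rec <- list(family_id = fid, newick = NA_character_, tree = NULL,
                    leaves = NULL, events = character(0))
      rec$crossed_wgd <- sim$crossed_wgd
      rec$retained_wgd <- any(rec$events == "wgd")
      rec
    })
  })
}

# Pairwise path lengths (true Ks) between leaves of a truth record.
true_pair_ks <- function(record) {
  if (is.null(record$tree)) return(NULL)
  ape::cophenetic.phylo(record$tree)
}
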