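# Gene-tree/species-tree duplication mapping: bootstrapped gene trees,
# outgroup-or-midpoint rooting, LCA-based node classification, and
# circumscription of anchor-supported duplication events onto a
# species-tree branch interval (duplication node image = lower bound,
# first rootward speciation node image = upper bound).

aln_to_dnabin <- function(aln) {
  stopifnot(!is.null(names(aln)))
  lens <- unique(nchar(aln))
  if (length(lens) != 1) stop("alignment is not rectangular")
  m <- do.call(rbind, strsplit(tolower(aln), ""))
  rownames(m) <- names(aln)
  ape::as.DNAbin(m)
}

nj_from_aln <- function(bin) {
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  if (any(!is.finite(d))) d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  ape::nj(d)
}

#' Neighbor-joining gene tree with column-resampling bootstrap
#'
#' @param alignment named character vector of aligned nucleotide
#'   sequences (equal lengths).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed for the resampling.
#' @return unrooted [ape::phylo]; `node.label` holds integer percentage
#'   supports (the root gets NA); attribute `star_like` flags an
#'   all-identical alignment.
#' @export
build_gene_tree <- function(alignment, n_boot = 200, seed = 1L) {
  if (length(alignment) < 4) stop("need >= 4 sequences")
  bin <- aln_to_dnabin(alignment)
  tr <- nj_from_aln(bin)
  star <- all(tr$edge.length < 1e-12)
  bp <- with_seed(seed, {
    ape::boot.phylo(tr, as.matrix(bin), FUN = nj_from_aln, B = n_boot,
                    quiet = TRUE, rooted = FALSE)
  })
  tr$node.label <- as.character(round(100 * bp / n_boot))
  tr$node.label[1] <- ""   # root of the unrooted representation
  attr(tr, "star_like") <- star
  if (star) warning("all sequences identical; star-like tree")
  tr
}

#' Root a gene tree on an outgroup, falling back to midpoint
#'
#' If the outgroup-species genes form a monophyletic group under some
#' rooting, the tree is rooted on that clade's stem; otherwise midpoint
#' rooting is applied. Node labels are treated as edge (branch) supports
#' and follow the rerooting.
#'
#' @param tree unrooted [ape::phylo] with support node labels.
#' @param outgroup_species character vector of outgroup species names.
#' @param species_of named map gene id -> species.
#' @return rooted tree; attribute `rooting` is "outgroup" or "midpoint".
#' @export
root_gene_tree <- function(tree, outgroup_species, species_of) {
  og <- tree$tip.label[species_of[tree$tip.label] %in% outgroup_species]
  method <- "midpoint"
  out <- NULL
  if (length(og) == 0) {
    warning("no outgroup genes in tree; midpoint rooting")
  } else if (length(og) < ape::Ntip(tree)) {
    out <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE,
                              edgelabel = TRUE),
                    error = function(e) NULL)
    if (!is.null(out)) method <- "outgroup"
  }
  if (is.null(out)) out <- phangorn::midpoint(tree, node.labels = "support")
  attr(out, "rooting") <- method
  out
}

# Species-set image (MRCA in the species tree) of a set of species names.
species_mrca <- function(species_tree, species) {
  tips <- match(unique(species), species_tree$tip.label)
  if (anyNA(tips)) stop("species not in species tree: ",
                        paste(unique(species)[is.na(tips)], collapse = ", "))
  if (length(tips) == 1) return(tips)
  ape::getMRCA(species_tree, tips)
}

sp_node_name <- function(species_tree, node) {
  c(species_tree$tip.label, species_tree$node.label)[node]
}

# is `anc` an ancestor of (or equal to) `node` in the species tree?
sp_is_ancestor <- function(species_tree, anc, node) {
  if (anc == node) return(TRUE)
  root <- ape::Ntip(species_tree) + 1L
  while (node != root) {
    node <- species_tree$edge[species_tree$edge[, 2] == node, 1]
    if (length(node) == 0) return(FALSE)
    if (node == anc) return(TRUE)
  }
  anc == root
}

#' Classify gene-tree nodes against the species tree
#'
#' Each internal node is mapped to the species-tree MRCA of its leaf
#' species. A node is a `duplication` iff its two child clades' species
#' sets intersect; a `speciation` iff they are disjoint and both children
#' map strictly below the node's image (with `strict = TRUE`, each child
#' must map to/inside an immediate child of the image); otherwise
#' `inconsistent`.
#'
#' @param tree rooted binary gene tree.
#' @param species_tree rooted species tree with labelled nodes.
#' @param species_of named map gene id -> species.
#' @param strict stricter speciation congruence criterion (default FALSE).
#' @return data.frame: node (gene-tree node number), image (species-tree
#'   node number), image_name, class.
#' @export
classify_nodes <- function(tree, species_tree, species_of, strict = FALSE) {
  n_tip <- ape::Ntip(tree)
  tipsets <- phangorn::Descendants(tree, (n_tip + 1):(n_tip + tree$Nnode), "tips")
  spsets <- lapply(tipsets, function(t) unique(species_of[tree$tip.label[t]]))
  images <- vapply(spsets, function(s) species_mrca(species_tree, s), numeric(1))
  node_image <- function(nd) {
    if (nd <= n_tip) species_mrca(species_tree, species_of[tree$tip.label[nd]])
    else images[nd - n_tip]
  }
  node_spset <- function(nd) {
    if (nd <= n_tip) species_of[tree$tip.label[nd]] else spsets[[nd - n_tip]]
  }
  sp_children <- function(node) species_tree$edge[species_tree$edge[, 1] == node, 2]
  cls <- character(tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    nd <- n_tip + k
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    sa <- node_spset(ch[1]); sb <- node_spset(ch[2])
    if (length(intersect(sa, sb)) > 0) { cls[k] <- "duplication"; next }
    ia <- node_image(ch[1]); ib <- node_image(ch[2]); im <- images[k]
    below <- ia != im && ib != im
    if (below && strict) {
      kids <- sp_children(im)
      ok <- function(x) any(vapply(kids, function(c2) sp_is_ancestor(species_tree, c2, x), logical(1)))
      below <- ok(ia) && ok(ib)
    }
    cls[k] <- if (below) "speciation" else "inconsistent"
  }
  data.frame(node = (n_tip + 1):(n_tip + tree$Nnode),
             image = images, image_name = sp_node_name(species_tree, images),
             class = cls, stringsAsFactors = FALSE)
}

node_support <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  lab <- tree$node.label[node - n_tip]
  suppressWarnings(as.numeric(lab))
}

#' Circumscribe anchor-supported duplication events
#'
#' For each anchor pair whose gene-tree MRCA is a duplication node, the
#' event interval is [image of the duplication node, image of the first
#' rootward speciation node] on the species tree (inconsistent and
#' further duplication nodes on the walk are skipped; if no speciation
#' node is reached the species root is the upper bound). If the bounds
#' are joined by a single species-tree branch the event is assigned to
#' it. Event support is the bootstrap value of the branch leading to the
#' duplication node.
#'
#' @param tree rooted gene tree with supports.
#' @param classification output of [classify_nodes()] for `tree`.
#' @param species_tree rooted species tree.
#' @param anchor_pairs data.frame gene_a, gene_b.
#' @return data.frame: gene_a, gene_b, placed, lower, upper,
#'   assigned_branch (child-node name of the branch, or NA), support.
#' @export
circumscribe_duplications <- function(tree, classification, species_tree,
                                      anchor_pairs) {
  n_tip <- ape::Ntip(tree)
  cls <- setNames(classification$class, classification$node)
  img <- setNames(classification$image, classification$node)
  sp_root <- ape::Ntip(species_tree) + 1L
  parent_of <- function(nd) {
    p <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  sp_parent <- function(nd) {
    p <- species_tree$edge[species_tree$edge[, 2] == nd, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  rows <- list()
  for (r in seq_len(nrow(anchor_pairs))) {
    a <- anchor_pairs$gene_a[r]; b <- anchor_pairs$gene_b[r]
    ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
    if (is.na(ia) || is.na(ib)) {
      wgd_log("anchor pair ", a, "/", b, " absent from tree; skipped",
              verbose = getOption("wgdlens.verbose", FALSE))
      next
    }
    mr <- ape::getMRCA(tree, c(ia, ib))
    if (cls[[as.character(mr)]] != "duplication") {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, placed = FALSE,
        lower = NA_character_, upper = NA_character_,
        assigned_branch = NA_character_, support = node_support(tree, mr),
        stringsAsFactors = FALSE)
      next
    }
    lower <- img[[as.character(mr)]]
    nd <- parent_of(mr)
    upper <- sp_root
    while (!is.na(nd)) {
      if (cls[[as.character(nd)]] == "speciation") { upper <- img[[as.character(nd)]]; break }
      nd <- parent_of(nd)
    }
    if (!sp_is_ancestor(species_tree, upper, lower)) upper <- sp_root
    assigned <- NA_character_
    lp <- sp_parent(lower)
    if (!is.na(lp) && lp == upper) assigned <- sp_node_name(species_tree, lower)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, placed = TRUE,
      lower = sp_node_name(species_tree, lower),
      upper = sp_node_name(species_tree, upper),
      assigned_branch = assigned, support = node_support(tree, mr),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0), placed = logical(0),
               lower = character(0), upper = character(0),
               assigned_branch = character(0), support = numeric(0))
  rownames(out) <- NULL
  out
}

#' Does an event interval contain a given species-tree branch?
#'
#' The interval spans the branches above `lower` up to (and including)
#' the branch below `upper`; the branch above node `x` is contained iff
#' `x` is an ancestor-or-self of `lower` and a strict descendant of
#' `upper`.
#'
#' @param species_tree rooted species tree.
#' @param lower,upper,branch_child node names.
#' @return logical.
#' @export
event_contains_branch <- function(species_tree, lower, upper, branch_child) {
  labs <- c(species_tree$tip.label, species_tree$node.label)
  lo <- match(lower, labs); up <- match(upper, labs); x <- match(branch_child, labs)
  if (anyNA(c(lo, up, x))) return(FALSE)
  sp_is_ancestor(species_tree, x, lo) && x != up &&
    sp_is_ancestor(species_tree, up, x)
}

#' Tally circumscribed events per assigned branch and support threshold
#'
#' @param events output of [circumscribe_duplications()] (possibly
#'   concatenated over families).
#' @param thresholds bootstrap thresholds (default 50 and 80).
#' @return data.frame branch x threshold counts (placed, branch-assigned
#'   events only).
#' @export
tally_duplications <- function(events, thresholds = c(50, 80)) {
  ev <- events[events$placed & !is.na(events$assigned_branch), , drop = FALSE]
  rows <- list()
  for (th in thresholds) {
    sub <- ev[!is.na(ev$support) & ev$support >= th, , drop = FALSE]
    if (nrow(sub) == 0) next
    t1 <- table(sub$assigned_branch)
    rows[[length(rows) + 1L]] <- data.frame(branch = names(t1),
                                            threshold = th,
                                            n_events = as.integer(t1),
                                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(0), threshold = numeric(0), n_events = integer(0))
  rownames(out) <- NULL
  out
}

#' Classify an ANA-grade gene-tree topology
#'
#' With the outgroup removed, tests which of three arrangements the
#' rooted tree supports: type I = (Amborella + Nymphaeales) sister to
#' mesangiosperms; type II = Amborella sister to (Nymphaeales +
#' mesangiosperms); type III = Nymphaeales sister to (Amborella +
#' mesangiosperms). The defining branch is the stem of the two-group
#' clade; calls below `bs_threshold` are `unresolved`.
#'
#' @param tree rooted gene tree (rooted with the outgroup) with percent
#'   supports as node labels.
#' @param groups named list with character vectors `amborella`,
#'   `nymphaeales`, `mesangiosperms`, `outgroup` (species names).
#' @param species_of named map gene id -> species.
#' @param bs_threshold defining-branch support threshold (default 80).
#' @return data.frame label ("I","II","III","unresolved"), support, reason.
#' @export
classify_grade_topology <- function(tree, groups, species_of, bs_threshold = 80) {
  need <- c("amborella", "nymphaeales", "mesangiosperms", "outgroup")
  stopifnot(all(need %in% names(groups)))
  sp <- species_of[tree$tip.label]
  grp_tips <- lapply(groups, function(g) tree$tip.label[sp %in% g])
  for (g in setdiff(need, "outgroup")) {
    if (length(grp_tips[[g]]) == 0)
      return(data.frame(label = "unresolved", support = NA_real_,
                        reason = paste0("group absent: ", g), stringsAsFactors = FALSE))
  }
  ingroup <- setdiff(tree$tip.label, grp_tips$outgroup)
  tr <- if (length(grp_tips$outgroup)) ape::drop.tip(tree, grp_tips$outgroup,
                                                    collapse.singles = TRUE) else tree
  mono_support <- function(tips) {
    tips <- intersect(tips, tr$tip.label)
    if (length(tips) < 2) return(NULL)
    if (length(tips) == ape::Ntip(tr)) return(NULL)
    mr <- ape::getMRCA(tr, match(tips, tr$tip.label))
    clade <- tr$tip.label[phangorn::Descendants(tr, mr, "tips")[[1]]]
    if (!setequal(clade, tips)) return(NULL)
    node_support(tr, mr)
  }
  defs <- list(I = c("amborella", "nymphaeales"),
               II = c("nymphaeales", "mesangiosperms"),
               III = c("amborella", "mesangiosperms"))
  for (lab in names(defs)) {
    tips <- unlist(grp_tips[defs[[lab]]])
    s <- mono_support(tips)
    if (!is.null(s)) {
      # the two groups themselves must also be coherent sides of the split
      if (is.na(s)) s <- 0
      if (s >= bs_threshold)
        return(data.frame(label = lab, support = s, reason = "",
                          stringsAsFactors = FALSE))
      return(data.frame(label = "unresolved", support = s,
                        reason = "defining branch below threshold",
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(label = "unresolved", support = NA_real_,
             reason = "no grouping monophyletic", stringsAsFactors = FALSE)
}

#' Tally topology calls over a set of gene trees
#'
#' @param calls data.frame of per-tree calls (rbind of
#'   [classify_grade_topology()] rows).
#' @return data.frame label, n, pct (percentage of all trees).
#' @export
tally_topologies <- function(calls) {
  labs <- c("I", "II", "III", "unresolved")
  n <- vapply(labs, function(l) sum(calls$label == l), integer(1))
  data.frame(label = labs, n = n, pct = 100 * n / nrow(calls),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove alignment columns below a coverage threshold
#'
#' @param alignment named character vector (rectangular, `-` gaps).
#' @param min_coverage minimum non-gap fraction per kept column
#'   (default 0.9).
#' @return alignment with low-coverage columns removed, order preserved.
#' @export
trim_low_coverage_columns <- function(alignment, min_coverage = 0.9) {
  m <- do.call(rbind, strsplit(alignment, ""))
  cov <- colMeans(m != "-")
  keep <- cov >= min_coverage
  if (!any(keep)) stop("no columns meet the coverage threshold")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  setNames(out, names(alignment))
}
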