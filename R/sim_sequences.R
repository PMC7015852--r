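# Codon-level sequence evolution for simulated gene trees.
#
# The process is built so that the synonymous channel is exactly
# identifiable by pairwise counting estimators and additive along the
# tree: root sequences are drawn from the 24 codons of six four-fold
# degenerate amino acids (Val, Ser-TCN, Pro, Thr, Ala, Gly). For these
# codons the NG86 synonymous site count is exactly 1 (the third position),
# and the third position evolves as a Kimura two-parameter nucleotide
# chain with transition/transversion ratio kappa and one synonymous
# substitution per synonymous site per Ks unit of branch length. The
# nonsynonymous channel replaces the amino acid (uniformly among the other
# five, i.e. first/second codon positions) at the reduced rate
# 2*omega per codon per Ks unit. Stop codons are unreachable. Indels are
# never introduced, so family alignments are the identity.

FOURFOLD_AA <- c("V", "S", "P", "T", "A", "G")

fourfold_tables <- function() {
  if (!is.null(.wgd_cache$fourfold)) return(.wgd_cache$fourfold)
  ct <- codon_table()
  # stems: first two nucleotides of the 4-fold boxes used
  stems <- c(V = "GT", S = "TC", P = "CC", T = "AC", A = "GC", G = "GG")
  # codon index for stem + third-position nucleotide
  idx <- sapply(NUC, function(n3) codon_index(paste0(stems, n3)))  # 6 x 4
  rownames(idx) <- names(stems)
  aa_of <- match(ct$aa, FOURFOLD_AA)  # 64 -> 1..6 or NA
  pos3_of <- integer(64)
  for (a in 1:6) for (n in 1:4) pos3_of[idx[a, n]] <- n
  .wgd_cache$fourfold <- list(stems = stems, idx = idx, aa_of = aa_of, pos3_of = pos3_of)
  .wgd_cache$fourfold
}

# K80 transition probability matrix for distance d (substitutions/site),
# nucleotide order A, C, G, T.
k80_matrix <- function(d, kappa) {
  # rate alpha for transitions, beta for each transversion; d = alpha + 2*beta
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta)
  e2 <- exp(-2 * (alpha + beta))
  p_ts <- 1 / 4 + 1 / 4 * e1 - 1 / 2 * e2
  p_tv <- 1 / 4 - 1 / 4 * e1
  p_same <- 1 - p_ts - 2 * p_tv
  P <- matrix(p_tv, 4, 4, dimnames = list(NUC, NUC))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- p_ts
  P
}

# Evolve integer codon vector along one branch of length t (per-lineage Ks).
evolve_branch <- function(codons, t, kappa, omega) {
  if (t <= 0) return(codons)
  ft <- fourfold_tables()
  aa <- ft$aa_of[codons]
  pos3 <- ft$pos3_of[codons]
  if (anyNA(aa)) stop("sequence contains codons outside the simulator alphabet")
  n <- length(codons)
  # nonsynonymous channel: uniform jump chain among the 6 amino acids;
  # k jumps leave the amino acid unchanged with prob 1/6 + 5/6*(-1/5)^k
  k <- rpois(n, 2 * omega * t)
  p_same <- 1 / 6 + 5 / 6 * (-1 / 5)^k
  changed <- runif(n) >= p_same
  if (any(changed)) {
    shift <- sample.int(5, sum(changed), replace = TRUE)
    aa[changed] <- ((aa[changed] - 1 + shift) %% 6) + 1
  }
  # synonymous channel: third position K80 at 1 substitution/site/Ks
  P <- k80_matrix(t, kappa)
  cum <- t(apply(P, 1, cumsum))
  u <- runif(n)
  cmat <- cum[pos3, , drop = FALSE]                    # n x 4 cumulative rows
  pos3 <- max.col(cmat >= u, ties.method = "first")    # first column with cum >= u
  ft$idx[cbind(aa, pos3)]
}

#' Evolve coding sequences along a gene tree
#'
#' Simulates indel-free codon sequences down a gene tree whose branch
#' lengths are per-lineage synonymous distances, so the expected pairwise
#' synonymous distance between two leaves equals the tree path length
#' between them.
#'
#' @param gene_tree [ape::phylo] (a truth record's `tree`), or `NULL`/a
#'   single-leaf record handled via `leaves`.
#' @param config a [sim_config()] (uses `codon_length`, `kappa`, `omega`).
#' @param root_seq optional root CDS (nucleotide string, length
#'   `3*codon_length`, no stop codons); default: random draw from the
#'   simulator alphabet.
#' @param seed optional integer seed (default: leave RNG state alone).
#' @return named character vector of CDS, one per leaf gene.
#' @export
evolve_cds <- function(gene_tree, config, root_seq = NULL, seed = NULL) {
  run <- function() {
    ct <- codon_table()
    ft <- fourfold_tables()
    if (is.null(root_seq)) {
      root <- sample(as.vector(ft$idx), config$codon_length, replace = TRUE)
    } else {
      root <- dna_to_codons(root_seq)
      if (length(root) != config$codon_length)
        stop("root sequence must have codon_length = ", config$codon_length, " codons")
      if (any(ct$stop[root])) stop("root sequence contains a stop codon")
      if (anyNA(ft$aa_of[root])) {
        # project foreign codons onto the simulator alphabet, keeping pos3
        aa <- ft$aa_of[root]
        aa[is.na(aa)] <- sample.int(6, sum(is.na(aa)), replace = TRUE)
        pos3 <- ((root - 1) %% 4) + 1
        root <- ft$idx[cbind(aa, pos3)]
      }
    }
    if (is.null(gene_tree)) stop("gene_tree is NULL")
    if (inherits(gene_tree, "phylo")) {
      tr <- ape::reorder.phylo(gene_tree, "cladewise")
      n_tip <- ape::Ntip(tr)
      seqs <- vector("list", n_tip + tr$Nnode)
      root_node <- n_tip + 1L
      seqs[[root_node]] <- root
      out <- character(n_tip)
      for (k in seq_len(nrow(tr$edge))) {
        p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
        seqs[[ch]] <- evolve_branch(seqs[[p]], tr$edge.length[k], config$kappa, config$omega)
        if (ch <= n_tip) out[ch] <- codons_to_dna(seqs[[ch]])
      }
      names(out) <- tr$tip.label
      out
    } else stop("gene_tree must be an ape phylo tree")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# CDS for a single-gene family (no tree): root evolved down the root-to-tip
# distance is not defined without a tree, so the gene simply receives an
# independent random sequence (its Ks to everything else is effectively
# infinite, which matches a singleton family).
random_cds <- function(config) {
  ft <- fourfold_tables()
  codons_to_dna(sample(as.vector(ft$idx), config$codon_length, replace = TRUE))
}

#' Translate CDS to protein
#'
#' @param cds named character vector of coding sequences.
#' @return named character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) codons_to_aa(dna_to_codons(s)), character(1))
}
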