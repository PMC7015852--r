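# Paranome and orthologue inference from protein similarity evidence:
# all-against-all scoring (builtin global-alignment scoring with an exact
# k-mer seed prefilter, or externally computed tabular hits), Markov
# clustering into gene families, reciprocal-best-hit one-to-one
# orthologues, and low-copy-nuclear (LCN) family selection.

# Karlin-Altschul-style scale for a match/mismatch scoring scheme given a
# match probability p: solve p*e^(2L) + (1-p)*e^(-L) = 1 for L > 0.
ka_lambda <- function(p, match = 2, mismatch = -1) {
  if (p * match + (1 - p) * mismatch >= 0)
    stop("scoring scheme has nonnegative expected score; cannot calibrate significance")
  f <- function(l) p * exp(match * l) + (1 - p) * exp(mismatch * l) - 1
  stats::uniroot(f, c(1e-6, 5))$root
}

score_to_evalue <- function(score, len_a, len_b, lambda, K = 0.1) {
  K * as.numeric(len_a) * as.numeric(len_b) * exp(-lambda * pmax(score, 0)) +
    ifelse(score <= 0, 0, 0)
}

# Candidate pair generation by shared exact amino-acid k-mers.
seed_candidate_pairs <- function(seqs, k = 6, min_shared = 2) {
  n <- length(seqs)
  kmer_list <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  gene_idx <- rep.int(seq_len(n), lengths(kmer_list))
  buckets <- split(gene_idx, unlist(kmer_list))
  buckets <- buckets[lengths(buckets) >= 2 & lengths(buckets) <= 200]
  if (length(buckets) == 0) return(data.frame(i = integer(0), j = integer(0)))
  keys <- unlist(lapply(buckets, function(g) {
    g <- sort.int(g)
    p <- utils::combn(g, 2)
    p[1, ] * (n + 1) + p[2, ]
  }), use.names = FALSE)
  counts <- table(keys)
  hit <- as.numeric(names(counts)[counts >= min_shared])
  if (length(hit) == 0) return(data.frame(i = integer(0), j = integer(0)))
  data.frame(i = as.integer(hit %/% (n + 1)), j = as.integer(hit %% (n + 1)))
}

# Global alignment score of two proteins. Equal-length pairs are scored
# position-wise (match/mismatch); unequal lengths go through
# Needleman-Wunsch with affine gaps via Biostrings.
align_score <- function(a, b, match = 2, mismatch = -1,
                        gap_open = 5, gap_ext = 1) {
  if (nchar(a) == nchar(b)) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    sum(ifelse(va == vb, match, mismatch))
  } else {
    alphabet <- union(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
    m <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
    diag(m) <- match
    as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_ext,
      scoreOnly = TRUE))
  }
}

#' All-against-all protein similarity edges
#'
#' `mode = "builtin"` computes deterministic global-alignment scores
#' (match/mismatch scoring with affine gaps for unequal lengths) over
#' candidate pairs sharing at least `min_shared_kmers` exact `seed_k`-mers,
#' and converts scores to an E-value-like significance with
#' Karlin-Altschul statistics on the empirical residue composition.
#' `mode = "file"` reads a 12-column BLAST `outfmt6`-style tabular file
#' (columns 1, 2, 11, 12: query, subject, E-value, bit score).
#' Edges with significance above `threshold` are removed and the edge set
#' is symmetrized (the better direction is kept); self-edges are dropped.
#'
#' @param proteins named character vector of protein sequences
#'   (builtin mode) or `NULL`.
#' @param mode "builtin" or "file".
#' @param path tabular hit file (file mode).
#' @param threshold significance cutoff (default `1e-10`).
#' @param seed_k,min_shared_kmers seed prefilter parameters.
#' @return data.frame (`similarity_edges`): gene_a, gene_b, score,
#'   significance, with gene_a < gene_b lexicographically.
#' @export
pairwise_similarity <- function(proteins = NULL, mode = c("builtin", "file"),
                                path = NULL, threshold = 1e-10,
                                seed_k = 6, min_shared_kmers = 2) {
  mode <- match.arg(mode)
  if (mode == "file") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t")
    bad <- which(vapply(parts, length, integer(1)) < 12)
    if (length(bad)) stop("malformed tabular hit line ", bad[1], " (need 12 columns)")
    edges <- data.frame(
      gene_a = vapply(parts, `[[`, character(1), 1),
      gene_b = vapply(parts, `[[`, character(1), 2),
      significance = as.numeric(vapply(parts, `[[`, character(1), 11)),
      score = as.numeric(vapply(parts, `[[`, character(1), 12)),
      stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(names(proteins)))
    empty <- nchar(proteins) == 0
    if (any(empty)) {
      warning("skipping ", sum(empty), " empty sequence(s)")
      proteins <- proteins[!empty]
    }
    cand <- seed_candidate_pairs(proteins, k = seed_k, min_shared = min_shared_kmers)
    if (nrow(cand) == 0)
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        score = numeric(0), significance = numeric(0)))
    # match probability from the overall residue composition
    comp <- table(strsplit(paste(proteins, collapse = ""), "")[[1]])
    p_match <- sum((comp / sum(comp))^2)
    lambda <- ka_lambda(p_match)
    ids <- names(proteins)
    score <- numeric(nrow(cand))
    lens <- nchar(proteins)
    eq <- lens[cand$i] == lens[cand$j]
    # equal-length scoring on pre-split character vectors
    if (any(eq)) {
      chars <- strsplit(proteins, "")
      sub <- which(eq)
      score[sub] <- vapply(sub, function(r) {
        va <- chars[[cand$i[r]]]; vb <- chars[[cand$j[r]]]
        n_id <- sum(va == vb)
        2 * n_id - (length(va) - n_id)
      }, numeric(1))
    }
    for (r in which(!eq))
      score[r] <- align_score(proteins[[cand$i[r]]], proteins[[cand$j[r]]])
    edges <- data.frame(
      gene_a = ids[cand$i], gene_b = ids[cand$j], score = score,
      significance = score_to_evalue(score, lens[cand$i], lens[cand$j], lambda),
      stringsAsFactors = FALSE)
  }
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]; edges$gene_a[swap] <- edges$gene_b[swap]; edges$gene_b[swap] <- tmp
  # keep best direction per unordered pair
  o <- order(edges$gene_a, edges$gene_b, edges$significance, -edges$score)
  edges <- edges[o, , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  edges <- edges[edges$significance <= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write / read similarity edges as 12-column tabular hits
#'
#' The BLAST `outfmt6` dialect: only query, subject, E-value and bit score
#' are meaningful; the other columns are placeholders.
#' @param edges data.frame from [pairwise_similarity()].
#' @param path file path.
#' @export
write_hits <- function(edges, path) {
  n <- nrow(edges)
  tab <- data.frame(edges$gene_a, edges$gene_b, rep(100, n), rep(0, n),
                    rep(0, n), rep(0, n), rep(0, n), rep(0, n), rep(0, n),
                    rep(0, n), edges$significance, edges$score)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Markov clustering of the similarity graph into gene families
#'
#' Column-normalized expansion/inflation iterations on each connected
#' component of the (score-weighted) similarity graph until convergence;
#' attractor overlap defines the clusters. Genes without edges come back
#' as singleton families. Deterministic given the edge set.
#'
#' @param edges data.frame with gene_a, gene_b, score.
#' @param genes optional full gene universe (adds edge-less singletons).
#' @param inflation inflation exponent (> 1, default 2).
#' @param max_iter iteration cap; on non-convergence the component falls
#'   back to its connected components, with a warning.
#' @return data.frame `family_id`, `gene_id`.
#' @export
cluster_families <- function(edges, genes = NULL, inflation = 2, max_iter = 100) {
  stopifnot(inflation > 1)
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = genes)
  igraph::E(g)$weight <- pmax(edges$score, 1e-6)
  comp <- igraph::components(g)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) == 1) { clusters[[length(clusters) + 1L]] <- vs; next }
    sub <- igraph::induced_subgraph(g, vs)
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    cl <- mcl_cluster(A, inflation, max_iter)
    if (is.null(cl)) {
      warning("MCL did not converge on a component of size ", length(vs),
              "; using connected component as one family")
      clusters[[length(clusters) + 1L]] <- vs
    } else {
      for (m in cl) clusters[[length(clusters) + 1L]] <- rownames(A)[m]
    }
  }
  # order clusters by their lexicographically smallest member for determinism
  clusters <- clusters[order(vapply(clusters, function(x) sort(x)[1], character(1)))]
  do.call(rbind, lapply(seq_along(clusters), function(i) data.frame(
    family_id = sprintf("fam%05d", i), gene_id = sort(clusters[[i]]),
    stringsAsFactors = FALSE)))
}

# Dense MCL on one adjacency matrix; returns list of integer index vectors
# or NULL on non-convergence.
mcl_cluster <- function(A, inflation, max_iter) {
  n <- nrow(A)
  diag(A) <- pmax(apply(A, 2, max), 1e-6)  # self-loops
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                 # expansion
    M2 <- M2^inflation            # inflation
    M2[M2 < 1e-8] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
    if (it == max_iter) return(NULL)
  }
  attract <- which(rowSums(M > 1e-4) > 0)
  groups <- list()
  assigned <- rep(FALSE, n)
  for (a in attract) {
    mem <- which(M[a, ] > 1e-4 | seq_len(n) == a)
    hit <- which(vapply(groups, function(gr) any(gr %in% mem), logical(1)))
    if (length(hit)) {
      merged <- sort(unique(c(unlist(groups[hit]), mem)))
      groups <- groups[-hit]
      groups[[length(groups) + 1L]] <- merged
    } else groups[[length(groups) + 1L]] <- mem
    assigned[mem] <- TRUE
  }
  for (v in which(!assigned)) groups[[length(groups) + 1L]] <- v
  groups
}

#' Reciprocal-best-hit one-to-one orthologues between two species
#'
#' A pair (a, b) is returned iff b is a's best-scoring hit in species B
#' and a is b's best in species A. Score ties are broken by lexicographic
#' gene id and reported via an attribute.
#'
#' @param edges similarity edges (any direction; symmetric input fine).
#' @param species_of named character vector mapping gene id -> species.
#' @param species_a,species_b the two species.
#' @return data.frame gene_a (species A), gene_b (species B), score;
#'   attribute `ties` counts tie-broken best hits.
#' @export
reciprocal_best_orthologs <- function(edges, species_of, species_a, species_b) {
  sa <- species_of[edges$gene_a]; sb <- species_of[edges$gene_b]
  sel <- (sa == species_a & sb == species_b) | (sa == species_b & sb == species_a)
  e <- edges[which(sel), , drop = FALSE]
  if (nrow(e) == 0)
    return(structure(data.frame(gene_a = character(0), gene_b = character(0),
                                score = numeric(0)), ties = 0L))
  flip <- species_of[e$gene_a] != species_a
  ga <- ifelse(flip, e$gene_b, e$gene_a)
  gb <- ifelse(flip, e$gene_a, e$gene_b)
  d <- data.frame(a = ga, b = gb, score = e$score, stringsAsFactors = FALSE)
  best_of <- function(keys, others, scores) {
    o <- order(keys, -scores, others)   # best score first, lexicographic ties
    first <- !duplicated(keys[o])
    tie_ct <- 0L
    ko <- keys[o]; so <- scores[o]
    idx <- which(first)
    for (i in idx) {
      j <- i + 1L
      if (j <= length(ko) && ko[j] == ko[i] && so[j] == so[i]) tie_ct <- tie_ct + 1L
    }
    list(best = setNames(others[o][first], ko[first]), ties = tie_ct)
  }
  ba <- best_of(d$a, d$b, d$score)   # best hit in B for each a
  bb <- best_of(d$b, d$a, d$score)   # best hit in A for each b
  a_ids <- names(ba$best)
  keep <- !is.na(bb$best[ba$best]) & bb$best[ba$best] == a_ids
  pairs <- data.frame(gene_a = a_ids[keep], gene_b = unname(ba$best[keep]),
                      stringsAsFactors = FALSE)
  sc <- setNames(d$score, paste0(d$a, "\r", d$b))
  pairs$score <- unname(sc[paste0(pairs$gene_a, "\r", pairs$gene_b)])
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, ties = ba$ties + bb$ties)
}

#' Copy-number matrix of gene families
#'
#' @param families data.frame family_id, gene_id.
#' @param species_of named map gene id -> species.
#' @param species optional species universe (absent species = 0 copies).
#' @return integer matrix families x species.
#' @export
family_copy_number <- function(families, species_of, species = NULL) {
  sp <- species_of[families$gene_id]
  species <- species %||% sort(unique(sp))
  tab <- table(factor(families$family_id), factor(sp, levels = species))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m
}

#' Select low-copy nuclear (LCN) families
#'
#' A family is selected iff it is strictly single-copy in every
#' `focal_single` species and single-copy in at least
#' `min_single_in_panel` of the `panel` species.
#'
#' @param copy_number matrix families x species (counts; absent = 0).
#' @param focal_single species that must all have exactly one copy.
#' @param panel species panel for the relaxed criterion.
#' @param min_single_in_panel minimum panel species with exactly one copy
#'   (default 5).
#' @return character vector of selected family ids.
#' @export
select_lcn_families <- function(copy_number, focal_single, panel,
                                min_single_in_panel = 5) {
  need <- c(focal_single, panel)
  missing <- setdiff(need, colnames(copy_number))
  if (length(missing))
    stop("species absent from copy-number table: ", paste(missing, collapse = ", "))
  ok_focal <- rowSums(copy_number[, focal_single, drop = FALSE] == 1) == length(focal_single)
  ok_panel <- rowSums(copy_number[, panel, drop = FALSE] == 1) >= min_single_in_panel
  rownames(copy_number)[ok_focal & ok_panel]
}
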