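# Independent brute-force oracles used to verify the optimized
# implementations on small instances.

# All valid chains (gap-bounded, strictly increasing on both axes) by
# exhaustive depth-first enumeration; returns the best chain under the
# same tie rule as the DP (max length, then lexicographically smallest
# (ra, rb) sequence) or NULL if none reaches min_len.
oracle_best_chain <- function(ra, rb, max_gap, min_len, active) {
  idx <- which(active)
  if (length(idx) == 0) return(NULL)
  o <- idx[order(ra[idx], rb[idx])]
  best <- NULL
  seq_better <- function(a, b) {     # is chain a better than b?
    if (is.null(b)) return(TRUE)
    if (length(a) != length(b)) return(length(a) > length(b))
    ka <- rbind(ra[a], rb[a]); kb <- rbind(ra[b], rb[b])
    for (i in seq_len(ncol(ka))) {
      if (ka[1, i] != kb[1, i]) return(ka[1, i] < kb[1, i])
      if (ka[2, i] != kb[2, i]) return(ka[2, i] < kb[2, i])
    }
    FALSE
  }
  extend <- function(chain) {
    last <- chain[length(chain)]
    nxt <- o[ra[o] > ra[last] & rb[o] > rb[last] &
               ra[o] - ra[last] <= max_gap & rb[o] - rb[last] <= max_gap]
    if (seq_better(chain, best)) best <<- chain
    for (j in nxt) extend(c(chain, j))
  }
  for (s in o) extend(s)
  if (is.null(best) || length(best) < min_len) NULL else best
}

# Greedy chain extraction by exhaustive search (mirror of the DP's
# extraction loop, but with enumeration instead of DP).
oracle_chains <- function(ra, rb, max_gap = 20, min_len = 4) {
  active <- rep(TRUE, length(ra))
  out <- list()
  repeat {
    ch <- oracle_best_chain(ra, rb, max_gap, min_len, active)
    if (is.null(ch)) break
    out[[length(out) + 1L]] <- ch
    active[ch] <- FALSE
  }
  out
}

# Brute-force reciprocal best hits on a bipartite score matrix.
oracle_rbh <- function(scores, a_ids, b_ids) {
  pairs <- list()
  for (i in seq_along(a_ids)) {
    s <- scores[i, ]
    bestb <- b_ids[order(-s, b_ids)][1]
    j <- match(bestb, b_ids)
    besta <- a_ids[order(-scores[, j], a_ids)][1]
    if (besta == a_ids[i]) pairs[[length(pairs) + 1L]] <- c(a_ids[i], bestb)
  }
  do.call(rbind, pairs)
}

# Transitive closure components of a thresholded Ks matrix (naive
# Floyd-Warshall-style reachability).
oracle_components <- function(ks, threshold) {
  n <- nrow(ks)
  adj <- !is.na(ks) & !is.nan(ks) & ks <= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  groups <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  lapply(strsplit(groups, ","), function(g) sort(rownames(ks)[as.integer(g)]))
}

# Reference Markov clustering (independent straightforward implementation
# with the same algorithm definition) used on hand-sized matrices.
oracle_mcl <- function(A, inflation = 2, iter = 200) {
  diag(A) <- pmax(apply(A, 2, max), 1e-6)
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iter)) {
    M <- M %*% M
    M <- M^inflation
    M[M < 1e-8] <- 0
    M <- sweep(M, 2, pmax(colSums(M), 1e-12), "/")
  }
  comp <- list()
  for (r in which(rowSums(M > 1e-4) > 0)) {
    mem <- sort(unique(c(r, which(M[r, ] > 1e-4))))
    hit <- which(vapply(comp, function(g) any(g %in% mem), logical(1)))
    if (length(hit)) {
      comp[[hit[1]]] <- sort(unique(c(unlist(comp[hit]), mem)))
      comp <- comp[-setdiff(hit, hit[1])]
    } else comp[[length(comp) + 1L]] <- mem
  }
  comp
}

# Brute-force node classification against the species tree by direct
# species-set logic (independent of classify_nodes internals).
oracle_classify <- function(tree, sptree, species_of) {
  n_tip <- ape::Ntip(tree)
  sp_set <- function(nd) {
    tips <- if (nd <= n_tip) nd else phangorn::Descendants(tree, nd, "tips")[[1]]
    unique(unname(species_of[tree$tip.label[tips]]))
  }
  img <- function(sps) {
    t2 <- match(sps, sptree$tip.label)
    if (length(t2) == 1) t2 else ape::getMRCA(sptree, t2)
  }
  res <- character(tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    nd <- n_tip + k
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    sa <- sp_set(ch[1]); sb <- sp_set(ch[2])
    if (length(intersect(sa, sb))) { res[k] <- "duplication"; next }
    im <- img(union(sa, sb))
    res[k] <- if (img(sa) != im && img(sb) != im) "speciation" else "inconsistent"
  }
  res
}

# Exhaustive one-to-one block screening optimum (max total score over
# pairwise-compatible subsets).
oracle_screen_optimum <- function(blocks) {
  n <- nrow(blocks)
  conflict <- matrix(FALSE, n, n)
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    conflict[i, j] <-
      ov(blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i],
         blocks$chrom_a[j], blocks$start_a[j], blocks$end_a[j]) ||
      ov(blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i],
         blocks$chrom_b[j], blocks$start_b[j], blocks$end_b[j]) ||
      ov(blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i],
         blocks$chrom_b[j], blocks$start_b[j], blocks$end_b[j]) ||
      ov(blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i],
         blocks$chrom_a[j], blocks$start_a[j], blocks$end_a[j])
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1 && any(conflict[sel, sel])) next
    sc <- sum(blocks$n_pairs[sel])
    if (sc > best) best <- sc
  }
  best
}
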