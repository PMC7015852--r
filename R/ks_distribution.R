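# Redundancy-corrected paranome Ks age distributions and peak inference.
#
# A gene family of n members yields n(n-1)/2 pairwise Ks estimates but
# only n-1 duplication events; to correct for this redundancy each family
# is split into subfamilies at Ks <= 5, a subfamily tree is built, and for
# every duplication node the m cross-clade pair estimates enter the
# distribution with weight 1/m, so each duplication event contributes
# total weight one.

#' Split a family into subfamilies at a Ks threshold
#'
#' Connected components of the graph whose edges are unsaturated pairs
#' with Ks <= threshold. Singleton components are dropped (they contribute
#' no pairs to the distribution).
#'
#' @param ks_matrix symmetric Ks matrix (`NaN`/`NA` = saturated pair).
#' @param threshold subfamily threshold (default 5).
#' @return list of character vectors (members), each of size >= 2.
#' @export
split_subfamilies <- function(ks_matrix, threshold = 5) {
  stopifnot(threshold > 0, nrow(ks_matrix) == ncol(ks_matrix))
  ids <- rownames(ks_matrix)
  n <- length(ids)
  adj <- !is.na(ks_matrix) & !is.nan(ks_matrix) & ks_matrix <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  out <- split(ids, comp)
  out <- out[vapply(out, length, integer(1)) >= 2]
  unname(lapply(out, sort))
}

#' Neighbor-joining subfamily tree from a Ks matrix
#'
#' Midpoint-rooted NJ topology on the pairwise Ks distances; negative NJ
#' branch lengths are clamped to zero. Deterministic: members are taken
#' in lexicographic order.
#'
#' @param ks_matrix symmetric finite Ks matrix restricted to one subfamily.
#' @return rooted [ape::phylo] (a 2-member subfamily gives a cherry).
#' @export
build_subfamily_tree <- function(ks_matrix) {
  ids <- sort(rownames(ks_matrix))
  m <- ks_matrix[ids, ids, drop = FALSE]
  if (any(!is.finite(m))) stop("non-finite Ks entries; filter saturated pairs first")
  if (length(ids) < 2) stop("need >= 2 members")
  if (length(ids) == 2) {
    d <- m[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", ids[1], d / 2, ids[2], d / 2)))
  }
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  tr
}

#' Node-weighted Ks values from a subfamily tree
#'
#' For each internal (duplication) node with child clades A and B, the
#' m = |A|*|B| cross-clade pair estimates are emitted with weight 1/m;
#' every pair appears at exactly one node (the MRCA of its two genes), so
#' per-node weights sum to one and a subfamily of n members contributes
#' total weight n-1.
#'
#' @param tree rooted subfamily tree.
#' @param ks_matrix symmetric Ks matrix covering the tree's leaves.
#' @param family_id optional family label carried into the output.
#' @return data.frame ks, weight, family_id, node_id.
#' @export
node_weighted_distribution <- function(tree, ks_matrix, family_id = NA_character_) {
  stopifnot(all(tree$tip.label %in% rownames(ks_matrix)))
  n_tip <- ape::Ntip(tree)
  rows <- list()
  kids <- phangorn::Descendants(tree, (n_tip + 1):(n_tip + tree$Nnode), type = "tips")
  children_of <- lapply((n_tip + 1):(n_tip + tree$Nnode),
                        function(nd) tree$edge[tree$edge[, 1] == nd, 2])
  for (k in seq_len(tree$Nnode)) {
    ch <- children_of[[k]]
    if (length(ch) != 2) next
    tips_l <- if (ch[1] <= n_tip) ch[1] else kids[[ch[1] - n_tip]]
    tips_r <- if (ch[2] <= n_tip) ch[2] else kids[[ch[2] - n_tip]]
    A <- tree$tip.label[tips_l]; B <- tree$tip.label[tips_r]
    m <- length(A) * length(B)
    vals <- as.vector(ks_matrix[A, B, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      ks = vals, weight = 1 / m, family_id = family_id,
      node_id = paste0(family_id, ":node", k + n_tip),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the node-weighted paranome Ks distribution
#'
#' Convenience wrapper: for each family runs subfamily splitting, tree
#' building, and node weighting, concatenating the weighted values.
#'
#' @param family_matrices named list of symmetric Ks matrices (one per
#'   family, as `family_ks_matrix()$ks`).
#' @param threshold subfamily split threshold (default 5).
#' @return data.frame ks, weight, family_id, node_id.
#' @export
weighted_paranome_distribution <- function(family_matrices, threshold = 5) {
  rows <- list()
  for (fid in names(family_matrices)) {
    ksm <- family_matrices[[fid]]
    if (is.null(dim(ksm)) || nrow(ksm) < 2) next
    for (sub in split_subfamilies(ksm, threshold)) {
      m <- ksm[sub, sub, drop = FALSE]
      m[!is.finite(m)] <- threshold * 2  # saturated within-component pairs: flat cap
      tr <- build_subfamily_tree(m)
      w <- node_weighted_distribution(tr, ksm[sub, sub, drop = FALSE], fid)
      rows[[length(rows) + 1L]] <- w
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ks = numeric(0), weight = numeric(0),
               family_id = character(0), node_id = character(0))
  # saturated pairs may still surface as NaN values at deep nodes: drop them
  out[is.finite(out$ks), , drop = FALSE]
}

# Silverman's rule on a weighted sample (effective sample size).
silverman_bw <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  s <- sqrt(sum(w * (x - mu)^2))
  qs <- weighted_quantile(x, w, c(0.25, 0.75))
  iqr <- diff(qs)
  n_eff <- 1 / sum(w^2)
  spread <- min(s, iqr / 1.34)
  if (spread <= 0) spread <- max(s, 1e-3)
  0.9 * spread * n_eff^(-1 / 5)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# Weighted Gaussian KDE mode on a fixed grid.
kde_mode <- function(x, w, from, to, bw, n_grid = 512) {
  d <- stats::density(x, weights = w / sum(w), bw = bw, from = from, to = to,
                      n = n_grid)
  d$x[which.max(d$y)]
}

#' KDE peak location with bootstrap confidence interval
#'
#' Weighted Gaussian kernel density on a 512-point grid over `ks_range`;
#' the mode is the grid argmax. The confidence interval is the percentile
#' interval of modes over `n_boot` bootstrap resamples of the values
#' (weights carried along). Deterministic given `seed`.
#'
#' @param ks weighted Ks values (data.frame with `ks`, `weight`, or a
#'   numeric vector).
#' @param weights weights if `ks` is a numeric vector.
#' @param ks_range analysis range, default (0.05, 5].
#' @param bandwidth kernel bandwidth; default Silverman's rule on the
#'   weighted sample restricted to the range.
#' @param n_boot bootstrap replicates (default 200).
#' @param ci confidence level (default 0.90).
#' @param seed integer seed for the bootstrap.
#' @param min_values minimum values within range (default 30).
#' @return list of class `ks_peak`: mode, bandwidth, ci_low, ci_high,
#'   ci_level, n_values, ci_contains_mode.
#' @export
kde_peak_ci <- function(ks, weights = NULL, ks_range = c(0.05, 5),
                        bandwidth = NULL, n_boot = 200, ci = 0.90,
                        seed = 1L, min_values = 30) {
  if (is.data.frame(ks)) { weights <- ks$weight; ks <- ks$ks }
  if (is.null(weights)) weights <- rep(1, length(ks))
  sel <- is.finite(ks) & ks > ks_range[1] & ks <= ks_range[2]
  x <- ks[sel]; w <- weights[sel]
  if (length(x) < min_values)
    stop("only ", length(x), " Ks values inside (", ks_range[1], ", ", ks_range[2],
         "]; need >= ", min_values, " - consider widening ks_range")
  if (max(x) - min(x) < 1e-12) {
    out <- list(mode = x[1], bandwidth = 0, ci_low = x[1], ci_high = x[1],
                ci_level = ci, n_values = length(x), ci_contains_mode = TRUE)
    class(out) <- "ks_peak"
    return(out)
  }
  bw <- bandwidth %||% silverman_bw(x, w)
  mode <- kde_mode(x, w, ks_range[1], ks_range[2], bw)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      kde_mode(x[idx], w[idx], ks_range[1], ks_range[2], bw)
    }, numeric(1))
  })
  alpha <- (1 - ci) / 2
  qs <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  out <- list(mode = mode, bandwidth = bw, ci_low = qs[1], ci_high = qs[2],
              ci_level = ci, n_values = length(x),
              ci_contains_mode = qs[1] <= mode && mode <= qs[2])
  if (!out$ci_contains_mode)
    warning("bootstrap CI does not contain the point estimate")
  class(out) <- "ks_peak"
  out
}

#' @export
print.ks_peak <- function(x, ...) {
  cat(sprintf("Ks peak: mode %.4f (bw %.4f), %d%% CI [%.4f, %.4f], n = %d\n",
              x$mode, x$bandwidth, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$n_values))
  invisible(x)
}

#' Compare the paralogue WGD peak with orthologue divergence modes
#'
#' For each species pair the orthologue Ks KDE mode (a speciation age on
#' the Ks scale) is computed and compared with the paralogue peak: a WGD
#' younger than a divergence has a smaller Ks mode.
#'
#' @param ortholog_ks named list: species-pair label -> numeric Ks values.
#' @param paralog_peak the paralogue peak mode (number or `ks_peak`).
#' @param ks_range,bandwidth,min_values KDE parameters; pairs with fewer
#'   than `min_values` values are omitted with a warning.
#' @return data.frame comparison, mode, n, wgd_younger, ordered by mode,
#'   with attribute `paralog_mode`.
#' @export
compare_ortholog_ks <- function(ortholog_ks, paralog_peak,
                                ks_range = c(0.05, 5), bandwidth = NULL,
                                min_values = 30) {
  pk <- if (inherits(paralog_peak, "ks_peak")) paralog_peak$mode else paralog_peak
  rows <- list()
  for (lab in sort(names(ortholog_ks))) {
    v <- ortholog_ks[[lab]]
    v <- v[is.finite(v)]
    in_range <- v[v > ks_range[1] & v <= ks_range[2]]
    if (length(in_range) < min_values) {
      warning("species pair ", lab, " has only ", length(in_range),
              " usable Ks values; omitted")
      next
    }
    if (max(in_range) - min(in_range) < 1e-12) {
      md <- in_range[1]
    } else {
      w <- rep(1, length(in_range))
      bw <- bandwidth %||% silverman_bw(in_range, w)
      md <- kde_mode(in_range, w, ks_range[1], ks_range[2], bw)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = lab, mode = md, n = length(in_range),
      wgd_younger = pk < md, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "paralog_mode") <- pk
  out
}

#' Relative substitution rates from a shared outgroup
#'
#' Orthologue Ks between each ingroup species and one shared outgroup all
#' contain the same outgroup path, so a larger mode means a faster
#' ingroup lineage. Reports per-species modes ranked fastest first.
#'
#' @param outgroup outgroup species name.
#' @param ortholog_ks named list: ingroup species -> Ks values vs the
#'   outgroup.
#' @param ks_range,bandwidth,min_values KDE parameters.
#' @return data.frame species, mode, n, rank (1 = fastest), sorted by
#'   species name.
#' @export
relative_rates <- function(outgroup, ortholog_ks, ks_range = c(0.05, 5),
                           bandwidth = NULL, min_values = 30) {
  if (length(ortholog_ks) == 0) stop("no orthologue Ks data for outgroup ", outgroup)
  cmp <- compare_ortholog_ks(ortholog_ks, paralog_peak = Inf,
                             ks_range = ks_range, bandwidth = bandwidth,
                             min_values = min_values)
  out <- data.frame(species = cmp$comparison, mode = cmp$mode, n = cmp$n,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mode, ties.method = "min")
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, outgroup = outgroup)
}

#' Least-squares branch lengths in Ks units
#'
#' Given a fixed rooted topology and observed pairwise orthologue Ks
#' modes, fits nonnegative branch lengths minimizing the squared
#' deviation between tree path sums and the observed modes.
#'
#' @param topology rooted binary [ape::phylo] (branch lengths ignored).
#' @param pair_modes data.frame species_a, species_b, ks (one row per
#'   leaf pair; every leaf pair required for exact recovery, at least as
#'   many pairs as branches for identifiability).
#' @return list: `tree` (topology with fitted edge lengths), `lengths`
#'   (per-branch, named by child node), `residuals`, `clamped` (branches
#'   whose unconstrained estimate was negative).
#' @export
fit_branch_ks <- function(topology, pair_modes) {
  tr <- topology
  n_tip <- ape::Ntip(tr)
  labs <- c(tr$tip.label, tr$node.label %||% paste0("n", seq_len(tr$Nnode)))
  n_edge <- nrow(tr$edge)
  if (nrow(pair_modes) < n_edge)
    stop("under-determined: ", nrow(pair_modes), " pairs for ", n_edge, " branches")
  # path indicator matrix
  A <- matrix(0, nrow(pair_modes), n_edge)
  y <- pair_modes$ks
  for (r in seq_len(nrow(pair_modes))) {
    i <- match(pair_modes$species_a[r], tr$tip.label)
    j <- match(pair_modes$species_b[r], tr$tip.label)
    if (is.na(i) || is.na(j)) stop("species not in topology: ",
                                   pair_modes$species_a[r], "/", pair_modes$species_b[r])
    p <- ape::nodepath(tr, i, j)
    for (q in seq_len(length(p) - 1)) {
      e <- which((tr$edge[, 1] == p[q] & tr$edge[, 2] == p[q + 1]) |
                 (tr$edge[, 1] == p[q + 1] & tr$edge[, 2] == p[q]))
      A[r, e] <- 1
    }
  }
  ls <- tryCatch(stats::lm.fit(A, y)$coefficients, error = function(e) rep(NA_real_, n_edge))
  fit <- pracma::lsqnonneg(A, y)
  lens <- fit$x
  tr$edge.length <- lens
  resid <- y - as.vector(A %*% lens)
  names(lens) <- labs[tr$edge[, 2]]
  clamped <- names(lens)[!is.na(ls) & ls < -1e-8 & lens <= 1e-12]
  list(tree = tr, lengths = lens, residuals = resid, clamped = clamped)
}
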