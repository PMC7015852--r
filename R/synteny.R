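# Collinear (syntenic) block detection in gene-rank space.
#
# Matches between two chromosomes are chained by sparse dynamic
# programming: a chain is a set of matches whose ranks are strictly
# increasing on genome A and strictly monotone (increasing for "+",
# decreasing for "-") on genome B, with consecutive rank gaps of at most
# max_gap on both axes. Chains shorter than min_len are discarded.
# Matches are assigned greedily to the highest-scoring chain, then the
# remainder is re-chained.

#' Build gene orders from a table or GFF3
#'
#' @param x data.frame with columns gene_id, species, chromosome, rank
#'   (0-based; recomputed per chromosome if missing or non-consecutive),
#'   optional strand; or a path to a GFF3 file, in which case the rank of
#'   a gene is the order of `gene` features along each seqid and
#'   `species` must be supplied.
#' @param species species name for GFF3 input.
#' @return data.frame gene_id, species, chromosome, rank, strand
#'   (class `gene_order`).
#' @export
gene_order <- function(x, species = NULL) {
  if (is.character(x) && length(x) == 1) {
    stopifnot(!is.null(species))
    lines <- readLines(x)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t")
    bad <- which(vapply(f, length, integer(1)) < 9)
    if (length(bad)) stop("malformed GFF3 line ", bad[1])
    keep <- vapply(f, function(v) v[3] == "gene", logical(1))
    f <- f[keep]
    ids <- vapply(f, function(v) {
      m <- regmatches(v[9], regexec("ID=([^;]+)", v[9]))[[1]]
      if (length(m) < 2) stop("GFF3 gene feature without ID attribute")
      m[2]
    }, character(1))
    df <- data.frame(gene_id = ids,
                     species = species,
                     chromosome = vapply(f, `[[`, character(1), 1),
                     start = as.numeric(vapply(f, `[[`, character(1), 4)),
                     strand = vapply(f, `[[`, character(1), 7),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chromosome, df$start), ]
    x <- df[, c("gene_id", "species", "chromosome", "strand")]
  }
  stopifnot(all(c("gene_id", "species", "chromosome") %in% names(x)))
  if (is.null(x$strand)) x$strand <- "+"
  if (!is.null(x$rank)) x <- x[order(x$species, x$chromosome, x$rank), ]
  parts <- split(seq_len(nrow(x)), paste(x$species, x$chromosome, sep = "\r"))
  for (p in parts) x$rank[p] <- seq_along(p) - 1L
  if (anyDuplicated(paste(x$species, x$gene_id)))
    stop("gene ids must be unique within a species")
  rownames(x) <- NULL
  class(x) <- c("gene_order", "data.frame")
  x[, c("gene_id", "species", "chromosome", "rank", "strand")]
}

# Collapse tandem arrays: within one chromosome, genes of the same family
# at consecutive ranks (gap <= tandem_gap) are represented by the
# lowest-rank member. Returns the representative map gene -> gene.
collapse_tandem <- function(orders, family_of, tandem_gap = 1) {
  rep_map <- setNames(orders$gene_id, orders$gene_id)
  fams <- family_of[orders$gene_id]
  key <- paste(orders$species, orders$chromosome, sep = "\r")
  for (p in split(seq_len(nrow(orders)), key)) {
    p <- p[order(orders$rank[p])]
    f <- fams[p]
    if (all(is.na(f))) next
    run_rep <- NA_character_; run_fam <- NA_character_; run_rank <- -10
    for (i in p) {
      fi <- fams[i]
      if (!is.na(fi) && !is.na(run_fam) && fi == run_fam &&
          orders$rank[i] - run_rank <= tandem_gap) {
        rep_map[orders$gene_id[i]] <- run_rep
        run_rank <- orders$rank[i]
      } else {
        run_rep <- orders$gene_id[i]; run_fam <- fi; run_rank <- orders$rank[i]
      }
    }
  }
  rep_map
}

# DP chaining of matches on one chromosome pair and one orientation.
# m: ra, rb (rb already negated for "-"). Returns list of integer index
# vectors (chains), extracted greedily best-first. Tie-break: longest
# chain, then the lexicographically smallest (ra, rb) match sequence
# (hence smallest start rank on genome A first).
chain_dp <- function(ra, rb, max_gap, min_len) {
  n <- length(ra)
  active <- rep(TRUE, n)
  chains <- list()
  link_ok <- function(i, j) {       # can chain step i -> j
    ra[j] > ra[i] && rb[j] > rb[i] &&
      ra[j] - ra[i] <= max_gap && rb[j] - rb[i] <= max_gap
  }
  repeat {
    idx <- which(active)
    if (length(idx) < min_len) break
    o <- idx[order(ra[idx], rb[idx])]
    L <- length(o)
    f <- rep(1L, L)                 # longest chain starting at o[i]
    for (i in rev(seq_len(L))) {
      for (j in seq_len(L)) {
        if (j > i && link_ok(o[i], o[j]) && f[j] + 1L > f[i]) f[i] <- f[j] + 1L
      }
    }
    top <- max(f)
    if (top < min_len) break
    # forward reconstruction: at each step take the smallest (ra, rb)
    # match that still allows a chain of the required total length
    chain <- integer(0)
    need <- top
    cand <- which(f == need)        # o is (ra, rb)-sorted; first = lex smallest
    cur <- cand[1]
    chain <- o[cur]
    while (need > 1L) {
      need <- need - 1L
      nxt <- which(f == need)
      nxt <- nxt[nxt > cur & vapply(nxt, function(j) link_ok(o[cur], o[j]), logical(1))]
      cur <- nxt[1]
      chain <- c(chain, o[cur])
    }
    chains[[length(chains) + 1L]] <- chain
    active[chain] <- FALSE
  }
  chains
}

#' Chain homologous matches into collinear blocks
#'
#' @param orders a [gene_order()] table covering both genomes (a genome =
#'   one species; self-comparison uses the same species on both sides).
#' @param pairs data.frame gene_a, gene_b of homologous pairs; every gene
#'   must appear in `orders`.
#' @param max_gap maximum rank gap between consecutive chained pairs on
#'   both chromosomes (default 20).
#' @param min_len minimum pairs per block (default 4).
#' @param self logical: intra-genome comparison (the self-diagonal is
#'   removed and mirrored blocks deduplicated).
#' @param family_of optional named map gene -> family for tandem-array
#'   collapsing (arrays are represented by their lowest-rank member).
#' @return data.frame of blocks: block_id, chrom_a, chrom_b, orientation,
#'   n_pairs, start_a, end_a, start_b, end_b (half-open rank intervals),
#'   plus attribute `pairs`: per-block matched gene pairs.
#' @export
chain_collinear_blocks <- function(orders, pairs, max_gap = 20, min_len = 4,
                                   self = FALSE, family_of = NULL) {
  loc <- orders
  pos <- match(pairs$gene_a, loc$gene_id)
  pos_b <- match(pairs$gene_b, loc$gene_id)
  if (anyNA(pos)) stop("unknown gene in pairs: ", pairs$gene_a[which(is.na(pos))[1]])
  if (anyNA(pos_b)) stop("unknown gene in pairs: ", pairs$gene_b[which(is.na(pos_b))[1]])
  if (!is.null(family_of)) {
    rep_map <- collapse_tandem(orders, family_of)
    pairs$gene_a <- unname(rep_map[pairs$gene_a])
    pairs$gene_b <- unname(rep_map[pairs$gene_b])
    pairs <- unique(pairs[, c("gene_a", "gene_b")])
    pos <- match(pairs$gene_a, loc$gene_id)
    pos_b <- match(pairs$gene_b, loc$gene_id)
  }
  m <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  chrom_a = loc$chromosome[pos], ra = loc$rank[pos],
                  chrom_b = loc$chromosome[pos_b], rb = loc$rank[pos_b],
                  stringsAsFactors = FALSE)
  if (self) {
    m <- m[m$gene_a != m$gene_b, , drop = FALSE]
    # canonical orientation of each match so mirrored blocks coincide
    swap <- m$chrom_a > m$chrom_b | (m$chrom_a == m$chrom_b & m$ra > m$rb)
    m[swap, c("gene_a", "gene_b", "chrom_a", "ra", "chrom_b", "rb")] <-
      m[swap, c("gene_b", "gene_a", "chrom_b", "rb", "chrom_a", "ra")]
    m <- unique(m)
  }
  blocks <- list(); block_pairs <- list()
  for (cp in split(seq_len(nrow(m)), paste(m$chrom_a, m$chrom_b, sep = "\r"))) {
    sub <- m[cp, , drop = FALSE]
    for (orient in c("+", "-")) {
      rb_eff <- if (orient == "+") sub$rb else -sub$rb
      chains <- chain_dp(sub$ra, rb_eff, max_gap, min_len)
      for (ch in chains) {
        b <- sub[ch, , drop = FALSE]
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom_a = b$chrom_a[1], chrom_b = b$chrom_b[1], orientation = orient,
          n_pairs = nrow(b),
          start_a = min(b$ra), end_a = max(b$ra) + 1L,
          start_b = min(b$rb), end_b = max(b$rb) + 1L,
          stringsAsFactors = FALSE)
        block_pairs[[length(block_pairs) + 1L]] <- b
      }
    }
  }
  if (length(blocks) == 0) {
    out <- data.frame(block_id = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_pairs = integer(0), start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0))
    attr(out, "pairs") <- list()
    return(out)
  }
  out <- do.call(rbind, blocks)
  o <- order(-out$n_pairs, out$chrom_a, out$start_a, out$chrom_b, out$start_b)
  out <- out[o, , drop = FALSE]
  block_pairs <- block_pairs[o]
  out$block_id <- sprintf("blk%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  validate_blocks(out, block_pairs, max_gap, min_len)
  out <- out[, c("block_id", "chrom_a", "chrom_b", "orientation", "n_pairs",
                 "start_a", "end_a", "start_b", "end_b")]
  attr(out, "pairs") <- setNames(block_pairs, out$block_id)
  out
}

# Invariant checks run on every chaining output.
validate_blocks <- function(blocks, block_pairs, max_gap, min_len) {
  for (k in seq_along(block_pairs)) {
    b <- block_pairs[[k]]
    stopifnot(nrow(b) >= min_len)
    o <- order(b$ra)
    ra <- b$ra[o]; rb <- b$rb[o]
    stopifnot(all(diff(ra) > 0), all(diff(ra) <= max_gap))
    if (blocks$orientation[k] == "+") {
      stopifnot(all(diff(rb) > 0), all(diff(rb) <= max_gap))
    } else {
      stopifnot(all(diff(rb) < 0), all(-diff(rb) <= max_gap))
    }
  }
  invisible(TRUE)
}

#' Screen blocks down to a one-to-one tiling
#'
#' Greedy selection by descending score (pair count): a block is kept iff
#' its rank interval overlaps no already-kept block on either genome axis
#' (same chromosome, intersecting half-open interval). Excludes older
#' large-scale duplications so each region is covered at most once per
#' axis.
#'
#' @param blocks output of [chain_collinear_blocks()].
#' @return the kept subset (same columns, `pairs` attribute subset).
#' @export
screen_one_to_one <- function(blocks) {
  if (nrow(blocks) == 0) return(blocks)
  o <- order(-blocks$n_pairs, blocks$chrom_a, blocks$start_a)
  kept <- integer(0)
  overlaps <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1
  for (i in o) {
    clash <- FALSE
    for (j in kept) {
      if (overlaps(blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i],
                   blocks$chrom_a[j], blocks$start_a[j], blocks$end_a[j]) ||
          overlaps(blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i],
                   blocks$chrom_b[j], blocks$start_b[j], blocks$end_b[j]) ||
          overlaps(blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i],
                   blocks$chrom_b[j], blocks$start_b[j], blocks$end_b[j]) ||
          overlaps(blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i],
                   blocks$chrom_a[j], blocks$start_a[j], blocks$end_a[j])) {
        clash <- TRUE; break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- blocks[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs") <- attr(blocks, "pairs")[out$block_id]
  out
}

#' Extract anchor pairs from intra-genomic blocks
#'
#' Returns all matched pairs of the given self-comparison blocks; pairs
#' with Ks greater than `ks_cap` or flagged saturated are removed and
#' counted. Pairs without a Ks value are retained with a missing-value
#' flag and a warning.
#'
#' @param blocks blocks from a within-species comparison (with `pairs`
#'   attribute).
#' @param ks_table optional data.frame gene_a, gene_b, Ks, saturated.
#' @param ks_cap Ks cap (default 5).
#' @return data.frame gene_a, gene_b, block_id, ks, ks_missing; attributes
#'   `n_total`, `n_removed` (cap/saturation), `n_kept`.
#' @export
extract_anchor_pairs <- function(blocks, ks_table = NULL, ks_cap = 5) {
  bp <- attr(blocks, "pairs")
  if (is.null(bp) || length(bp) == 0)
    return(structure(data.frame(gene_a = character(0), gene_b = character(0),
                                block_id = character(0), ks = numeric(0),
                                ks_missing = logical(0)),
                     n_total = 0L, n_removed = 0L, n_kept = 0L))
  all_pairs <- do.call(rbind, lapply(names(bp), function(id) {
    data.frame(gene_a = bp[[id]]$gene_a, gene_b = bp[[id]]$gene_b,
               block_id = id, stringsAsFactors = FALSE)
  }))
  ks <- rep(NA_real_, nrow(all_pairs))
  saturated <- rep(FALSE, nrow(all_pairs))
  if (!is.null(ks_table)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    kk <- setNames(ks_table$Ks, key(ks_table$gene_a, ks_table$gene_b))
    ss <- setNames(as.logical(ks_table$saturated %||% rep(FALSE, nrow(ks_table))),
                   key(ks_table$gene_a, ks_table$gene_b))
    k2 <- key(all_pairs$gene_a, all_pairs$gene_b)
    ks <- unname(kk[k2])
    saturated <- unname(ss[k2]); saturated[is.na(saturated)] <- FALSE
  }
  missing_ks <- is.na(ks) & !saturated
  if (any(missing_ks) && !is.null(ks_table))
    warning(sum(missing_ks), " anchor pair(s) lack a Ks value; retained with flag")
  drop <- (!is.na(ks) & ks > ks_cap) | saturated
  out <- all_pairs[!drop, , drop = FALSE]
  out$ks <- ks[!drop]
  out$ks_missing <- missing_ks[!drop]
  rownames(out) <- NULL
  structure(out, n_total = nrow(all_pairs), n_removed = sum(drop),
            n_kept = nrow(out))
}
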