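#' Codon alignment container
#'
#' A codon alignment is stored as an integer matrix of codon indices
#' (1..64, `NA` for a gap) with one row per gene; row names are gene ids.
#' Columns containing a gap or a stop codon in any sequence are excluded
#' from Ks counting.
#'
#' @param codons integer matrix (genes x codon columns), values 1..64 or NA.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  structure(list(codons = codons), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x$codons), "sequences x", ncol(x$codons), "codon columns\n")
  invisible(x)
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Maps every aligned amino-acid column to its source codon; protein gaps
#' become codon gaps. Each CDS must be exactly 3x its ungapped protein
#' length and must translate to the protein (standard genetic code).
#'
#' @param protein_aln named character vector of aligned protein sequences
#'   (equal lengths, `-` for gaps).
#' @param cds named character vector of unaligned coding sequences.
#' @return a [codon_alignment()].
#' @export
back_translate <- function(protein_aln, cds) {
  stopifnot(!is.null(names(protein_aln)))
  lens <- nchar(protein_aln)
  if (length(unique(lens)) != 1L) stop("protein alignment is not rectangular")
  ncol_aln <- lens[[1]]
  ct <- codon_table()
  out <- matrix(NA_integer_, nrow = length(protein_aln), ncol = ncol_aln,
                dimnames = list(names(protein_aln), NULL))
  for (g in names(protein_aln)) {
    if (is.null(cds[[g]]) || is.na(cds[g])) stop("no CDS for gene ", g)
    aa_aln <- strsplit(protein_aln[[g]], "")[[1]]
    non_gap <- aa_aln != "-"
    codons <- dna_to_codons(cds[[g]])
    if (length(codons) != sum(non_gap))
      stop("CDS length mismatch for gene ", g, ": ", length(codons),
           " codons vs ", sum(non_gap), " aligned residues")
    trans <- ct$aa[codons]
    if (!all(trans == aa_aln[non_gap]))
      stop("CDS does not translate to aligned protein for gene ", g)
    out[g, non_gap] <- codons
  }
  codon_alignment(out)
}

# Core pairwise NG86 computation on two integer codon vectors (NA = gap).
ks_pair_ng86 <- function(a, b, min_columns = 30) {
  ct <- codon_table()
  ok <- !is.na(a) & !is.na(b) & !ct$stop[a] & !ct$stop[b]
  a <- a[ok]; b <- b[ok]
  n_col <- length(a)
  if (n_col == 0L) stop("no counted codon columns (all gapped or stop-containing)")
  S <- (sum(ct$syn_sites[a]) + sum(ct$syn_sites[b])) / 2
  N <- (sum(ct$nonsyn_sites[a]) + sum(ct$nonsyn_sites[b])) / 2
  dt <- ng86_diff_tables()
  sd_ <- sum(dt$SD[cbind(a, b)])
  nd_ <- sum(dt$ND[cbind(a, b)])
  ps <- if (S > 0) sd_ / S else 0
  pn <- if (N > 0) nd_ / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NaN
  saturated <- ps >= 3 / 4
  list(S = S, N = N, sd = sd_, nd = nd_, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn), saturated = saturated,
       n_columns = n_col, low_information = n_col < min_columns)
}

#' NG86 synonymous/nonsynonymous distance for a codon-aligned gene pair
#'
#' Fractional site counting per codon (synonymous fraction of each
#' position's three possible changes under the standard genetic code),
#' differences averaged with equal weight over all minimal mutational
#' pathways (pathways through stop codons excluded), and Jukes-Cantor
#' correction `Ks = -(3/4) log(1 - (4/3) ps)`. Pairs with `ps >= 3/4` are
#' flagged saturated and `Ks` is `NaN`.
#'
#' @param aln a [codon_alignment()] with at least the two genes.
#' @param gene_a,gene_b gene ids; default: the first two rows.
#' @param min_columns columns below which the estimate is flagged
#'   low-information (default 30).
#' @return one-row data.frame with columns gene_a, gene_b, S, N, sd, nd,
#'   ps, pn, Ks, Ka, saturated, n_columns, low_information.
#' @export
estimate_ks_ng86 <- function(aln, gene_a = NULL, gene_b = NULL, min_columns = 30) {
  stopifnot(inherits(aln, "codon_alignment"))
  ids <- rownames(aln$codons)
  if (is.null(gene_a)) gene_a <- ids[1]
  if (is.null(gene_b)) gene_b <- ids[2]
  est <- ks_pair_ng86(aln$codons[gene_a, ], aln$codons[gene_b, ], min_columns)
  data.frame(gene_a = gene_a, gene_b = gene_b, est, stringsAsFactors = FALSE)
}

#' NG86 Ks for one pair of positionally aligned CDS
#'
#' Convenience wrapper around [estimate_ks_ng86()] for two equal-length
#' coding sequences (codon-for-codon aligned, as simulator output is).
#'
#' @param cds_a,cds_b coding sequences (equal length, no gaps).
#' @param min_columns see [estimate_ks_ng86()].
#' @return one-row data.frame as [estimate_ks_ng86()].
#' @export
pair_ks_ng86 <- function(cds_a, cds_b, min_columns = 30) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences differ in length; build a codon_alignment instead")
  est <- ks_pair_ng86(dna_to_codons(cds_a), dna_to_codons(cds_b), min_columns)
  data.frame(gene_a = "a", gene_b = "b", est, stringsAsFactors = FALSE)
}

#' All pairwise Ks estimates within a gene family
#'
#' Computes the n(n-1)/2 pairwise NG86 estimates for a family. Sequences
#' are taken as positionally aligned codon-for-codon (indel-free families,
#' as produced by the simulator); for gapped families build a
#' [codon_alignment()] with [back_translate()] and pass it directly.
#'
#' @param cds named character vector of CDS (equal lengths), or a
#'   [codon_alignment()].
#' @param min_columns see [estimate_ks_ng86()].
#' @return list with `table` (data.frame of all pair estimates) and `ks`
#'   (symmetric numeric matrix, `NaN` where saturated, zero diagonal).
#' @export
family_ks_matrix <- function(cds, min_columns = 30) {
  if (inherits(cds, "codon_alignment")) {
    aln <- cds
  } else {
    stopifnot(!is.null(names(cds)), length(cds) >= 2)
    if (length(unique(nchar(cds))) != 1L)
      stop("family CDS lengths differ; supply a codon_alignment built with back_translate()")
    codons <- do.call(rbind, lapply(cds, dna_to_codons))
    rownames(codons) <- names(cds)
    aln <- codon_alignment(codons)
  }
  ids <- rownames(aln$codons)
  if (length(ids) < 2) stop("need >= 2 family members")
  prs <- utils::combn(ids, 2)
  ests <- lapply(seq_len(ncol(prs)), function(k)
    ks_pair_ng86(aln$codons[prs[1, k], ], aln$codons[prs[2, k], ], min_columns))
  tab <- data.frame(gene_a = prs[1, ], gene_b = prs[2, ],
                    do.call(rbind, lapply(ests, function(e) as.data.frame(e))),
                    stringsAsFactors = FALSE)
  ks <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(tab))) {
    v <- if (tab$saturated[k]) NaN else tab$Ks[k]
    ks[tab$gene_a[k], tab$gene_b[k]] <- v
    ks[tab$gene_b[k], tab$gene_a[k]] <- v
  }
  list(table = tab, ks = ks)
}

#' Read or write per-pair Ks tables
#'
#' Tab-separated with a `#`-prefixed header line; columns gene_a, gene_b,
#' S, N, ps, pn, Ks, Ka, saturated. Lets externally computed (e.g.
#' likelihood-based) Ks values be injected anywhere a Ks table is consumed.
#'
#' @param tab data.frame as produced by [family_ks_matrix()]`$table`.
#' @param path file path.
#' @export
write_ks_table <- function(tab, path) {
  cols <- c("gene_a", "gene_b", "S", "N", "ps", "pn", "Ks", "Ka", "saturated")
  keep <- tab[, intersect(cols, names(tab)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(keep), collapse = "\t")), con)
  write.table(keep, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ks_table
#' @export
read_ks_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  tab <- read.delim(path, header = FALSE, skip = 1, col.names = strsplit(header, "\t")[[1]],
                    stringsAsFactors = FALSE)
  tab$saturated <- as.logical(tab$saturated)
  tab
}
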