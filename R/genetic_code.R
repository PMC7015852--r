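# Standard-genetic-code machinery shared by the simulator and the Ks engine.
#
# Codons are represented internally as integers 1..64 with
# index = 16*(n1-1) + 4*(n2-1) + n3, nucleotides ordered A,C,G,T.
# All per-codon quantities (amino acid, NG86 fractional site counts,
# single-nucleotide neighbourhoods, pathway-averaged difference tables)
# are computed once from Biostrings::GENETIC_CODE and cached.

.wgd_cache <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

codon_strings <- function() {
  g <- expand.grid(n3 = NUC, n2 = NUC, n1 = NUC, stringsAsFactors = FALSE)
  paste0(g$n1, g$n2, g$n3)
}

codon_index <- function(codons) {
  m <- match(codons, codon_strings())
  if (anyNA(m)) stop("invalid codon(s): ", paste(unique(codons[is.na(m)]), collapse = ", "))
  m
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) || (a %in% c("C", "T") && b %in% c("C", "T"))
}

codon_table <- function() {
  if (!is.null(.wgd_cache$codon_table)) return(.wgd_cache$codon_table)
  cs <- codon_strings()
  gc <- Biostrings::GENETIC_CODE  # standard code, names like "TTT"
  aa <- unname(gc[cs])
  stop_codon <- aa == "*"

  # 9 single-nucleotide neighbours per codon
  neighbors <- vector("list", 64)
  for (i in seq_len(64)) {
    from <- strsplit(cs[i], "")[[1]]
    tab <- list()
    for (pos in 1:3) {
      for (nt in setdiff(NUC, from[pos])) {
        to <- from
        to[pos] <- nt
        j <- codon_index(paste(to, collapse = ""))
        tab[[length(tab) + 1L]] <- list(
          to = j, pos = pos,
          transition = is_transition(from[pos], nt),
          synonymous = !stop_codon[i] && !stop_codon[j] && aa[i] == aa[j],
          to_stop = stop_codon[j]
        )
      }
    }
    neighbors[[i]] <- tab
  }

  # NG86 fractional site counts: per position the fraction of the three
  # possible changes that is synonymous; changes to stop codons count as
  # nonsynonymous. Stop codons themselves carry zero sites.
  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    if (stop_codon[i]) next
    syn_sites[i] <- sum(vapply(neighbors[[i]], function(n) n$synonymous, logical(1))) / 3
  }
  nonsyn_sites <- ifelse(stop_codon, 0, 3 - syn_sites)

  out <- list(codons = cs, aa = aa, stop = stop_codon,
              neighbors = neighbors, syn_sites = syn_sites,
              nonsyn_sites = nonsyn_sites,
              sense = which(!stop_codon))
  .wgd_cache$codon_table <- out
  out
}

# Pathway-averaged synonymous / nonsynonymous difference counts for every
# ordered codon pair (64 x 64). For a pair differing at k positions all k!
# minimal mutational pathways are enumerated with equal weight; pathways
# passing through a stop codon are excluded. If every pathway is blocked the
# average falls back to all pathways (rare; keeps the estimator total sd+nd=k).
ng86_diff_tables <- function() {
  if (!is.null(.wgd_cache$ng86_diff)) return(.wgd_cache$ng86_diff)
  ct <- codon_table()
  cs <- ct$codons
  SD <- matrix(0, 64, 64)
  ND <- matrix(0, 64, 64)
  split_cs <- strsplit(cs, "")

  step_counts <- function(i, j) {
    # one-nucleotide step i -> j: c(syn, nonsyn)
    if (!ct$stop[i] && !ct$stop[j] && ct$aa[i] == ct$aa[j]) c(1, 0) else c(0, 1)
  }

  for (i in seq_len(64)) {
    ci <- split_cs[[i]]
    for (j in seq_len(64)) {
      if (i == j) next
      cj <- split_cs[[j]]
      pos <- which(ci != cj)
      k <- length(pos)
      if (k == 1L) {
        sc <- step_counts(i, j)
        SD[i, j] <- sc[1]; ND[i, j] <- sc[2]
        next
      }
      perms <- if (k == 2L) list(pos, rev(pos)) else {
        out <- list()
        for (p in 1:3) for (q in setdiff(1:3, p)) out[[length(out) + 1L]] <- c(pos[p], pos[q], setdiff(pos, pos[c(p, q)]))
        out
      }
      acc <- matrix(0, 0, 2)
      acc_all <- matrix(0, 0, 2)
      for (ord in perms) {
        cur <- ci; cur_i <- i
        tot <- c(0, 0); blocked <- FALSE
        for (p in ord) {
          nxt <- cur; nxt[p] <- cj[p]
          nxt_i <- codon_index(paste(nxt, collapse = ""))
          tot <- tot + step_counts(cur_i, nxt_i)
          if (ct$stop[nxt_i] && nxt_i != j) blocked <- TRUE
          cur <- nxt; cur_i <- nxt_i
        }
        acc_all <- rbind(acc_all, tot)
        if (!blocked) acc <- rbind(acc, tot)
      }
      use <- if (nrow(acc) > 0) acc else acc_all
      SD[i, j] <- mean(use[, 1]); ND[i, j] <- mean(use[, 2])
    }
  }
  .wgd_cache$ng86_diff <- list(SD = SD, ND = ND)
  .wgd_cache$ng86_diff
}

# Translate an integer codon vector to an amino-acid string.
codons_to_aa <- function(idx) paste(codon_table()$aa[idx], collapse = "")

# Integer codon vector <-> nucleotide string.
codons_to_dna <- function(idx) paste(codon_table()$codons[idx], collapse = "")

dna_to_codons <- function(seq) {
  if (nchar(seq) %% 3 != 0) stop("sequence length not a multiple of 3")
  codon_index(substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3)))
}
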