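toy_orders <- function(n_a = 50, n_b = 50) {
  rbind(
    data.frame(gene_id = sprintf("A%03d", seq_len(n_a)), species = "spA",
               chromosome = "c1", rank = seq_len(n_a) - 1L, strand = "+"),
    data.frame(gene_id = sprintf("B%03d", seq_len(n_b)), species = "spB",
               chromosome = "c2", rank = seq_len(n_b) - 1L, strand = "+"))
}

match_pairs <- function(ra, rb) {
  data.frame(gene_a = sprintf("A%03d", ra + 1L), gene_b = sprintf("B%03d", rb + 1L))
}

test_that("a perfect diagonal run of four forms one forward block", {
  ords <- gene_order(toy_orders())
  blocks <- chain_collinear_blocks(ords, match_pairs(1:4, 1:4))
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_pairs, 4)
  expect_equal(blocks$orientation, "+")
  expect_equal(blocks$start_a, 1L)
  expect_equal(blocks$end_a, 5L)   # half-open
})

test_that("three matches are below min_len and give no block", {
  ords <- gene_order(toy_orders())
  blocks <- chain_collinear_blocks(ords, match_pairs(1:3, 1:3))
  expect_equal(nrow(blocks), 0)
})

test_that("a gap above max_gap splits the chain; only the 4-run survives", {
  ords <- gene_order(toy_orders())
  m <- match_pairs(c(1, 2, 23, 24, 25, 26), c(1, 2, 23, 24, 25, 26))
  blocks <- chain_collinear_blocks(ords, m, max_gap = 20, min_len = 4)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_pairs, 4)
  expect_equal(blocks$start_a, 23L)
  ref <- oracle_chains(c(1, 2, 23, 24, 25, 26), c(1, 2, 23, 24, 25, 26))
  expect_equal(length(ref), 1)
  expect_equal(length(ref[[1]]), 4)
})

test_that("reverse-orientation runs are chained as minus blocks", {
  ords <- gene_order(toy_orders())
  blocks <- chain_collinear_blocks(ords, match_pairs(1:5, c(20, 19, 18, 17, 16)))
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "-")
  expect_equal(blocks$n_pairs, 5)
})

test_that("DP chaining equals brute-force search on random instances", {
  set.seed(5)
  for (inst in 1:60) {
    n <- sample(4:15, 1)
    ra <- sample(0:30, n)
    rb <- sample(0:30, n)
    got <- chain_dp(ra, rb, max_gap = 20, min_len = 4)
    want <- oracle_chains(ra, rb, max_gap = 20, min_len = 4)
    expect_equal(length(got), length(want), info = paste("instance", inst))
    for (k in seq_along(want))
      expect_equal(got[[k]], want[[k]], info = paste("instance", inst, "chain", k))
  }
})

test_that("unknown genes in pairs are reported by name", {
  ords <- gene_order(toy_orders())
  expect_error(chain_collinear_blocks(ords, data.frame(gene_a = "Zzz", gene_b = "B001")),
               "Zzz")
})

test_that("genome swap symmetry: axes exchange but blocks agree", {
  ords <- gene_order(toy_orders())
  m <- match_pairs(c(3:6, 10:14), c(8:11, 20:24))
  fwd <- chain_collinear_blocks(ords, m)
  swapped <- data.frame(gene_a = m$gene_b, gene_b = m$gene_a)
  rev <- chain_collinear_blocks(ords, swapped)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$start_a, rev$start_b)
  expect_equal(fwd$end_b, rev$end_a)
  expect_equal(fwd$n_pairs, rev$n_pairs)
})

test_that("tandem arrays are collapsed to their lowest-rank representative", {
  a_ids <- append(sprintf("A%03d", 1:50), "A_tand", after = 2)  # tandem after A002
  ords <- gene_order(rbind(
    data.frame(gene_id = a_ids, species = "spA", chromosome = "c1",
               rank = seq_along(a_ids) - 1L, strand = "+"),
    data.frame(gene_id = sprintf("B%03d", 1:50), species = "spB",
               chromosome = "c2", rank = 0:49, strand = "+")))
  fam <- setNames(c(paste0("f", 1:50), paste0("g", 1:50), "f2"),
                  c(sprintf("A%03d", 1:50), sprintf("B%03d", 1:50), "A_tand"))
  m <- rbind(match_pairs(0:4, 0:4),
             data.frame(gene_a = "A_tand", gene_b = "B002"))
  blocks <- chain_collinear_blocks(ords, m, family_of = fam)
  pr <- attr(blocks, "pairs")[[1]]
  expect_false("A_tand" %in% pr$gene_a)
  expect_equal(blocks$n_pairs, 5)
})

test_that("one-to-one screening keeps the best of overlapping blocks", {
  mk <- function(ca, sa, ea, cb, sb, eb, n) data.frame(
    block_id = paste0("b", n), chrom_a = ca, chrom_b = cb, orientation = "+",
    n_pairs = n, start_a = sa, end_a = ea, start_b = sb, end_b = eb)
  two <- rbind(mk("c1", 0, 10, "c2", 0, 10, 10), mk("c1", 20, 30, "c2", 20, 30, 6))
  attr(two, "pairs") <- list()
  kept <- screen_one_to_one(two)
  expect_equal(nrow(kept), 2)

  ov <- rbind(mk("c1", 0, 10, "c2", 0, 10, 10), mk("c1", 5, 15, "c2", 40, 50, 6))
  attr(ov, "pairs") <- list()
  kept2 <- screen_one_to_one(ov)
  expect_equal(kept2$n_pairs, 10)
})

test_that("greedy screening is valid and near-optimal on random blocks", {
  set.seed(8)
  gaps <- numeric(0)
  for (inst in 1:20) {
    n <- sample(3:8, 1)
    b <- data.frame(block_id = paste0("b", seq_len(n)),
                    chrom_a = sample(c("c1", "c2"), n, TRUE),
                    chrom_b = sample(c("d1", "d2"), n, TRUE),
                    orientation = "+",
                    n_pairs = sample(4:20, n, TRUE),
                    start_a = sample(0:40, n, TRUE))
    b$end_a <- b$start_a + sample(5:15, n, TRUE)
    b$start_b <- sample(0:40, n, TRUE)
    b$end_b <- b$start_b + sample(5:15, n, TRUE)
    attr(b, "pairs") <- list()
    kept <- screen_one_to_one(b)
    # validity: kept blocks are pairwise non-overlapping per axis
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        same_a <- kept$chrom_a[i] == kept$chrom_a[j] &&
          kept$start_a[i] < kept$end_a[j] && kept$start_a[j] < kept$end_a[i]
        same_b <- kept$chrom_b[i] == kept$chrom_b[j] &&
          kept$start_b[i] < kept$end_b[j] && kept$start_b[j] < kept$end_b[i]
        expect_false(same_a || same_b)
      }
    }
    gaps <- c(gaps, oracle_screen_optimum(b) - sum(kept$n_pairs))
  }
  # report the greedy optimality gap observed across instances
  expect_true(all(gaps >= 0))
  message("greedy 1:1 screening total-score gap vs optimum: max ", max(gaps))
})

test_that("anchor extraction applies the Ks cap and conserves counts", {
  ords <- gene_order(rbind(
    data.frame(gene_id = sprintf("N%03d", 1:10), species = "sp", chromosome = "c1",
               rank = 0:9, strand = "+"),
    data.frame(gene_id = sprintf("M%03d", 1:10), species = "sp", chromosome = "c1b",
               rank = 0:9, strand = "+")))
  pairs <- data.frame(gene_a = sprintf("N%03d", 1:10), gene_b = sprintf("M%03d", 1:10))
  blocks <- chain_collinear_blocks(ords, pairs, self = TRUE)
  expect_equal(sum(blocks$n_pairs), 10)

  ks_tab <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                       Ks = c(rep(0.9, 7), rep(6, 3)), saturated = FALSE)
  anch <- extract_anchor_pairs(blocks, ks_tab, ks_cap = 5)
  expect_equal(attr(anch, "n_total"), 10L)
  expect_equal(attr(anch, "n_removed"), 3L)
  expect_equal(attr(anch, "n_kept"), 7L)
  expect_equal(attr(anch, "n_kept") + attr(anch, "n_removed"), attr(anch, "n_total"))
  expect_warning(extract_anchor_pairs(blocks, ks_tab[1:5, ], ks_cap = 5), "lack a Ks")
})

test_that("anchors are recovered with high recall and precision on simulations", {
  cfg <- sim_config(seed = 77, n_families = 150, retention_prob = 0.5,
                    fractionation_prob = 0.2, tandem_prob = 1, codon_length = 200)
  ds <- simulate_dataset(cfg)
  truth_fam <- sub("^.*_(f[0-9]{4})_g[0-9]+$", "\\1", names(ds$cds))
  family_of <- setNames(truth_fam, names(ds$cds))
  orders <- gene_order(ds$orders)
  foc <- orders[orders$species == "Nymphaea_colorata", ]
  fam_split <- split(foc$gene_id, family_of[foc$gene_id])
  pairs <- do.call(rbind, lapply(fam_split, function(g) {
    if (length(g) < 2) return(NULL)
    p <- combn(g, 2); data.frame(gene_a = p[1, ], gene_b = p[2, ])
  }))
  blocks <- chain_collinear_blocks(foc, pairs, self = TRUE, family_of = family_of)
  anch <- extract_anchor_pairs(screen_one_to_one(blocks))
  truth <- ds$anchors[ds$anchors$species == "Nymphaea_colorata", ]
  tk <- pair_key(truth$gene_a, truth$gene_b)
  dk <- pair_key(anch$gene_a, anch$gene_b)
  expect_gte(mean(tk %in% dk), 0.9)   # recall
  expect_gte(mean(dk %in% tk), 0.95)  # precision (tandem-only background)
})
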