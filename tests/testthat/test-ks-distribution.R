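mat_from_pairs <- function(ids, f) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i != j)
    m[i, j] <- f(ids[i], ids[j])
  m
}

test_that("subfamily splitting follows connected components at the threshold", {
  ids <- paste0("g", 1:4)
  m_all <- mat_from_pairs(ids, function(a, b) 1)
  expect_equal(split_subfamilies(m_all, 5), list(ids))

  # two tight clusters joined only by pairs above the threshold
  m2 <- matrix(10, 4, 4, dimnames = list(ids, ids))
  m2[1:2, 1:2] <- 1; m2[3:4, 3:4] <- 1; diag(m2) <- 0
  got <- split_subfamilies(m2, 5)
  expect_equal(got, list(c("g1", "g2"), c("g3", "g4")))

  # random matrices vs brute-force transitive closure; singletons dropped
  set.seed(4)
  for (r in 1:25) {
    n <- sample(3:8, 1)
    idr <- paste0("x", seq_len(n))
    mr <- matrix(runif(n * n, 0, 10), n, n, dimnames = list(idr, idr))
    mr[upper.tri(mr)] <- t(mr)[upper.tri(mr)]
    diag(mr) <- 0
    mr[sample(length(mr), 3)] <- NaN
    mr[upper.tri(mr)] <- t(mr)[upper.tri(mr)]   # keep symmetric incl. NaN
    got <- split_subfamilies(mr, 5)
    want <- Filter(function(g) length(g) >= 2, oracle_components(mr, 5))
    key <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_equal(key(got), key(want))
  }
})

test_that("subfamily trees: cherries, additive recovery, order invariance", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- build_subfamily_tree(m)
  expect_equal(ape::Ntip(tr), 2)

  # additive distances from a known 4-leaf tree are recovered by NJ
  ref <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:0.5):1);")
  D <- ape::cophenetic.phylo(ref)
  tr4 <- build_subfamily_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  perm <- sample(rownames(D))
  tr4b <- build_subfamily_tree(D[perm, perm])
  expect_equal(ape::write.tree(tr4b), ape::write.tree(tr4))

  expect_error(build_subfamily_tree(matrix(c(0, NaN, NaN, 0), 2, 2,
                                           dimnames = list(c("a", "b"), c("a", "b")))),
               "saturated|finite")
})

test_that("node weighting: per-node weights sum to one, totals equal n-1", {
  m <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w <- node_weighted_distribution(build_subfamily_tree(m), m, "fam")
  expect_equal(nrow(w), 1)
  expect_equal(w$weight, 1)
  expect_equal(w$ks, 0.4)

  # balanced quartet: two cherries (weight 1) and a root node with 4 x 1/4
  ref <- ape::read.tree(text = "((a:0.1,b:0.1):0.35,(c:0.1,d:0.1):0.35);")
  D <- ape::cophenetic.phylo(ref)
  w4 <- node_weighted_distribution(ref, D, "fam")
  expect_equal(sum(w4$weight), 3)                      # n - 1 events
  expect_equal(sort(unique(w4$weight)), c(0.25, 1))
  expect_equal(sum(w4$weight == 0.25), 4)
  per_node <- tapply(w4$weight, w4$node_id, sum)
  expect_true(all(abs(per_node - 1) < 1e-12))

  # random trees up to 8 leaves
  set.seed(9)
  for (r in 1:30) {
    n <- sample(2:8, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    D <- ape::cophenetic.phylo(tr)
    wr <- node_weighted_distribution(tr, D, "f")
    expect_equal(nrow(wr), n * (n - 1) / 2)
    expect_equal(sum(wr$weight), n - 1, tolerance = 1e-12)
    expect_true(all(abs(tapply(wr$weight, wr$node_id, sum) - 1) < 1e-12))
  }
})

test_that("redundancy correction stops one large family from dominating", {
  # 30 two-member families near Ks 0.9 (the signal) and one 20-member
  # family with all pairs near Ks 2 (background redundancy)
  set.seed(2)
  mats <- list()
  for (i in 1:30) {
    k <- rnorm(1, 0.9, 0.03)
    ids <- c("a", "b")
    mats[[paste0("s", i)]] <- matrix(c(0, k, k, 0), 2, 2, dimnames = list(ids, ids))
  }
  ids <- paste0("g", 1:20)
  big <- matrix(2 + abs(rnorm(400, 0, 0.02)), 20, 20, dimnames = list(ids, ids))
  big[upper.tri(big)] <- t(big)[upper.tri(big)]
  diag(big) <- 0
  mats[["big"]] <- big
  wd <- weighted_paranome_distribution(mats)
  dens_ratio <- function(x, w) {
    d <- density(x, weights = w / sum(w), from = 0.5, to = 2.5, n = 512, bw = 0.05)
    d$y[which.min(abs(d$x - 0.9))] / d$y[which.min(abs(d$x - 2))]
  }
  weighted_ratio <- dens_ratio(wd$ks, wd$weight)
  unweighted_ratio <- dens_ratio(wd$ks, rep(1, nrow(wd)))
  expect_gte(weighted_ratio, unweighted_ratio)
})

test_that("KDE peak: constant values, known mixture, determinism", {
  p0 <- kde_peak_ci(rep(0.7, 50), seed = 1)
  expect_equal(p0$mode, 0.7)
  expect_equal(p0$ci_low, 0.7)
  expect_equal(p0$ci_high, 0.7)

  set.seed(31)
  x <- c(rnorm(800, 0.3, 0.05), rnorm(1200, 0.9, 0.08))
  p <- kde_peak_ci(x, seed = 2)
  expect_lt(abs(p$mode - 0.9), 0.05)
  expect_true(p$ci_low <= p$ci_high)
  p2 <- kde_peak_ci(x, seed = 2)
  expect_identical(p[c("ci_low", "ci_high")], p2[c("ci_low", "ci_high")])

  expect_error(kde_peak_ci(rep(0.5, 10)), "widening|need")
})

test_that("orthologue comparison orders divergences and flags WGD timing", {
  set.seed(12)
  ortho <- list(near = rnorm(200, 0.5, 0.08), far = rnorm(200, 1.0, 0.1))
  cmp <- compare_ortholog_ks(ortho, paralog_peak = 0.7)
  expect_equal(cmp$comparison, c("near", "far"))
  expect_lt(abs(cmp$mode[1] - 0.5), 0.1)
  expect_lt(abs(cmp$mode[2] - 1.0), 0.1)
  expect_equal(cmp$wgd_younger, c(FALSE, TRUE))

  # self-comparison: all Ks ~ 0 gives a mode at ~0
  self <- list(self = rep(0, 100))
  cmp0 <- compare_ortholog_ks(self, 0.7, ks_range = c(-0.01, 5))
  expect_equal(cmp0$mode, 0)

  expect_warning(compare_ortholog_ks(list(a = rnorm(200, 0.5, 0.05),
                                          tiny = rnorm(5, 1, 0.1)), 0.7),
                 "omitted")
})

test_that("relative rates rank a fast lineage first, input-order invariant", {
  cfg_fast <- sim_config(seed = 13, n_families = 60, codon_length = 200,
                         branch_rates = c(Victoria_cruziana = 2),
                         wgd_branch = NA, birth_rate = 0, loss_rate = 0)
  ds <- simulate_dataset(cfg_fast)
  sp <- species_map(ds)
  fam <- sub("^.*_(f[0-9]{4})_g[0-9]+$", "\\1", names(ds$cds))
  ortho <- list()
  for (target in c("Nymphaea_colorata", "Victoria_cruziana", "Euryale_ferox")) {
    vals <- numeric(0)
    for (f in unique(fam)) {
      g <- names(ds$cds)[fam == f]
      a <- g[sp[g] == "Illicium_henryi"]; b <- g[sp[g] == target]
      if (length(a) == 1 && length(b) == 1) {
        est <- ks_pair_ng86(dna_to_codons(ds$cds[[a]]), dna_to_codons(ds$cds[[b]]))
        if (!est$saturated) vals <- c(vals, est$Ks)
      }
    }
    ortho[[target]] <- vals
  }
  rr <- relative_rates("Illicium_henryi", ortho)
  expect_equal(rr$species[rr$rank == 1], "Victoria_cruziana")
  rr2 <- relative_rates("Illicium_henryi", rev(ortho))
  expect_equal(rr, rr2, ignore_attr = TRUE)
})

test_that("branch Ks fitting recovers additive inputs and clamps negatives", {
  topo <- ape::read.tree(text = "((A,B)ab,(C,D)cd)r;")
  true_tr <- ape::read.tree(text = "((A:0.2,B:0.3)ab:0.25,(C:0.15,D:0.4)cd:0.1)r;")
  D <- ape::cophenetic.phylo(true_tr)
  pairs <- t(combn(rownames(D), 2))
  pm <- data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                   ks = D[pairs])
  fit <- fit_branch_ks(topo, pm)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  d_fit <- ape::cophenetic.phylo(fit$tree)[rownames(D), colnames(D)]
  expect_equal(d_fit, D, tolerance = 1e-8)

  # +/-5% perturbation: recovered path distances within 10%
  set.seed(6)
  pm2 <- pm
  pm2$ks <- pm2$ks * runif(nrow(pm2), 0.95, 1.05)
  fit2 <- fit_branch_ks(topo, pm2)
  d2 <- ape::cophenetic.phylo(fit2$tree)[rownames(D), colnames(D)]
  off <- abs(d2 - D) / D
  expect_lt(max(off[upper.tri(off)]), 0.10)

  # inconsistent distances force a negative unconstrained branch: clamped
  pm3 <- pm
  pm3$ks[pm3$species_a == "A" & pm3$species_b == "B"] <- 0.01
  fit3 <- fit_branch_ks(topo, pm3)
  expect_true(all(fit3$lengths >= 0))

  expect_error(fit_branch_ks(topo, pm[1:3, ]), "under-determined")
})
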