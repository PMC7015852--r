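test_that("make_species_tree returns a rooted binary tree with Ks lengths", {
  tr <- make_species_tree(sim_config())
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 8)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
  expect_false(anyDuplicated(tr$tip.label) > 0)
})

test_that("two-leaf tree branch lengths are additive on the leaf path", {
  cfg <- sim_config(species_topology = "(a:0.45,b:0.45)r;", wgd_branch = NA)
  tr <- make_species_tree(cfg)
  expect_equal(unname(ape::cophenetic.phylo(tr)["a", "b"]), 0.9)
})

test_that("invalid topologies and negative rates are rejected", {
  expect_error(make_species_tree(sim_config(
    species_topology = "(a:1,b:1,c:1)r;", wgd_branch = NA)), "rooted|binary")
  expect_error(make_species_tree(sim_config(
    species_topology = "((a:1,b:1,c:1)x:1,d:2)r;", wgd_branch = NA)), "binary")
  expect_error(sim_config(birth_rate = -1), "nonnegative")
  expect_error(make_species_tree(sim_config(
    branch_rates = c(Nymphaea_colorata = -0.5))), "negative")
  expect_error(sim_config(retention_prob = 1.5), "\\[0,1\\]")
})

test_that("branch rate multipliers scale the named branches", {
  cfg <- sim_config(branch_rates = c(Nymphaea_colorata = 2))
  tr <- make_species_tree(cfg)
  base <- make_species_tree(sim_config())
  i <- which(tr$edge[, 2] == match("Nymphaea_colorata", tr$tip.label))
  expect_equal(tr$edge.length[i], 2 * base$edge.length[i])
})

test_that("retention probability controls WGD duplicate survival", {
  tr <- make_species_tree(sim_config())
  cfg0 <- sim_config(seed = 5, retention_prob = 0, n_families = 50)
  fams0 <- simulate_gene_trees(tr, cfg0)
  expect_false(any(vapply(fams0, `[[`, logical(1), "retained_wgd")))

  cfg1 <- sim_config(seed = 5, retention_prob = 1, loss_rate = 0, birth_rate = 0,
                     n_families = 50)
  fams1 <- simulate_gene_trees(tr, cfg1)
  crossed <- vapply(fams1, `[[`, logical(1), "crossed_wgd")
  n_wgd <- vapply(fams1, function(f) sum(f$events == "wgd"), integer(1))
  expect_true(all(crossed))
  expect_true(all(n_wgd[crossed] == 1))
})

test_that("retained fraction follows the binomial law at retention 0.25", {
  tr <- make_species_tree(sim_config())
  cfg <- sim_config(seed = 9, retention_prob = 0.25, loss_rate = 0,
                    birth_rate = 0, n_families = 400)
  fams <- simulate_gene_trees(tr, cfg)
  k <- sum(vapply(fams, `[[`, logical(1), "retained_wgd"))
  bounds <- qbinom(c(0.005, 0.995), 400, 0.25)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("zero-length branches leave sequences unchanged", {
  cfg <- sim_config(codon_length = 50, wgd_branch = NA)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  s <- evolve_cds(tr, cfg, seed = 1)
  expect_identical(s[["a"]], s[["b"]])
})

test_that("root sequences with stop codons are rejected", {
  cfg <- sim_config(codon_length = 2, wgd_branch = NA)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  expect_error(evolve_cds(tr, cfg, root_seq = "TAAGGA"), "stop codon")
})

test_that("mean pairwise NG86 Ks matches the tree path length", {
  cfg <- sim_config(codon_length = 500, wgd_branch = NA)
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  ks <- vapply(1:200, function(i) {
    s <- evolve_cds(tr, cfg, seed = i)
    ks_pair_ng86(dna_to_codons(s[["a"]]), dna_to_codons(s[["b"]]))$Ks
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.5) / 0.5, 0.10)
})

test_that("huge kappa makes observed substitutions overwhelmingly transitions", {
  cfg <- sim_config(codon_length = 2000, kappa = 200, omega = 0, wgd_branch = NA)
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  s <- evolve_cds(tr, cfg, seed = 3)
  na <- strsplit(s[["a"]], "")[[1]]; nb <- strsplit(s[["b"]], "")[[1]]
  d <- which(na != nb)
  is_ts <- (na[d] %in% c("A", "G") & nb[d] %in% c("A", "G")) |
    (na[d] %in% c("C", "T") & nb[d] %in% c("C", "T"))
  expect_gt(mean(is_ts), 0.9)
})

test_that("full fractionation leaves no surviving anchor pairs", {
  cfg <- sim_config(seed = 2, n_families = 40, fractionation_prob = 1)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$anchors), 0)
})

test_that("a fully retained duplicated segment yields order-preserving anchors", {
  cfg <- sim_config(seed = 3, n_families = 10, n_chromosomes = 1,
                    retention_prob = 1, fractionation_prob = 0,
                    birth_rate = 0, loss_rate = 0)
  ds <- simulate_dataset(cfg)
  nc <- ds$anchors[ds$anchors$species == "Nymphaea_colorata", ]
  expect_equal(nrow(nc), 10)
  o <- ds$orders[ds$orders$species == "Nymphaea_colorata", ]
  ra <- o$rank[match(nc$gene_a, o$gene_id)]
  rb <- o$rank[match(nc$gene_b, o$gene_id)]
  expect_equal(order(ra), order(rb))  # two order-preserving runs
  expect_setequal(unique(o$chromosome[match(nc$gene_a, o$gene_id)]), "chr1")
  expect_setequal(unique(o$chromosome[match(nc$gene_b, o$gene_id)]), "chr1b")
})

test_that("surviving anchors at fractionation 0.5 follow the binomial law", {
  cfg <- sim_config(seed = 4, n_families = 1000, n_chromosomes = 4,
                    retention_prob = 1, fractionation_prob = 0.5,
                    birth_rate = 0, loss_rate = 0, codon_length = 10)
  tr <- make_species_tree(cfg)
  fams <- simulate_gene_trees(tr, cfg)
  lay <- layout_genomes(fams, tr, cfg)
  k <- sum(lay$anchors$species == "Nymphaea_colorata")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("true anchor pair path Ks equals the configured WGD age exactly", {
  ds <- wgd_fixture()
  nc <- ds$anchors[ds$anchors$species == "Nymphaea_colorata", ]
  fams <- setNames(ds$families, vapply(ds$families, `[[`, "", "family_id"))
  for (r in seq_len(min(nrow(nc), 20))) {
    f <- fams[[nc$family_id[r]]]
    d <- ape::cophenetic.phylo(f$tree)[nc$gene_a[r], nc$gene_b[r]]
    expect_equal(unname(d), ds$config$wgd_ks, tolerance = 1e-8)
  }
})

test_that("truth is consistent: anchor genes exist in orders and sequences", {
  ds <- wgd_fixture()
  genes <- unique(c(ds$anchors$gene_a, ds$anchors$gene_b))
  expect_true(all(genes %in% ds$orders$gene_id))
  expect_true(all(genes %in% names(ds$cds)))
  expect_true(all(ds$orders$gene_id %in% names(ds$cds)))
})

test_that("emit/load round-trips the dataset and checksums are reproducible", {
  cfg <- sim_config(seed = 21, n_families = 15, codon_length = 60)
  ds <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- emit_dataset(ds, d1)
  m2 <- emit_dataset(simulate_dataset(cfg), d2)
  expect_identical(m1$md5, m2$md5)            # same seed => identical bytes
  expect_setequal(m1$file, setdiff(list.files(d1), "manifest.tsv"))
  back <- load_dataset(d1)
  expect_identical(back$orders, ds$orders)
  expect_identical(back$anchors[order(back$anchors$gene_a), ],
                   ds$anchors[order(ds$anchors$gene_a), ])
  expect_identical(back$cds[sort(names(back$cds))], ds$cds[sort(names(ds$cds))])
  expect_equal(unclass(back$config)[names(unclass(cfg))], unclass(cfg),
               tolerance = 1e-12)
})

test_that("allopolyploid mode lengthens the second homoeologue's divergence", {
  cfg <- sim_config(seed = 6, n_families = 60, retention_prob = 1,
                    fractionation_prob = 0, birth_rate = 0, loss_rate = 0,
                    allopolyploid = TRUE, allo_extra_ks = 0.4, codon_length = 10)
  tr <- make_species_tree(cfg)
  fams <- simulate_gene_trees(tr, cfg)
  f <- fams[[1]]
  lv <- f$leaves[f$leaves$species == "Nymphaea_colorata", ]
  a <- lv$gene_id[lv$wgd_copy == "A"][1]
  b <- lv$gene_id[lv$wgd_copy == "B"][1]
  d <- ape::cophenetic.phylo(f$tree)[a, b]
  expect_equal(unname(d), cfg$wgd_ks + cfg$allo_extra_ks / 2, tolerance = 1e-8)
})
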