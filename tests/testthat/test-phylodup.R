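# Small species tree used throughout: ((A,B)ab,(C,D)cd)root
small_sptree <- function() ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)root;")

test_that("gene trees from clean simulated quartets recover the topology", {
  cfg <- sim_config(codon_length = 400, wgd_branch = NA)
  ref <- ape::read.tree(text = "((a:0.2,b:0.2):0.3,(c:0.2,d:0.2):0.3);")
  s <- evolve_cds(ref, cfg, seed = 4)
  tr <- build_gene_tree(s, n_boot = 100, seed = 1)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))
  tr2 <- build_gene_tree(s, n_boot = 100, seed = 1)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("duplicate sequences form a zero-length cherry", {
  cfg <- sim_config(codon_length = 200, wgd_branch = NA)
  ref <- ape::read.tree(text = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);")
  s <- evolve_cds(ref, cfg, seed = 5)
  s <- c(s, dup = unname(s[["a"]]))
  tr <- build_gene_tree(s, n_boot = 20, seed = 1)
  d <- ape::cophenetic.phylo(tr)["a", "dup"]
  expect_lt(d, 1e-8)
})

test_that("rooting uses the outgroup when monophyletic, else midpoint", {
  sp <- c(g1 = "A", g2 = "B", g3 = "C", og = "OUT")
  tr <- ape::unroot(ape::read.tree(text = "((g1:1,g2:1):1,(g3:1,og:1):1);"))
  r <- root_gene_tree(tr, "OUT", sp)
  expect_equal(attr(r, "rooting"), "outgroup")
  root_children <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1, 2]
  expect_true(match("og", r$tip.label) %in% root_children)

  # two outgroup genes that can never be monophyletic
  sp2 <- c(x1 = "A", o1 = "OUT", x2 = "B", o2 = "OUT")
  tr2 <- ape::unroot(ape::read.tree(text = "((x1:1,o1:1):1,(x2:1,o2:3):1);"))
  r2 <- root_gene_tree(tr2, "OUT", sp2)
  expect_equal(attr(r2, "rooting"), "midpoint")

  expect_warning(root_gene_tree(tr2, "NOT_PRESENT", sp2), "no outgroup")
})

test_that("midpoint rooting bisects the longest leaf-to-leaf path", {
  sp <- c(a = "A", b = "B", c = "C")
  tr <- ape::read.tree(text = "(a:1,b:2,c:4);")
  r <- suppressWarnings(root_gene_tree(tr, "NONE", sp))
  d <- ape::node.depth.edgelength(r)
  # diameter path b-c has length 6; the root should sit 3 from each end
  expect_equal(unname(d[match(c("b", "c"), r$tip.label)]), c(3, 3))
})

test_that("node classification matches species-set logic", {
  sptr <- small_sptree()
  sp <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  # congruent single-copy tree: all speciation
  g <- ape::read.tree(text = "((a1:1,b1:1):1,(c1:1,d1:1):1);")
  cl <- classify_nodes(g, sptr, sp)
  expect_true(all(cl$class == "speciation"))

  # same-species cherry is a duplication
  sp2 <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  g2 <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:1):1,c1:1);")
  cl2 <- classify_nodes(g2, sptr, sp2)
  cherry <- ape::getMRCA(g2, match(c("a1", "a2"), g2$tip.label))
  expect_equal(cl2$class[cl2$node == cherry], "duplication")

  # paralogue spanning a speciation: ((A1, C), A2) -> root duplication
  sp3 <- c(nc1 = "A", cc = "C", nc2 = "A")
  g3 <- ape::read.tree(text = "((nc1:1,cc:1):1,nc2:2);")
  cl3 <- classify_nodes(g3, sptr, sp3)
  root <- ape::Ntip(g3) + 1
  expect_equal(cl3$class[cl3$node == root], "duplication")
  expect_equal(cl3$image_name[cl3$node == root], "root")
})

test_that("node classification equals the brute-force oracle on random trees", {
  sptr <- small_sptree()
  set.seed(17)
  for (r in 1:30) {
    n <- sample(4:8, 1)
    g <- ape::rtree(n)
    sp <- setNames(sample(c("A", "B", "C", "D"), n, replace = TRUE), g$tip.label)
    got <- classify_nodes(g, sptr, sp)
    want <- oracle_classify(g, sptr, sp)
    expect_equal(got$class, want, info = paste("tree", r))
  }
})

test_that("anchor-supported duplications are circumscribed between bounds", {
  sptr <- small_sptree()
  # duplication of an A/B ancestor: copies retained in A only
  sp <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  g <- ape::read.tree(text = "(((a1:1,b1:1)95:1,a2:2)90:1,c1:3)0;")
  cl <- classify_nodes(g, sptr, sp)
  ev <- circumscribe_duplications(g, cl, sptr,
                                  data.frame(gene_a = "a1", gene_b = "a2"))
  expect_true(ev$placed)
  expect_equal(ev$lower, "ab")      # MRCA image of {A,B}
  expect_equal(ev$upper, "root")
  expect_equal(ev$assigned_branch, "ab")
  expect_equal(ev$support, 90)      # branch leading to the duplication node
  expect_true(event_contains_branch(sptr, ev$lower, ev$upper, "ab"))
  expect_false(event_contains_branch(sptr, ev$lower, ev$upper, "cd"))

  # a pair whose MRCA is a speciation node is reported unplaced
  ev2 <- circumscribe_duplications(g, cl, sptr,
                                   data.frame(gene_a = "a1", gene_b = "b1"))
  expect_false(ev2$placed)

  tal <- tally_duplications(rbind(ev, ev, ev), thresholds = c(50, 80, 95))
  expect_equal(tal$n_events[tal$threshold == 50], 3L)
  expect_equal(tal$n_events[tal$threshold == 80], 3L)
  expect_true(!95 %in% tal$threshold)  # support 90 < 95
})

test_that("simulated WGD events are placed on the true branch", {
  ds <- wgd_fixture()
  sp <- species_map(ds)
  anchors <- ds$anchors[ds$anchors$species == "Nymphaea_colorata", ]
  fams <- setNames(ds$families, vapply(ds$families, `[[`, "", "family_id"))
  hits <- 0; tot <- 0
  for (r in seq_len(nrow(anchors))) {
    f <- fams[[anchors$family_id[r]]]
    og <- f$leaves$gene_id[f$leaves$species == "Ginkgo_biloba"]
    if (length(og) == 0 || is.null(f$tree) || ape::Ntip(f$tree) < 4) next
    cds <- ds$cds[f$tree$tip.label]
    tr <- build_gene_tree(cds, n_boot = 50, seed = 100 + r)
    tr <- root_gene_tree(tr, "Ginkgo_biloba", sp)
    cl <- classify_nodes(tr, ds$species_tree, sp)
    ev <- circumscribe_duplications(tr, cl, ds$species_tree, anchors[r, ])
    if (!ev$placed || is.na(ev$support) || ev$support < 80) next
    tot <- tot + 1
    if (event_contains_branch(ds$species_tree, ev$lower, ev$upper, "nymphaeaceae"))
      hits <- hits + 1
    if (tot >= 25) break
  }
  expect_gt(tot, 10)
  expect_gte(hits / tot, 0.9)
})

test_that("the three grade topologies are classified correctly", {
  for (type in c("I", "II", "III")) {
    call <- classify_grade_topology(grade_fixture_tree(type), grade_groups,
                                    grade_species)
    expect_equal(call$label, type, info = type)
    expect_gte(call$support, 80)
  }
  low <- classify_grade_topology(grade_fixture_tree("II", support = 60),
                                 grade_groups, grade_species)
  expect_equal(low$label, "unresolved")
  ok60 <- classify_grade_topology(grade_fixture_tree("II", support = 60),
                                  grade_groups, grade_species, bs_threshold = 50)
  expect_equal(ok60$label, "II")

  no_amb <- ape::drop.tip(grade_fixture_tree("II"), "amb")
  miss <- classify_grade_topology(no_amb, grade_groups, grade_species)
  expect_equal(miss$label, "unresolved")
  expect_match(miss$reason, "absent")
})

test_that("topology tallies report exact percentages", {
  trees <- c(replicate(6, grade_fixture_tree("II"), simplify = FALSE),
             replicate(3, grade_fixture_tree("III"), simplify = FALSE),
             replicate(1, grade_fixture_tree("I"), simplify = FALSE))
  calls <- do.call(rbind, lapply(trees, classify_grade_topology,
                                 groups = grade_groups, species_of = grade_species))
  tal <- tally_topologies(calls)
  expect_equal(tal$pct[tal$label == "II"], 60)
  expect_equal(tal$pct[tal$label == "III"], 30)
  expect_equal(tal$pct[tal$label == "I"], 10)
})

test_that("column trimming matches a direct counting oracle", {
  gapfree <- c(a = "ACGT", b = "TGCA")
  expect_identical(trim_low_coverage_columns(gapfree), gapfree)

  ten <- setNames(rep("AAAA", 10), paste0("s", 1:10))
  ten[1] <- "A-AA"; ten[2] <- "A-AA"      # column 2 coverage 0.8
  out <- trim_low_coverage_columns(ten, 0.9)
  expect_equal(unique(nchar(out)), 3)

  set.seed(23)
  for (r in 1:10) {
    m <- matrix(sample(c("A", "C", "-"), 8 * 12, replace = TRUE, prob = c(.4, .4, .2)),
                8, 12)
    aln <- setNames(apply(m, 1, paste, collapse = ""), paste0("q", 1:8))
    keep <- colMeans(m != "-") >= 0.9
    if (!any(keep)) {
      expect_error(trim_low_coverage_columns(aln, 0.9), "coverage")
    } else {
      out <- trim_low_coverage_columns(aln, 0.9)
      want <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
      expect_equal(unname(out), unname(want))
    }
  }
})
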