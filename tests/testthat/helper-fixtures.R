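options(wgdlens.verbose = FALSE)

# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A mid-sized simulated dataset with a WGD, used by several modules.
wgd_fixture <- function() {
  fixture("wgd_ds", function() {
    simulate_dataset(sim_config(seed = 42, n_families = 120,
                                retention_prob = 0.4,
                                fractionation_prob = 0.1))
  })
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# species lookup from a dataset
species_map <- function(ds) setNames(ds$orders$species, ds$orders$gene_id)

# Tiny constructed alignment helpers
codons_of <- function(...) unlist(list(...))

random_fourfold_cds <- function(n_codons, seed = NULL) {
  stems <- c("GT", "TC", "CC", "AC", "GC", "GG")
  gen <- function() paste0(paste0(sample(stems, n_codons, replace = TRUE),
                                  sample(c("A", "C", "G", "T"), n_codons, replace = TRUE)),
                           collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Constructed ANA-grade topology fixtures (types I/II/III)
grade_fixture_tree <- function(type, support = 95) {
  # mes1/mes2 mesangiosperms, nym Nymphaeales, amb Amborella, gk outgroup
  core <- switch(type,
    I   = sprintf("((mes1:1,mes2:1)%d:1,(nym:1,amb:1)%d:1)", support, support),
    II  = sprintf("(((mes1:1,mes2:1)%d:1,nym:2)%d:1,amb:3)", support, support),
    III = sprintf("(((mes1:1,mes2:1)%d:1,amb:2)%d:1,nym:3)", support, support))
  ape::read.tree(text = paste0("(", core, "0:1,gk:4)0;"))
}

grade_groups <- list(amborella = "Amborella", nymphaeales = "Nymphaea",
                     mesangiosperms = c("Oryza", "Vitis"), outgroup = "Ginkgo")
grade_species <- c(mes1 = "Oryza", mes2 = "Vitis", nym = "Nymphaea",
                   amb = "Amborella", gk = "Ginkgo")

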