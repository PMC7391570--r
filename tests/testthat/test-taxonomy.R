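test_that("valid matches fall within the e-value window of the top hit", {
  h <- one_hit(); h2 <- one_hit(evalue = 5e-10); h$evalue <- 1e-10
  vm <- valid_matches(rbind(h, h2))
  expect_equal(nrow(vm), 2L)  # 5e-10 <= 10 * 1e-10
  h3 <- one_hit(evalue = 2e-9)
  expect_equal(nrow(valid_matches(rbind(h, h3))), 1L)
  expect_equal(nrow(valid_matches(h)), 1L)
  # exact-zero top e-value: only other zero hits qualify
  z <- rbind(one_hit(evalue = 0), one_hit(evalue = 0), one_hit(evalue = 1e-300))
  expect_equal(nrow(valid_matches(z)), 2L)
})

test_that("LCA agrees with the root-path-intersection oracle on random trees", {
  tree <- toy_taxonomy()
  expect_equal(lca("g3", tree), "g3")
  expect_equal(lca(c("g1", "g2"), tree), "f1")   # sibling genera -> parent
  expect_equal(lca(c("g1", "g3"), tree), "p1")
  expect_equal(lca(c("g1", "g8"), tree), "root")

  set.seed(41)
  for (t in 1:5) {
    tree <- taxonomy_tree(random_tree_nodes(500))
    for (s in 1:20) {
      ids <- sample(tree$nodes$node_id, sample(1:6, 1))
      expect_identical(lca(ids, tree), lca_brute(ids, tree))
    }
  }
})

test_that("LCA invariants hold: ancestry, order invariance, idempotence", {
  set.seed(42)
  tree <- taxonomy_tree(random_tree_nodes(200))
  for (s in 1:25) {
    ids <- sample(tree$nodes$node_id, sample(2:5, 1))
    a <- lca(ids, tree)
    for (id in ids) expect_true(a %in% ancestor_path(tree, id))
    expect_identical(lca(rev(ids), tree), a)
    expect_identical(lca(c(ids, a), tree), a)
  }
  expect_error(lca("nope", tree), "nope")
})

test_that("taxonomic assignment uses valid matches and excludes conflicts from genus tables", {
  tree <- toy_taxonomy()
  s2t <- c(pg1 = "g1", pg2 = "g2", pg5 = "g5")
  # all valid matches in one genus -> that genus
  h <- rbind(one_hit("geneA", "pg1", evalue = 1e-20),
             one_hit("geneA", "pg1", evalue = 3e-20))
  a <- assign_taxa(h, tree, s2t)
  expect_equal(a$node_id, "g1")
  expect_equal(a$rank, "genus")
  expect_equal(a$n_valid_matches, 2L)
  # valid matches spanning two phyla -> above genus, excluded from genus table
  h2 <- rbind(one_hit("geneB", "pg1", evalue = 1e-20),
              one_hit("geneB", "pg5", evalue = 2e-20))
  a2 <- assign_taxa(h2, tree, s2t)
  expect_equal(a2$node_id, "root")
  ab <- raw_abund(named_matrix(1, 1, 2, c("x", "s")))
  rownames(ab) <- "geneB"
  expect_equal(nrow(genus_abundance(a2, ab, tree)), 0L)
  # conflicting hit outside the 10x window is ignored
  h3 <- rbind(one_hit("geneC", "pg1", evalue = 1e-20),
              one_hit("geneC", "pg5", evalue = 5e-18))
  expect_equal(assign_taxa(h3, tree, s2t)$node_id, "g1")
  # unmapped subjects are skipped with a warning
  expect_warning(assign_taxa(one_hit("geneD", "mystery"), tree, s2t),
                 "no taxon mapping")
})

test_that("shrinking the valid-match window never yields a shallower assignment", {
  tree <- toy_taxonomy()
  s2t <- setNames(paste0("g", 1:8), paste0("pg", 1:8))
  set.seed(43)
  depth_of <- function(id) length(ancestor_path(tree, id))
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    h <- do.call(rbind, lapply(seq_len(k), function(i)
      one_hit("g", sample(names(s2t), 1), evalue = 10^runif(1, -30, -10))))
    wide <- assign_taxa(h, tree, s2t, factor = 100)$node_id
    narrow <- assign_taxa(h, tree, s2t, factor = 2)$node_id
    expect_gte(depth_of(narrow), depth_of(wide))
  }
})

test_that("genus abundance equals a group-by oracle and conserves mass", {
  tree <- toy_taxonomy()
  ab <- raw_abund(named_matrix(c(0.1, 0.2, 0.7), 3, 1, c("gene", "s")))
  asn <- data.frame(gene_id = c("gene1", "gene2", "gene3"),
                    node_id = c("g1", "g1", "f1"),
                    rank = c("genus", "genus", "family"),
                    n_valid_matches = 1L)
  ga <- genus_abundance(asn, ab, tree)
  expect_equal(unname(ga["g1", "s1"]), 0.3)
  expect_lte(sum(ga), sum(ab))  # family-level gene excluded

  sim <- simulate_study(simulation_config(
    seed = 44, n_genes = 300, planted_taxa = data.frame(
      genus = c("Genus003", "Genus007"), enzyme_family = c("CutC", "GrdH"),
      fold_change = 2)))
  tree <- taxonomy_tree(sim$taxonomy)
  taxa <- assign_taxa(sim$hits_taxonomy, tree, sim$maps$protein_to_taxon)
  # decoys sit outside the window, so every enzyme gene lands in its true genus
  want <- sim$truth$gene_taxon_map[taxa$gene_id]
  expect_identical(setNames(taxa$node_id, taxa$gene_id), want)
  ab <- gene_abundance(sim$counts, sim$catalog)
  ga <- genus_abundance(taxa, ab, tree)
  for (g in rownames(ga)) {
    members <- taxa$gene_id[taxa$node_id == g]
    expect_equal(unname(ga[g, ]), unname(colSums(unclass(ab)[members, , drop = FALSE])))
  }
})
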