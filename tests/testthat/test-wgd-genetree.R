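test_that("scenario b produces mirrored paralogue clades at the DR age", {
  sp <- fixture_species_tree()
  spec <- wgd_scenario("b", wgd_depth = 95, dr_depths = 80)
  gt <- simulate_wgd_gene_tree(sp, c("Eluc", "Dret"), spec)

  expect_true(is_ultrametric(gt))
  ing <- paste0(rep(c("Ssal", "Stru", "Tthy", "Tarc", "Clav", "Calb"), 2),
                "|", rep(c("P1", "P2"), each = 6))
  expect_setequal(gt$tip.label, c(ing, "Eluc", "Dret"))

  # paralogue clades are monophyletic and split at the DR age
  p1 <- grep("\\|P1$", gt$tip.label, value = TRUE)
  p2 <- grep("\\|P2$", gt$tip.label, value = TRUE)
  expect_true(ape::is.monophyletic(gt, p1))
  expect_true(ape::is.monophyletic(gt, p2))
  ages <- salmodiv:::node_ages(gt)
  dup_node <- ape::getMRCA(gt, c(p1, p2))
  expect_equal(unname(ages[dup_node]), 80, tolerance = 1e-6)

  # each paralogue clade mirrors the species tree topology
  sub1 <- ape::keep.tip(gt, p1)
  sub1$tip.label <- sub("\\|P1$", "", sub1$tip.label)
  ing_tree <- ape::keep.tip(sp, sub1$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(sub1), ape::unroot(ing_tree))[1], 0)
})

test_that("scenario b rejects inconsistent ages", {
  sp <- fixture_species_tree()
  out <- c("Eluc", "Dret")
  expect_error(simulate_wgd_gene_tree(
    sp, out, wgd_scenario("b", wgd_depth = 95, dr_depths = 40)),
    "older than the first speciation")
  expect_error(simulate_wgd_gene_tree(
    sp, out, wgd_scenario("b", wgd_depth = 40, dr_depths = 30)),
    "crown age")
  expect_error(simulate_wgd_gene_tree(
    sp, out, wgd_scenario("b", wgd_depth = 130, dr_depths = 125)),
    "outgroup split")
  expect_error(wgd_scenario("b", wgd_depth = 95, dr_depths = 100),
               "<= wgd_depth")
})

test_that("scenario c nests paralogue divergence within lineages", {
  sp <- fixture_species_tree()
  spec <- wgd_scenario("c", wgd_depth = 95, dr_depths = c(48, 42))
  gt <- simulate_wgd_gene_tree(sp, c("Eluc", "Dret"), spec)
  expect_true(is_ultrametric(gt))

  # lineage 1 (Salmoninae + Thymallinae) paralogues form one clade splitting
  # at its own DR age
  l1 <- grep("^(Ssal|Stru|Tthy|Tarc)\\|", gt$tip.label, value = TRUE)
  expect_true(ape::is.monophyletic(gt, l1))
  ages <- salmodiv:::node_ages(gt)
  split1 <- ape::getMRCA(gt, l1)
  expect_equal(unname(ages[split1]), 48, tolerance = 1e-6)
  kids <- salmodiv:::node_children(gt, split1)
  for (k in kids) {
    tips_k <- gt$tip.label[salmodiv:::tips_under(gt, k)]
    expect_true(all(grepl("\\|P1$", tips_k)) || all(grepl("\\|P2$", tips_k)))
  }
})

test_that("scenario d clusters a species' paralogues together", {
  sp <- fixture_species_tree()
  spec <- wgd_scenario("d", wgd_depth = 95, dr_depths = c(48, 42),
                       conversion_strength = 1, unresolved = 1L)
  gt <- simulate_wgd_gene_tree(sp, c("Eluc", "Dret"), spec)
  expect_true(is_ultrametric(gt))
  # full conversion: each unresolved-lineage species' two copies are sisters
  for (spp in c("Ssal", "Stru", "Tthy", "Tarc")) {
    pair <- paste0(spp, c("|P1", "|P2"))
    mrca <- ape::getMRCA(gt, pair)
    expect_setequal(gt$tip.label[salmodiv:::tips_under(gt, mrca)], pair)
  }
  # the resolved lineage keeps its own DR age
  spec2 <- wgd_scenario("d", wgd_depth = 95, dr_depths = c(48, 42),
                        conversion_strength = 0.5, unresolved = 1L)
  gt2 <- simulate_wgd_gene_tree(sp, c("Eluc", "Dret"), spec2)
  ages2 <- salmodiv:::node_ages(gt2)
  a <- unname(ages2[ape::getMRCA(gt2, c("Clav|P1", "Clav|P2"))])
  expect_equal(a, 42, tolerance = 1e-6)
})

test_that("scenario a returns the species tree unchanged", {
  sp <- fixture_species_tree()
  gt <- simulate_wgd_gene_tree(sp, c("Eluc", "Dret"),
                               wgd_scenario("a", wgd_depth = 95))
  expect_identical(write_newick(gt), write_newick(sp))
})
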