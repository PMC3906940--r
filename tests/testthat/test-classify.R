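make_gene_tree <- function(scenario, ...) {
  sp <- fixture_species_tree()
  spec <- switch(scenario,
    b = wgd_scenario("b", wgd_depth = 95, dr_depths = 80),
    c = wgd_scenario("c", wgd_depth = 95, dr_depths = c(48, 42)),
    d = wgd_scenario("d", wgd_depth = 95, dr_depths = c(48, 42),
                     conversion_strength = 1, unresolved = 1L))
  simulate_wgd_gene_tree(sp, c("Eluc", "Dret"), spec)
}

fixture_map <- function(gt) taxon_map_from_tips(gt$tip.label, fixture_subfamilies)

test_that("classifier recovers each simulated scenario", {
  gb <- make_gene_tree("b")
  cb <- classify_diploidization(gb, fixture_map(gb))
  expect_equal(cb$scenario, "resolved_ancestral")
  expect_true(cb$keep)
  expect_true(cb$diagnostics[["two_paralog_clades"]])
  expect_true(cb$diagnostics[["subfamily_representation"]])

  gc <- make_gene_tree("c")
  cc <- classify_diploidization(gc, fixture_map(gc))
  expect_equal(cc$scenario, "lineage_specific")
  expect_false(cc$keep)

  gd <- make_gene_tree("d")
  cd <- classify_diploidization(gd, fixture_map(gd))
  expect_equal(cd$scenario, "unresolved_tetrasomic")
  expect_false(cd$keep)
})

test_that("classifier is invariant to tip permutation and rerooting", {
  gb <- make_gene_tree("b")
  map <- fixture_map(gb)
  base <- classify_diploidization(gb, map)$scenario

  set.seed(42)
  for (i in 1:5) {
    perm <- ape::rotateConstr(gb, sample(gb$tip.label))
    expect_equal(classify_diploidization(perm, map)$scenario, base)
  }
  rerooted <- ape::root(ape::unroot(gb), outgroup = "Dret",
                        resolve.root = TRUE)
  expect_equal(classify_diploidization(rerooted, map)$scenario, base)
})

test_that("support threshold semantics follow the documented rule", {
  gb <- make_gene_tree("b")
  map <- fixture_map(gb)

  # no annotations + min_support set -> ambiguous
  c0 <- classify_diploidization(gb, map, min_support = 0.95)
  expect_equal(c0$scenario, "ambiguous")
  expect_false(c0$keep)

  # annotate every internal node, then the threshold decides
  gb$node.label <- rep("1.0", gb$Nnode)
  c1 <- classify_diploidization(gb, map, min_support = 0.95)
  expect_equal(c1$scenario, "resolved_ancestral")
  expect_equal(c1$support, 1.0)
  gb$node.label <- rep("0.50", gb$Nnode)
  expect_equal(classify_diploidization(gb, map, min_support = 0.95)$scenario,
               "ambiguous")
})

test_that("classifier validates its inputs", {
  gb <- make_gene_tree("b")
  map <- fixture_map(gb)
  expect_error(classify_diploidization(gb, map[-1L, ]), "unmapped")
  expect_error(taxon_map(gb$tip.label,
                         sub("\\|.*$", "", gb$tip.label),
                         rep("Salmoninae", length(gb$tip.label))),
               "outgroup")
})

test_that("a mixed batch is screened like the published 18-of-26 design", {
  trees <- c(lapply(1:18, function(i) make_gene_tree("b")),
             lapply(1:4, function(i) make_gene_tree("c")),
             lapply(1:4, function(i) make_gene_tree("d")))
  maps <- lapply(trees, fixture_map)
  res <- classify_batch(trees, maps)
  expect_equal(sum(res$keep), 18L)
  expect_equal(as.vector(table(res$scenario)[c("resolved_ancestral",
                                               "lineage_specific",
                                               "unresolved_tetrasomic")]),
               c(18L, 4L, 4L))
})
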