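#!/usr/bin/env Rscript
# Generate every synthetic dataset used by the downstream analysis drivers:
#  - a 65-tip BiSSE tree + binary (freshwater/anadromous) tip states at the
#    published posterior-mean rates,
#  - a small 3-subfamily species tree with two outgroups and a batch of 26
#    WGD paralogue gene trees (18 ancestrally resolved + 8 confounded),
#  - HKY codon alignments along the species tree,
#  - a synthetic sea-level series (130 Ma, 1100 points).
# Outputs go to results/data/.

suppressPackageStartupMessages(library(salmodiv))
out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## 1. study tree: BiSSE at the published rates ------------------------------
## state 0 = freshwater (ancestral), state 1 = anadromous (derived)
rates <- bisse_params(lambda0 = 0.09, lambda1 = 0.31,
                      mu0 = 0.04, mu1 = 0.14, q01 = 0.01, q10 = 0.01)
study <- simulate_bisse(rates, n_tips = 65, root_state = 1, seed = 1)
write_newick(study$tree, file.path(out_dir, "study_tree.nwk"))
write_trait_table(study$states, file.path(out_dir, "study_traits.tsv"))
message("study tree: 65 tips, root age ",
        round(max(branching_times(study$tree)$times), 2), " Ma, ",
        sum(study$states == 1), " anadromous tips")

## 2. species tree + WGD gene-tree batch ------------------------------------
species_tree <- read_newick(paste0(
  "(((((Ssal:20,Stru:20):25,(Tthy:25,Tarc:25):20):5,",
  "(Clav:30,Calb:30):20):70,Eluc:120):40,Dret:160);"))
write_newick(species_tree, file.path(out_dir, "species_tree.nwk"))

subfam <- c(Ssal = "Salmoninae", Stru = "Salmoninae",
            Tthy = "Thymallinae", Tarc = "Thymallinae",
            Clav = "Coregoninae", Calb = "Coregoninae",
            Eluc = "outgroup", Dret = "outgroup")
write.table(data.frame(species = names(subfam), subfamily = unname(subfam)),
            file.path(out_dir, "subfamilies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

outgroups <- c("Eluc", "Dret")
scenarios <- c(rep("b", 18), rep("c", 4), rep("d", 4))
gt_dir <- file.path(out_dir, "gene_trees")
dir.create(gt_dir, showWarnings = FALSE)
for (i in seq_along(scenarios)) {
  spec <- switch(scenarios[i],
    b = wgd_scenario("b", wgd_depth = 95, dr_depths = 80),
    c = wgd_scenario("c", wgd_depth = 95, dr_depths = c(48, 42)),
    d = wgd_scenario("d", wgd_depth = 95, dr_depths = c(48, 42),
                     conversion_strength = 1, unresolved = 1L))
  gt <- simulate_wgd_gene_tree(species_tree, outgroups, spec)
  write_newick(gt, file.path(gt_dir, sprintf("gene_tree_%02d.nwk", i)))
}
writeLines(scenarios, file.path(out_dir, "gene_tree_truth.txt"))
message("gene trees: ", length(scenarios), " (",
        sum(scenarios == "b"), " ancestrally resolved)")

## 3. codon alignments along the species tree -------------------------------
hky <- hky_params(kappa = 2.5, pos_rates = c(1, 1, 5))
aln <- simulate_alignment(species_tree, hky, n_codons = 400, rate = 0.002,
                          seed = 11)
write_fasta(aln, file.path(out_dir, "alignment_hky.fasta"))
message("alignment: ", length(aln_taxa(aln)), " x ", aln_length(aln), " bp")

## 4. sea-level series -------------------------------------------------------
sl <- make_sealevel_fixture(n_points = 1100, seed = 19)
write_sealevel(sl, file.path(out_dir, "sealevel.csv"))
message("sea level: ", nrow(sl), " points over 0-",
        round(max(sl$age_ma)), " Ma")
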