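#!/usr/bin/env Rscript
# Concatenation machinery on synthetic paralogue blocks with the published
# matrix dimensions: 18 pairs of blocks summing to 10,833 bp per paralogue,
# 50 randomly sampled paralogue concatenations, the 21,666 bp orthologue
# supermatrix and its 14,444 bp third-position-free reduction.
# Requires: analysis/01_simulate_data.R

suppressPackageStartupMessages(library(salmodiv))
data_dir <- file.path("results", "data")
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

species_tree <- read_newick(file.path(data_dir, "species_tree.nwk"))
hky <- hky_params(kappa = 2.5, pos_rates = c(1, 1, 5))

# 18 paralogue pairs: each member simulated independently along the species
# tree; block lengths sum to 10,833 bp (17 x 600 + 633)
lens <- c(rep(600L, 17L), 633L)
pairs <- lapply(seq_along(lens), function(j) {
  lapply(1:2, function(member)
    simulate_alignment(species_tree, hky, n_codons = lens[j] / 3L,
                       rate = 0.002, seed = 100 * j + member))
})
set <- enumerate_concatenations(pairs, outgroups = c("Eluc", "Dret"))
message(format(set$n_total, big.mark = ","), " assignments (",
        format(set$n_canonical, big.mark = ","), " canonical), ",
        sum(set$block_lengths), " bp per paralogue")

samp <- sample_concatenations(set, 50, seed = 7)
samp_tab <- data.frame(
  draw = seq_along(samp),
  assignment = vapply(samp, function(a)
    paste(attr(a, "assignment"), collapse = ""), character(1L)),
  n_taxa = vapply(samp, function(a) length(aln_taxa(a)), integer(1L)),
  columns = vapply(samp, aln_length, integer(1L)))
write.table(samp_tab, file.path(out_dir, "03_sampled_concatenations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_fasta(samp[[1L]], file.path(out_dir, "03_concatenation_draw1.fasta"))

sm <- concat_orthologs(pairs, outgroups = c("Eluc", "Dret"))
sm12 <- codon_partition(sm, keep = c(1, 2))
dims <- data.frame(
  matrix = c("paralogue concatenation", "orthologue supermatrix",
             "orthologue supermatrix, positions 1+2"),
  rows = c(length(aln_taxa(samp[[1L]])), length(aln_taxa(sm)),
           length(aln_taxa(sm12))),
  columns = c(aln_length(samp[[1L]]), aln_length(sm), aln_length(sm12)))
write.table(dims, file.path(out_dir, "03_matrix_dimensions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("supermatrix: ", aln_length(sm), " bp -> ", aln_length(sm12),
        " bp without third positions")
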