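#!/usr/bin/env Rscript
# Screen the simulated WGD paralogue gene trees with the
# diploidization-resolution classifier and write the keep/discard table
# (the analogue of the published 18-of-26 screen).
# Requires: analysis/01_simulate_data.R

suppressPackageStartupMessages(library(salmodiv))
data_dir <- file.path("results", "data")
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

subfam_df <- read.delim(file.path(data_dir, "subfamilies.tsv"))
subfam <- stats::setNames(subfam_df$subfamily, subfam_df$species)
truth <- readLines(file.path(data_dir, "gene_tree_truth.txt"))

files <- sort(list.files(file.path(data_dir, "gene_trees"),
                         full.names = TRUE))
trees <- lapply(files, read_newick)
maps <- lapply(trees, function(gt) taxon_map_from_tips(gt$tip.label, subfam))

res <- classify_batch(trees, maps)
res$file <- basename(files)
res$truth <- truth
write.table(res, file.path(out_dir, "02_classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("classified ", nrow(res), " gene trees; kept ", sum(res$keep))
agree <- mean((res$scenario == "resolved_ancestral") == (res$truth == "b"))
message("keep/discard agreement with simulation truth: ",
        round(100 * agree), "%")
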