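#!/usr/bin/env Rscript

# Stage 3: panel selection.
#
# Clusters the candidate genes by expression correlation, annotates cell
# types from blood-count correlations, screens normalization-gene
# candidates, summarizes sex-stratified effect directions, and assembles a
# ranked RT-PCR panel.

suppressMessages(library(cadscore))

expr <- read_expression("results/cohort_expression.tsv")
samples <- read_samples("results/cohort_samples.csv")
assoc <- utils::read.delim("results/association_unpaired.tsv",
                           stringsAsFactors = FALSE)

clusters <- cluster_genes(expr, corr_cutoff = 0.3)
cat(sprintf("clustering: %d clusters over %d genes\n",
            length(unique(clusters$cluster)), nrow(clusters)))
utils::write.table(clusters, "results/gene_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

tags <- assign_cell_types(expr, samples)
utils::write.table(tags, "results/cell_type_tags.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

norm_cand <- select_normalization_candidates(expr, samples)
cat(sprintf("normalization candidates: %d genes; top 3: %s\n",
            nrow(norm_cand),
            paste(utils::head(norm_cand$gene, 3), collapse = ", ")))
utils::write.table(norm_cand, "results/normalization_candidates.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

dirs <- sex_stratified_direction(expr, samples)
utils::write.table(dirs$tally, "results/sex_direction_tally.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

panel <- select_panel(assoc, clusters, panel_size = 60)
writeLines(panel, "results/selected_panel.txt")
cat(sprintf("panel: %d genes selected\n", length(panel)))
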