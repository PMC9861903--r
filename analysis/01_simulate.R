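#!/usr/bin/env Rscript
# Build the ground-truthed synthetic dataset used throughout the analysis:
# a 5 Mb, 2-chromosome genome fragmented into 40 contigs, scaffolded
# Hi-C-style with fixed 100 bp gap fillers, with 8 injected misjoins
# (4 translocations, 2 inversions, 2 chimeric fusions), noisy optical label
# maps for two nicking enzymes, and 30x simulated long-read alignments.
#
# Writes results/dataset/ (FASTA + AGP + CMAP + PAF + BED + JSON).

library(scaffval)

cfg <- sim_config(seed = 42,
                  misjoins = c(TRANSLOCATION = 4, INVERSION = 2, FUSION = 2))
ds <- simulate_dataset(cfg)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "results/dataset")
saveRDS(ds, "results/dataset.rds")   # convenience for the later steps

jt <- junction_truth(ds$truth)
cat(sprintf("genome: %d bp in %d chromosomes; %d contigs\n",
            sum(Biostrings::width(ds$genome)), length(ds$genome),
            length(ds$truth$contigs)))
cat(sprintf("observed layout: %d scaffolds, %d Hi-C junctions (%d misjoined)\n",
            length(unique(ds$truth$observed_layout$components$scaffold)),
            nrow(jt), sum(!jt$intact)))
cat(sprintf("query maps: %d; read records: %d\n",
            length(ds$query_maps), nrow(ds$reads)))
print(ds$truth$misjoin_records)
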