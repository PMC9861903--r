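#!/usr/bin/env Rscript
# Before/after assembly statistics, the contig-length error profile, and
# the published worked-example percentages.
#
# Reads results/dataset.rds and results/validation.rds; writes
# results/stats_before.tsv, results/stats_after.tsv, results/compare.tsv,
# results/error_by_length.tsv.

library(scaffval)

ds <- readRDS("results/dataset.rds")
res <- readRDS("results/validation.rds")

as_tsv <- function(x, path) {
  utils::write.table(tibble::tibble(field = names(x),
                                    value = as.numeric(unlist(x))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
as_tsv(res$stats_before, "results/stats_before.tsv")
as_tsv(res$stats_after, "results/stats_after.tsv")
cmp <- compare_runs(res$stats_before, res$stats_after)
utils::write.table(cmp, "results/compare.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
print(as.data.frame(cmp))
cat(sprintf("\ncutting confirmed conflicts: N50 %s -> %s (fold %.3f), %d -> %d scaffolds\n",
            format(res$stats_before$scaffold_n50, big.mark = ","),
            format(res$stats_after$scaffold_n50, big.mark = ","),
            res$stats_after$scaffold_n50 / res$stats_before$scaffold_n50,
            res$stats_before$n_scaffolds, res$stats_after$n_scaffolds))

# which contigs flank a misjoined junction?
jt <- junction_truth(ds$truth)
involved <- unique(c(jt$left_comp[!jt$intact], jt$right_comp[!jt$intact]))
tab <- error_rate_by_contig_length(ds$truth$observed_layout, involved,
                                   bin_width = 50000)
utils::write.table(tab, "results/error_by_length.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(as.data.frame(tab[tab$n_contigs > 0, ]))

# worked-example percentages from published junction-review counts
cat("\npublished worked examples (count ratios -> integer percent):\n")
cat(sprintf("  50/62 reviewed junctions unsupported -> %d%% (nearest)\n",
            percentage_summary(50, 62, "nearest")))
cat(sprintf("  12/62 supported -> %d%% (nearest)\n",
            percentage_summary(12, 62, "nearest")))
cat(sprintf("  21/48 scaffolds cut -> %d%% (floor)\n",
            percentage_summary(21, 48, "floor")))
cat(sprintf("  24/29 scaffolds cut -> %d%% (floor)\n",
            percentage_summary(24, 29, "floor")))
cat(sprintf("  21/29 chromosomes with errors -> %d%% (floor)\n",
            percentage_summary(21, 29, "floor")))
cat(sprintf("  5/6 contigs in the modal length bin -> %d%% (floor)\n",
            percentage_summary(5, 6, "floor")))
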