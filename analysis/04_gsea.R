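#!/usr/bin/env Rscript

# Stage 4: absolute GSEA. Proteins are ranked by |d|, each gene set scored
# with the weighted running sum, significance assessed against a
# gene-label permutation null, and the leading-edge component extracted
# for every set.

suppressPackageStartupMessages(library(spectralcounts))

root_seed <- 1L
de <- utils::read.delim("results/differential/de_table.tsv")
sets <- read_gmt("results/study/genesets.gmt", source = "simulated")

ranked <- build_ranked_list(de)
res <- run_gsea_collection(ranked, sets, P = 1000,
                           seed = substream_seed(root_seed, "gsea"))

cat(sprintf("%d of %d sets significant at nominal p < 0.05\n",
            sum(res$significant), nrow(res)))
cat(sprintf("median leading-edge size among significant sets: %d\n",
            as.integer(median(lengths(res$component[res$significant])))))

dir.create("results/gsea", showWarnings = FALSE)
flat <- res[, setdiff(names(res), "component")]
flat$component <- vapply(res$component, paste, character(1), collapse = ",")
utils::write.table(flat, "results/gsea/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
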