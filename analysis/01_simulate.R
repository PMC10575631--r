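#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study that stands in for the deposited
# 16-run organoid proteomics experiment: ~4,000 proteins, 8 healthy + 8
# patient samples, overdispersed sparse spectral counts with 10% planted
# differential proteins (4-fold shifts), peptide-level evidence, 500 gene
# sets (10% planted around the signal), and the planted-truth sidecar.

suppressPackageStartupMessages(library(spectralcounts))

root_seed <- 1L
dir.create("results/study", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = root_seed)
sim <- simulate_counts(cfg)
peptides <- simulate_peptides(sim$counts, c(1, 5),
                              seed = substream_seed(root_seed, "peptides"))
gs <- simulate_genesets(rownames(sim$counts), cfg, sim$truth)
dcfg <- cfg
dcfg$n_sets <- 50L
dcfg$set_size_range <- c(10L, 40L)
dcfg$seed <- substream_seed(root_seed, "disease")
dis <- simulate_genesets(rownames(sim$counts), dcfg, gs$truth,
                         prefix = "DIS")
truth <- gs$truth
truth$planted_disease_terms <- dis$truth$planted_sets

write_count_matrix(sim$counts, "results/study/counts.tsv")
write_design(sim$design, "results/study/design.tsv")
utils::write.table(peptides, "results/study/peptides.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_gmt(gs$collection, "results/study/genesets.gmt")
write_gmt(dis$collection, "results/study/disease.gmt")
jsonlite::write_json(truth, "results/study/truth.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("simulated %d proteins x %d samples; %d planted differential (%d up, %d down)\n",
            nrow(sim$counts), ncol(sim$counts),
            length(sim$truth$de_proteins),
            sum(sim$truth$directions == "up"),
            sum(sim$truth$directions == "down")))
cat(sprintf("peptide table: %d rows; gene sets: %d (%d planted); disease terms: %d\n",
            nrow(peptides), length(gs$collection),
            length(gs$truth$planted_sets), length(dis$collection)))
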