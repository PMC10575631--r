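#!/usr/bin/env Rscript

# Stage 2: protein inference and normalization. The peptide table goes
# through the two-peptide rule, the >= 4-sample detection filter, and the
# calibrated glog variance-stabilizing transform; sample-level QC (PCA,
# Ward clustering of samples) is exported alongside.

suppressPackageStartupMessages(library(spectralcounts))

peptides <- read_peptide_table("results/study/peptides.tsv")
design <- read_design("results/study/design.tsv")

counts <- aggregate_proteins(peptides, min_peptides = 2)
cat(sprintf("two-peptide rule: %d -> %d proteins\n",
            length(unique(peptides$protein_id)), nrow(counts)))

filtered <- variation_filter(counts, min_detected_samples = 4)
cat(sprintf("detection filter (>=4 samples): %d -> %d proteins\n",
            nrow(counts), nrow(filtered)))

nm <- glog_normalize(filtered)
cat(sprintf("glog normalization: phi-hat = %.3f, sample scales %.2f-%.2f\n",
            nm$phi, min(nm$params$scale), max(nm$params$scale)))

pca <- pca_scores(nm)
hc <- ward_clustering(nm, "columns")

dir.create("results/normalized", showWarnings = FALSE)
write_count_matrix(filtered, "results/normalized/filtered_counts.tsv")
write_count_matrix(round(nm$values, 6), "results/normalized/glog.tsv")
jsonlite::write_json(list(params = nm$params, phi = nm$phi),
                     "results/normalized/transform_params.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
utils::write.table(
  data.frame(sample_id = rownames(pca$scores),
             PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
             condition = design$condition[match(rownames(pca$scores),
                                                design$sample_id)]),
  "results/normalized/pca_scores.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
writeLines(paste(hc$labels[hc$order], collapse = "\t"),
           "results/normalized/sample_dendrogram_order.tsv")

cat(sprintf("PC1 explains %.1f%% of variance; sample leaf order written\n",
            100 * pca$explained[1]))
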