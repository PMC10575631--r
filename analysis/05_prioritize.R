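#!/usr/bin/env Rscript

# Stage 5: prioritization cascade. Count each protein's occurrences across
# the leading edges of significant pathways, keep the top-90th-percentile
# frequencies, then require |signed fold change| >= 3 and >= 10 total
# spectra; finally test the survivors for disease-library
# over-representation.

suppressPackageStartupMessages(library(spectralcounts))

counts <- read_count_matrix("results/normalized/filtered_counts.tsv")
design <- read_design("results/study/design.tsv")
enr <- utils::read.delim("results/gsea/enrichment.tsv")
enr$component <- strsplit(enr$component, ",", fixed = TRUE)
class(enr) <- c("gsea_result", class(enr))
disease_libs <- list(simulated_disease = read_gmt("results/study/disease.gmt"))

freq <- frequency_table(enr)
fc <- fold_change(counts, design, c("healthy", "patient1"))
spectra <- setNames(rowSums(counts), rownames(counts))
cand <- filter_cascade(freq, fc, spectra)
final <- cand$protein_id[cand$candidate]

cat(sprintf("frequency table: %d proteins across %d significant pathways\n",
            nrow(freq), sum(enr$significant)))
cat(sprintf("funnel: %d in top-90th percentile -> %d with |fc| >= 3 -> %d with >= 10 spectra\n",
            sum(cand$passed_percentile),
            sum(cand$passed_percentile & cand$passed_fc),
            length(final)))

dir.create("results/prioritize", showWarnings = FALSE)
utils::write.table(freq, "results/prioritize/frequency.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cand, "results/prioritize/candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

if (length(final)) {
  dis <- disease_frequency(final, disease_libs, rownames(counts))
  related <- dis$proteins$protein_id[dis$proteins$n_terms > 0]
  cat(sprintf("%d of %d candidates carry >= 1 significant disease term\n",
              length(related), length(final)))
  flat <- dis$proteins[, c("protein_id", "n_terms")]
  flat$terms <- vapply(dis$proteins$terms, paste, character(1),
                       collapse = ",")
  utils::write.table(flat, "results/prioritize/disease_frequency.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dis$tests[[1]], "results/prioritize/overrep_tests.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
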