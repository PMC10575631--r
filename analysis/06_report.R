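#!/usr/bin/env Rscript

# Stage 6: score the whole run against the planted truth and collate the
# funnel into one summary.

suppressPackageStartupMessages(library(spectralcounts))

counts <- read_count_matrix("results/normalized/filtered_counts.tsv")
truth <- jsonlite::read_json("results/study/truth.json",
                             simplifyVector = TRUE)
de <- utils::read.delim("results/differential/de_table.tsv")
enr <- utils::read.delim("results/gsea/enrichment.tsv")
cand <- utils::read.delim("results/prioritize/candidates.tsv")

final <- cand$protein_id[cand$candidate]
truth_de <- intersect(truth$de_proteins, rownames(counts))
N <- nrow(counts)
k <- length(intersect(final, truth_de))
enrich_p <- phyper(k - 1, length(truth_de), N - length(truth_de),
                   length(final), lower.tail = FALSE)

planted_sets <- truth$planted_sets
sig_sets <- enr$set[enr$significant]
set_recall <- mean(planted_sets %in% sig_sets)

summary <- list(
  n_quantified = N,
  n_planted_de = length(truth_de),
  n_de_selected = sum(de$selected),
  de_selected_precision = if (sum(de$selected)) {
    mean(de$protein_id[de$selected] %in% truth_de)
  } else 0,
  n_significant_pathways = length(sig_sets),
  planted_set_recall = set_recall,
  n_candidates = length(final),
  candidate_precision = if (length(final)) k / length(final) else 0,
  candidate_truth_enrichment_p = enrich_p
)
jsonlite::write_json(summary, "results/summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

cat(sprintf("quantified %d proteins (%d planted differential among them)\n",
            N, length(truth_de)))
cat(sprintf("differential selection: %d proteins, precision %.2f\n",
            summary$n_de_selected, summary$de_selected_precision))
cat(sprintf("pathways: %d significant; planted-set recall %.2f\n",
            length(sig_sets), set_recall))
cat(sprintf("final candidates: %d, precision %.2f, truth-enrichment p = %.3g\n",
            length(final), summary$candidate_precision, enrich_p))
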