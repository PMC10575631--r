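# Candidate prioritization: frequency across enriched pathway components,
# percentile selection, fold-change / spectral-count filters, and
# disease-library over-representation.

#' Protein frequency across enriched components of significant pathways
#'
#' For each protein, the number of significant pathways (pooled over all
#' supplied enrichment results, i.e. across gene-set collections and
#' contrasts) whose enriched component contains it. Non-significant
#' pathways contribute nothing; proteins absent from every component are
#' absent from the table.
#'
#' @param results a [run_gsea_collection()] result or a list of them.
#' @return data.frame with protein_id and frequency, sorted by decreasing
#'   frequency then id.
#' @export
frequency_table <- function(results) {
  if (inherits(results, "gsea_result")) results <- list(results)
  comps <- unlist(lapply(results, function(r) {
    r$component[r$significant]
  }), recursive = FALSE)
  members <- unlist(comps, use.names = FALSE)
  if (length(members) == 0) {
    return(data.frame(protein_id = character(0), frequency = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(members)
  out <- data.frame(protein_id = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$protein_id), , drop = FALSE]
}

#' Nearest-rank percentile selection of high-frequency proteins
#'
#' The threshold is the nearest-rank percentile of the frequency values
#' (the value at position ceiling(percentile/100 * n) of the sorted
#' frequencies); every protein with frequency at or above the threshold is
#' selected, so ties at the threshold are all included.
#'
#' @param freq a [frequency_table()] data.frame.
#' @param percentile percentile in (0, 100), default 90.
#' @return character vector of selected protein ids.
#' @export
percentile_select <- function(freq, percentile = 90) {
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 100) {
    stop("percentile must be a single number in (0, 100)", call. = FALSE)
  }
  if (nrow(freq) == 0) stop("frequency table is empty", call. = FALSE)
  v <- sort(freq$frequency)
  thr <- v[ceiling(percentile / 100 * length(v))]
  freq$protein_id[freq$frequency >= thr]
}

#' Signed fold change on the count scale
#'
#' The ratio of the test-group mean count to the reference-group mean
#' count, with each mean floored at one spectrum (a mean below one spectral
#' count is background), reported under the signed-ratio convention:
#' r if r >= 1, else -1/r, so the up/down thresholds +3 and -3 are
#' symmetric.
#'
#' @param counts protein x sample count matrix.
#' @param design study design.
#' @param contrast character pair (reference condition, test condition).
#' @param pseudocount floor applied to each group mean (default 1).
#' @return named numeric vector of signed fold changes, one per protein.
#' @export
fold_change <- function(counts, design, contrast, pseudocount = 1) {
  design <- check_design(design, colnames(counts))
  grp <- contrast_samples(design, contrast, colnames(counts))
  m_ref <- pmax(rowMeans(counts[, grp$reference, drop = FALSE]), pseudocount)
  m_tst <- pmax(rowMeans(counts[, grp$test, drop = FALSE]), pseudocount)
  r <- m_tst / m_ref
  ifelse(r >= 1, r, -1 / r)
}

#' Apply the fold-change / spectral-count filter cascade
#'
#' Combines the three prioritization filters into a candidate table:
#' membership in the top-frequency percentile, absolute signed fold change
#' >= `fc_cut`, and total spectral count >= `spectra_cut`. The filters
#' commute; the final candidates are the conjunction of the three flags,
#' partitioned into up- and downregulated by fold-change sign.
#'
#' @param freq a [frequency_table()] data.frame.
#' @param fold_changes named signed fold-change vector (see [fold_change()]).
#' @param total_spectra named total spectral-count vector.
#' @param percentile frequency percentile cutoff (default 90).
#' @param fc_cut absolute fold-change threshold (inclusive, default 3).
#' @param spectra_cut total spectral-count threshold (inclusive, default 10).
#' @return data.frame of class `candidate_list`: protein_id, frequency,
#'   fold_change, total_spectra, direction, passed_percentile, passed_fc,
#'   passed_spectra, candidate.
#' @export
filter_cascade <- function(freq, fold_changes, total_spectra,
                           percentile = 90, fc_cut = 3, spectra_cut = 10) {
  ids <- freq$protein_id
  sel <- percentile_select(freq, percentile)
  fc <- fold_changes[ids]
  sp <- total_spectra[ids]
  if (any(is.na(fc)) || any(is.na(sp))) {
    stop("fold_changes / total_spectra missing for some frequency-table proteins",
         call. = FALSE)
  }
  out <- data.frame(
    protein_id = ids,
    frequency = freq$frequency,
    fold_change = as.numeric(fc),
    total_spectra = as.numeric(sp),
    direction = ifelse(fc >= 0, "up", "down"),
    passed_percentile = ids %in% sel,
    passed_fc = abs(fc) >= fc_cut,
    passed_spectra = sp >= spectra_cut,
    stringsAsFactors = FALSE
  )
  out$candidate <- out$passed_percentile & out$passed_fc & out$passed_spectra
  class(out) <- c("candidate_list", class(out))
  out
}

#' Over-representation of an annotation library in a query set
#'
#' One-sided Fisher exact (hypergeometric upper-tail) p-value of the
#' overlap between the query and each term, against the quantified-protein
#' universe. Term membership is restricted to the universe before testing
#' (detection bias: only quantified proteins could ever be in the query).
#'
#' @param query character vector of protein ids (non-empty, within universe).
#' @param library named list of term member vectors (see [read_gmt()]).
#' @param universe character vector of quantifiable protein ids.
#' @param sig_p significance cutoff for the `significant` flag.
#' @return data.frame: term, term_size, overlap, p, significant.
#' @export
term_overrepresentation <- function(query, library, universe, sig_p = 0.05) {
  if (length(query) == 0) stop("query set is empty", call. = FALSE)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop(sprintf("query ids outside the universe: %s",
                 paste(utils::head(extra, 3), collapse = ", ")), call. = FALSE)
  }
  N <- length(universe)
  q <- length(unique(query))
  rows <- lapply(names(library), function(nm) {
    members <- intersect(library[[nm]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, q, lower.tail = FALSE)
    data.frame(term = nm, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < sig_p
  out[order(out$p, out$term), , drop = FALSE]
}

#' Per-protein counts of significant disease terms
#'
#' Runs [term_overrepresentation()] of the candidate set against each
#' disease library, then counts for every candidate the significant terms
#' (across libraries) whose member lists contain it. Candidates with at
#' least one such term form the clinically related subset.
#'
#' @param candidates character vector of candidate protein ids.
#' @param libraries named list of GMT-style libraries (each a named list of
#'   member vectors).
#' @param universe quantified-protein universe for the overlap tests.
#' @param sig_p per-term significance cutoff.
#' @return list with `proteins` (data.frame protein_id, n_terms, and a
#'   `terms` list-column of "library::term" labels) and `tests` (the
#'   per-library over-representation tables).
#' @export
disease_frequency <- function(candidates, libraries, universe, sig_p = 0.05) {
  tests <- lapply(libraries, function(lib) {
    term_overrepresentation(candidates, lib, universe, sig_p = sig_p)
  })
  term_labels <- list()
  for (lib_name in names(libraries)) {
    sig_terms <- tests[[lib_name]]$term[tests[[lib_name]]$significant]
    for (tm in sig_terms) {
      term_labels[[paste0(lib_name, "::", tm)]] <-
        intersect(libraries[[lib_name]][[tm]], candidates)
    }
  }
  counts <- vapply(candidates, function(p) {
    sum(vapply(term_labels, function(mem) p %in% mem, logical(1)))
  }, integer(1))
  terms_per_protein <- lapply(candidates, function(p) {
    names(term_labels)[vapply(term_labels, function(mem) p %in% mem,
                              logical(1))]
  })
  proteins <- data.frame(protein_id = candidates, n_terms = counts,
                         stringsAsFactors = FALSE, row.names = NULL)
  proteins$terms <- terms_per_protein
  list(proteins = proteins, tests = tests)
}
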