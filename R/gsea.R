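# Absolute gene-set enrichment analysis.
#
# Proteins are ranked by the magnitude of their differential statistic
# (ranking by |d| rather than signed d is what makes the analysis
# "absolute": coordinated up- and down-regulation both push a set toward
# the top). Enrichment uses the classical weighted running-sum statistic;
# significance comes from a gene-label permutation null (random same-size
# sets), which stays well-defined at the small group sizes typical of
# organoid proteomics where sample permutations are too few.

#' Build the |statistic|-ranked protein list
#'
#' @param result a [rots_de()] table (protein_id, d).
#' @param tie_seed optional integer; when given, ties in |d| are shuffled
#'   under this seed (and the seed recorded as an attribute), otherwise
#'   ties break deterministically by protein id.
#' @return data.frame of class `ranked_list` with protein_id and score
#'   (= |d|), in descending score order.
#' @export
build_ranked_list <- function(result, tie_seed = NULL) {
  if (anyDuplicated(result$protein_id)) {
    stop("duplicate protein ids in the result table", call. = FALSE)
  }
  score <- abs(result$d)
  if (any(!is.finite(score))) stop("statistics must be finite", call. = FALSE)
  if (is.null(tie_seed)) {
    ord <- order(-score, result$protein_id)
  } else {
    shuffle <- with_seed(substream_seed(tie_seed, "rank_ties"),
                         sample.int(length(score)))
    ord <- order(-score, shuffle)
  }
  out <- data.frame(protein_id = result$protein_id[ord], score = score[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tie_seed") <- tie_seed
  class(out) <- c("ranked_list", class(out))
  out
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, set members ("hits") increment the running
#' sum by |r_i|^weight_p / sum_hits |r_j|^weight_p and non-members decrement
#' it by 1 / (N - N_H). The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (on exact magnitude ties between a
#' positive and a negative extremum, the earlier one wins); with
#' weight_p = 0 this is the classical Kolmogorov-Smirnov running-sum
#' statistic.
#'
#' @param ranked a [build_ranked_list()] object.
#' @param geneset character vector of member ids.
#' @param weight_p hit-weight exponent (default 1).
#' @param return_running also return the full N-long running sum.
#' @return list with `es`, `peak_index` (1-based rank where |running sum|
#'   peaks; 0 when the score is 0), `n_hits`, and optionally `running_sum`.
#' @export
enrichment_score <- function(ranked, geneset, weight_p = 1,
                             return_running = FALSE) {
  ids <- ranked$protein_id
  N <- length(ids)
  pos <- sort(match(intersect(geneset, ids), ids))
  if (length(pos) == 0) stop("gene set is disjoint from the ranked universe",
                             call. = FALSE)
  if (length(pos) == N) stop("gene set covers the whole universe",
                             call. = FALSE)
  w <- abs(ranked$score[pos])^weight_p
  core <- es_core(pos, w, N)
  out <- list(es = core$es, peak_index = core$peak_index,
              n_hits = length(pos))
  if (return_running) {
    run <- numeric(N)
    run[pos] <- (if (sum(w) > 0) w / sum(w) else 0) + 1 / (N - length(pos))
    run <- cumsum(run - 1 / (N - length(pos)))
    out$running_sum <- run
  }
  out
}

# O(m) enrichment score from sorted hit positions. The running sum is
# piecewise linear between hits, so its extrema sit just before or just
# after a hit; both candidate families are scanned in closed form.
es_core <- function(pos, w, N) {
  m <- length(pos)
  W <- sum(w)
  miss_step <- 1 / (N - m)
  csum <- if (W > 0) cumsum(w) / W else numeric(m)
  after <- csum - (pos - seq_len(m)) * miss_step
  before <- c(0, csum[-m]) - (pos - seq_len(m)) * miss_step
  vals <- c(before, after)
  idx <- c(pos - 1L, pos)
  best <- max(abs(vals))
  if (best == 0) return(list(es = 0, peak_index = 0L))
  # positive and negative extrema can tie in magnitude exactly (they are
  # small rationals); the convention is the earliest peak, judged within
  # 1e-9 so float noise cannot flip the sign
  cand <- which(abs(vals) >= best - 1e-9)
  pick <- cand[which.min(idx[cand])]
  list(es = vals[pick], peak_index = as.integer(idx[pick]))
}

#' Permutation significance of one set's enrichment score
#'
#' The null distribution is generated by gene-label permutation: P random
#' sets of the same size drawn from the ranked universe. NES is the
#' observed ES divided by the mean null ES of matching sign;
#' nominal_p = (1 + #\{null |ES| >= |ES|\}) / (1 + P).
#'
#' @param ranked a [build_ranked_list()] object.
#' @param geneset character member vector.
#' @param P number of permutations (>= 1; >= 100 recommended).
#' @param weight_p hit-weight exponent.
#' @param seed integer seed.
#' @return list with `es`, `nes`, `nominal_p`, `peak_index`, `n_hits`.
#' @export
gsea_permutation <- function(ranked, geneset, P = 1000, weight_p = 1,
                             seed = 1) {
  if (P < 1) stop("field 'P' must be >= 1", call. = FALSE)
  obs <- enrichment_score(ranked, geneset, weight_p)
  N <- nrow(ranked)
  m <- obs$n_hits
  scores <- abs(ranked$score)^weight_p
  null_es <- with_seed(substream_seed(seed, "gsea_null"), {
    vapply(seq_len(P), function(i) {
      p <- sort(sample.int(N, m))
      es_core(p, scores[p], N)$es
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  denom <- if (length(same_sign) > 0) mean(abs(same_sign)) else mean(abs(null_es))
  nes <- if (obs$es == 0 || denom == 0) 0 else obs$es / denom
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + P)
  list(es = obs$es, nes = nes, nominal_p = p,
       peak_index = obs$peak_index, n_hits = m)
}

#' Leading-edge (enriched) component of a set
#'
#' For a positive enrichment score, the set members at ranks at or before
#' the running-sum peak; for a negative score, the members at or after it.
#' These are the proteins that drive the enrichment.
#'
#' @param ranked a [build_ranked_list()] object.
#' @param geneset character member vector.
#' @param es_result the [enrichment_score()] / [gsea_permutation()] result.
#' @return character vector of protein ids (in rank order).
#' @export
enriched_component <- function(ranked, geneset, es_result) {
  ids <- ranked$protein_id
  pos <- sort(match(intersect(geneset, ids), ids))
  if (es_result$es >= 0) {
    ids[pos[pos <= es_result$peak_index]]
  } else {
    ids[pos[pos >= es_result$peak_index]]
  }
}

#' Absolute GSEA over a whole collection
#'
#' Runs [gsea_permutation()] for every set with at least `min_overlap`
#' members in the ranked universe (smaller sets are skipped with a
#' warning); flags sets with nominal p < `sig_p` as significant and
#' extracts each set's enriched component.
#'
#' @param ranked a [build_ranked_list()] object.
#' @param collection named list of member vectors (see [read_gmt()]).
#' @param P permutations per set.
#' @param weight_p hit-weight exponent.
#' @param min_overlap minimum overlap with the universe (default 3).
#' @param sig_p nominal significance cutoff.
#' @param seed integer seed.
#' @return data.frame of class `gsea_result`: set, size, n_hits, es, nes,
#'   nominal_p, significant, and a `component` list-column.
#' @export
run_gsea_collection <- function(ranked, collection, P = 1000, weight_p = 1,
                                min_overlap = 3, sig_p = 0.05, seed = 1) {
  ids <- ranked$protein_id
  N <- length(ids)
  overlap <- vapply(collection, function(s) sum(s %in% ids), integer(1))
  usable <- overlap >= min_overlap & overlap < N
  if (any(!usable)) {
    warning(sprintf("skipping %d set(s) with universe overlap < %d or = universe",
                    sum(!usable), min_overlap), call. = FALSE)
  }
  sets <- collection[usable]
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    gp <- gsea_permutation(ranked, sets[[i]], P = P, weight_p = weight_p,
                           seed = substream_seed(seed, names(sets)[i]))
    rows[[i]] <- data.frame(
      set = names(sets)[i], size = length(sets[[i]]), n_hits = gp$n_hits,
      es = gp$es, nes = gp$nes, nominal_p = gp$nominal_p,
      significant = gp$nominal_p < sig_p, stringsAsFactors = FALSE
    )
    rows[[i]]$component <- list(enriched_component(ranked, sets[[i]], gp))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size = integer(0), n_hits = integer(0),
               es = numeric(0), nes = numeric(0), nominal_p = numeric(0),
               significant = logical(0))
  attr(out, "source") <- attr(collection, "source")
  attr(out, "n_skipped") <- sum(!usable)
  class(out) <- c("gsea_result", class(out))
  out
}
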