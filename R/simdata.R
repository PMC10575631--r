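# Synthetic spectral-count data with known planted truth.
#
# The simulator emulates a label-free shotgun proteomics experiment of the
# kind run on patient-derived brain organoids: ~16 nanoLC-MS/MS runs split
# across a healthy and one or more patient conditions, ~4,000 quantified
# proteins, sparse overdispersed spectral counts, a planted subset of
# differential proteins, and gene-set collections with planted
# signal-enriched sets.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults are the study conditions the package is exercised under: 4,000
#' proteins, 8 samples per group in 2 groups (16 runs), 10% planted
#' differential proteins with a 2 log2-unit shift, negative-binomial
#' dispersion 0.5, 85% per-cell detection, and 500 gene sets of 15-100
#' members of which 10% are planted around the differential proteins.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_samples_per_group samples in each condition.
#' @param n_groups number of conditions (>= 2; group 1 is the healthy
#'   reference, the others are patient conditions).
#' @param de_fraction fraction of proteins with a planted abundance shift.
#' @param effect_log2 planted shift, in log2 units of the group mean.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); small values approach Poisson counts.
#' @param detection_prob per-cell probability that a nonzero count is
#'   observed rather than zeroed (independent thinning).
#' @param n_sets number of simulated gene sets.
#' @param set_size_range integer pair, inclusive range of set sizes.
#' @param planted_set_fraction fraction of sets enriched in planted proteins.
#' @param seed integer root seed; identical seeds give bit-identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 4000, n_samples_per_group = 8,
                       n_groups = 2, de_fraction = 0.1, effect_log2 = 2,
                       dispersion = 0.5, detection_prob = 0.85,
                       n_sets = 500, set_size_range = c(15, 100),
                       planted_set_fraction = 0.1, seed = 1) {
  cfg <- list(
    n_proteins = as_count(n_proteins, "n_proteins"),
    n_samples_per_group = as_count(n_samples_per_group, "n_samples_per_group"),
    n_groups = as_count(n_groups, "n_groups", min = 2),
    de_fraction = as_fraction(de_fraction, "de_fraction"),
    effect_log2 = as_positive(effect_log2, "effect_log2"),
    dispersion = as_positive(dispersion, "dispersion"),
    detection_prob = as_fraction(detection_prob, "detection_prob", lo_open = TRUE),
    n_sets = as_count(n_sets, "n_sets"),
    set_size_range = c(as_count(set_size_range[1], "set_size_range[1]"),
                       as_count(set_size_range[2], "set_size_range[2]")),
    planted_set_fraction = as_fraction(planted_set_fraction,
                                       "planted_set_fraction"),
    seed = as_count(seed, "seed", min = 0)
  )
  if (cfg$set_size_range[1] > cfg$set_size_range[2]) {
    stop("field 'set_size_range' must be a non-decreasing pair", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a protein-by-sample spectral-count matrix with planted effects
#'
#' Counts are negative binomial around protein-specific baseline means drawn
#' log-normally, which reproduces the sparse, overdispersed mean-variance
#' behaviour of spectral counts. In every patient group, a planted fraction
#' of proteins has its mean shifted by `effect_log2` log2 units (up or down,
#' chosen at random per protein); zeros are injected by independent thinning
#' with probability `1 - detection_prob`.
#'
#' @param cfg a [sim_config()].
#' @return a list with `counts` (integer matrix, proteins x samples),
#'   `design` (data.frame sample_id/condition), and `truth` (list with
#'   `de_proteins`, `directions`, and an empty `planted_sets` slot filled by
#'   [simulate_genesets()]).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_proteins
  nspg <- cfg$n_samples_per_group
  ns <- nspg * cfg$n_groups
  conditions <- c("healthy", if (cfg$n_groups > 1)
    paste0("patient", seq_len(cfg$n_groups - 1L)))
  design <- data.frame(
    sample_id = sprintf("S%02d", seq_len(ns)),
    condition = rep(conditions, each = nspg),
    stringsAsFactors = FALSE
  )
  protein_ids <- sprintf("P%04d", seq_len(n))

  with_seed(substream_seed(cfg$seed, "counts"), {
    base_mean <- stats::rlnorm(n, meanlog = log(8), sdlog = 1.2)
    n_de <- round(cfg$de_fraction * n)
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
    dir_up <- if (n_de > 0) sample(c(TRUE, FALSE), n_de, replace = TRUE) else logical(0)
    shift <- rep(1, n)
    shift[de_idx] <- 2^(ifelse(dir_up, cfg$effect_log2, -cfg$effect_log2))

    mu <- matrix(base_mean, nrow = n, ncol = ns)
    patient_cols <- design$condition != "healthy"
    mu[, patient_cols] <- mu[, patient_cols] * shift

    size <- 1 / cfg$dispersion
    counts <- matrix(stats::rnbinom(n * ns, mu = as.vector(mu), size = size),
                     nrow = n, ncol = ns)
    if (cfg$detection_prob < 1) {
      drop <- matrix(stats::runif(n * ns) > cfg$detection_prob, nrow = n)
      counts[drop] <- 0L
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(protein_ids, design$sample_id)

    truth <- list(
      de_proteins = protein_ids[de_idx],
      directions = stats::setNames(ifelse(dir_up, "up", "down"),
                                   protein_ids[de_idx]),
      planted_sets = character(0)
    )
    list(counts = counts, design = design, truth = truth)
  })
}

#' Partition protein counts into synthetic peptide evidence
#'
#' Each protein is assigned a number of peptides drawn uniformly from
#' `peptides_per_protein_range`; its per-sample spectral count is split
#' across those peptides multinomially with protein-specific peptide
#' propensities. Summing peptide counts per protein recovers the input
#' matrix exactly, so protein inference can be tested as a round trip.
#'
#' @param counts protein x sample integer matrix.
#' @param peptides_per_protein_range integer pair, lower bound >= 1.
#' @param seed integer seed.
#' @return a long data.frame with columns protein_id, peptide_id,
#'   sample_id, spectral_count (zero rows included, so the peptide table
#'   carries the full matrix support).
#' @export
simulate_peptides <- function(counts, peptides_per_protein_range = c(1, 5),
                              seed = 1) {
  r <- c(as_count(peptides_per_protein_range[1], "peptides_per_protein_range[1]"),
         as_count(peptides_per_protein_range[2], "peptides_per_protein_range[2]"))
  if (r[1] > r[2]) stop("peptides_per_protein_range must be non-decreasing",
                        call. = FALSE)
  if (nrow(counts) == 0) {
    return(data.frame(protein_id = character(0), peptide_id = character(0),
                      sample_id = character(0), spectral_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  protein_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  with_seed(substream_seed(seed, "peptides"), {
    sizes_avail <- seq(r[1], r[2])
    n_pep <- sizes_avail[sample.int(length(sizes_avail), nrow(counts),
                                    replace = TRUE)]
    out <- vector("list", nrow(counts))
    for (i in seq_len(nrow(counts))) {
      k <- n_pep[i]
      w <- stats::runif(k, 0.2, 1)
      pep_counts <- vapply(counts[i, ], function(ct) {
        if (ct == 0) integer(k) else as.integer(stats::rmultinom(1, ct, w))
      }, integer(k))
      if (k == 1) pep_counts <- matrix(pep_counts, nrow = 1)
      out[[i]] <- data.frame(
        protein_id = protein_ids[i],
        peptide_id = rep(sprintf("%s_pep%d", protein_ids[i], seq_len(k)),
                         times = length(sample_ids)),
        sample_id = rep(sample_ids, each = k),
        spectral_count = as.integer(pep_counts),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate gene-set collections with planted signal-enriched sets
#'
#' Non-planted sets draw members uniformly from the protein universe;
#' planted sets draw each member from the differential proteins with
#' probability `de_member_prob`, so they are genuinely enriched in planted
#' signal and downstream enrichment can be scored against known truth.
#'
#' @param protein_ids character vector, the simulated protein universe.
#' @param cfg a [sim_config()] (uses n_sets, set_size_range,
#'   planted_set_fraction, seed).
#' @param truth the truth list from [simulate_counts()].
#' @param de_member_prob probability a planted-set member is drawn from the
#'   differential proteins.
#' @param prefix stem for the generated set names (default "SET"; use a
#'   different stem per collection so names never collide).
#' @return a list with `collection` (named list of member vectors, with a
#'   `source` attribute) and `truth` (input truth with `planted_sets`
#'   filled in).
#' @export
simulate_genesets <- function(protein_ids, cfg, truth,
                              de_member_prob = 0.7, prefix = "SET") {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(protein_ids) == 0) stop("protein_ids must be non-empty",
                                     call. = FALSE)
  if (cfg$set_size_range[2] > length(protein_ids)) {
    stop("set_size_range upper bound exceeds the number of proteins",
         call. = FALSE)
  }
  de <- intersect(truth$de_proteins, protein_ids)
  nonde <- setdiff(protein_ids, de)
  n_planted <- round(cfg$planted_set_fraction * cfg$n_sets)
  if (length(de) == 0) n_planted <- 0L

  with_seed(substream_seed(cfg$seed, "genesets"), {
    sizes_avail <- seq(cfg$set_size_range[1], cfg$set_size_range[2])
    sizes <- sizes_avail[sample.int(length(sizes_avail), cfg$n_sets,
                                    replace = TRUE)]
    names <- sprintf("%s%04d", prefix, seq_len(cfg$n_sets))
    planted <- if (n_planted > 0) sort(sample(names, n_planted)) else character(0)
    sets <- vector("list", cfg$n_sets)
    names(sets) <- names
    for (i in seq_len(cfg$n_sets)) {
      k <- sizes[i]
      if (names[i] %in% planted) {
        k_de <- min(stats::rbinom(1, k, de_member_prob), length(de))
        k_bg <- min(k - k_de, length(nonde))
        sets[[i]] <- c(sample(de, k_de), sample(nonde, k_bg))
      } else {
        sets[[i]] <- sample(protein_ids, k)
      }
    }
    attr(sets, "source") <- "simulated"
    truth$planted_sets <- planted
    list(collection = sets, truth = truth)
  })
}
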