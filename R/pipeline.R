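# End-to-end orchestration: ingest -> normalize -> differential abundance
# (per contrast) -> absolute GSEA -> prioritization -> report data.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to on-disk tables) or `sim` (a
#' [sim_config()]) must be given. With `input`, supply either a peptide
#' table (`peptides`) or a protein count matrix (`counts`), plus a design
#' TSV and GMT paths for gene-set collections and disease libraries. With
#' `sim`, all inputs are generated with planted truth.
#'
#' @param input NULL or list(peptides=, counts=, design=, genesets=,
#'   disease=) of file paths (genesets/disease are character vectors of
#'   GMT paths, named by collection tag).
#' @param sim NULL or a [sim_config()].
#' @param min_peptides two-peptide protein-inference threshold.
#' @param min_detected_samples detection filter threshold.
#' @param p_cut,fdr_cut differential-abundance selection thresholds.
#' @param percentile frequency percentile cutoff.
#' @param fc_cut,spectra_cut filter-cascade thresholds.
#' @param weight_p GSEA hit-weight exponent.
#' @param rots a [rots_params()] (its seed is overridden by `seed`).
#' @param gsea_P permutations per gene set.
#' @param seed root seed; every stage derives a named substream from it.
#' @param outdir output directory (created if missing); NULL to skip
#'   writing files.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, min_peptides = 2,
                            min_detected_samples = 4, p_cut = 0.05,
                            fdr_cut = 0.25, percentile = 90, fc_cut = 3,
                            spectra_cut = 10, weight_p = 1,
                            rots = rots_params(), gsea_P = 1000,
                            seed = 1, outdir = NULL) {
  if (is.null(input) == is.null(sim)) {
    stop("exactly one of 'input' and 'sim' must be given", call. = FALSE)
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    stop("field 'sim' must be a sim_config object", call. = FALSE)
  }
  if (!is.null(input) && is.null(input$peptides) && is.null(input$counts)) {
    stop("field 'input' needs either a 'peptides' or a 'counts' path",
         call. = FALSE)
  }
  cfg <- list(
    input = input, sim = sim,
    min_peptides = as_count(min_peptides, "min_peptides"),
    min_detected_samples = as_count(min_detected_samples,
                                    "min_detected_samples"),
    p_cut = as_fraction(p_cut, "p_cut", lo_open = TRUE),
    fdr_cut = as_fraction(fdr_cut, "fdr_cut"),
    percentile = as_fraction(percentile, "percentile", lo = 0, hi = 100,
                             lo_open = TRUE),
    fc_cut = as_positive(fc_cut, "fc_cut"),
    spectra_cut = as_count(spectra_cut, "spectra_cut", min = 0),
    weight_p = as_fraction(weight_p, "weight_p", hi = 2),
    rots = rots, gsea_P = as_count(gsea_P, "gsea_P"),
    seed = as_count(seed, "seed", min = 0), outdir = outdir
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full prioritization pipeline
#'
#' Stages run in order ingest -> normalize -> differential abundance (one
#' run per contrast of a patient condition against the healthy reference)
#' -> absolute GSEA -> frequency/percentile/fold-change/spectral-count
#' prioritization -> disease over-representation -> report data. Any stage
#' failure aborts with an error naming the stage. When `outdir` is set,
#' every table is written as TSV (atomically: to a temporary name, then
#' renamed) together with a JSON run manifest; on the simulation route the
#' planted truth is written as a JSON sidecar.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all stage objects and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage_counts <- list()
  log_stage <- function(stage, n_in, n_out) {
    stage_counts[[stage]] <<- c(rows_in = n_in, rows_out = n_out)
    message(sprintf("[%s] in=%d out=%d (%.1fs elapsed)", stage, n_in, n_out,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- ingest ----------------------------------------------------------
  truth <- NULL
  ing <- run_stage("ingest", {
    if (!is.null(config$sim)) {
      sim <- simulate_counts(config$sim)
      peptides <- simulate_peptides(sim$counts, c(1, 5),
                                    seed = substream_seed(config$seed,
                                                          "sim_peptides"))
      truth <- sim$truth
      list(peptides = peptides, design = sim$design,
           n_source = nrow(sim$counts))
    } else {
      design <- read_design(config$input$design)
      if (!is.null(config$input$peptides)) {
        peptides <- read_peptide_table(config$input$peptides)
        list(peptides = peptides, design = design,
             n_source = length(unique(peptides$protein_id)))
      } else {
        counts <- read_count_matrix(config$input$counts)
        list(counts = counts, design = design, n_source = nrow(counts))
      }
    }
  })

  counts <- run_stage("protein_inference", {
    if (!is.null(ing$peptides)) {
      aggregate_proteins(ing$peptides, min_peptides = config$min_peptides)
    } else ing$counts
  })
  log_stage("protein_inference", ing$n_source, nrow(counts))

  counts <- run_stage("variation_filter", {
    variation_filter(counts, config$min_detected_samples)
  })
  log_stage("variation_filter", stage_counts$protein_inference[["rows_out"]],
            nrow(counts))

  design <- check_design(ing$design, colnames(counts))

  # ---- normalize -------------------------------------------------------
  normalized <- run_stage("normalize", glog_normalize(counts))
  log_stage("normalize", nrow(counts), nrow(normalized$values))

  # ---- gene sets -------------------------------------------------------
  collections <- run_stage("gene_sets", {
    if (!is.null(config$sim)) {
      gs <- simulate_genesets(rownames(counts), config$sim, truth)
      truth <- gs$truth
      list(simulated = gs$collection)
    } else {
      paths <- config$input$genesets
      out <- lapply(seq_along(paths), function(i) {
        read_gmt(paths[i], source = names(paths)[i])
      })
      names(out) <- if (!is.null(names(paths))) names(paths) else
        basename(paths)
      out
    }
  })

  disease_libs <- run_stage("disease_libraries", {
    if (!is.null(config$sim)) {
      dcfg <- config$sim
      dcfg$n_sets <- 50L
      dcfg$set_size_range <- c(10L, pmin(40L, length(rownames(counts))))
      dcfg$seed <- substream_seed(config$seed, "disease_sim")
      dis <- simulate_genesets(rownames(counts), dcfg, truth,
                               prefix = "DIS")
      truth$planted_disease_terms <- dis$truth$planted_sets
      list(simulated_disease = dis$collection)
    } else if (!is.null(config$input$disease)) {
      paths <- config$input$disease
      out <- lapply(seq_along(paths), function(i) read_gmt(paths[i]))
      names(out) <- if (!is.null(names(paths))) names(paths) else
        basename(paths)
      out
    } else list()
  })

  # ---- differential abundance, per contrast ----------------------------
  conditions <- unique(design$condition)
  reference <- conditions[1]
  contrasts <- lapply(conditions[-1], function(tc) c(reference, tc))
  names(contrasts) <- vapply(contrasts, function(ct)
    paste0(ct[1], "_vs_", ct[2]), character(1))

  rots_par <- config$rots
  de <- run_stage("differential", {
    lapply(names(contrasts), function(nm) {
      par_i <- rots_par
      par_i$seed <- substream_seed(config$seed, paste0("rots_", nm))
      rots_de(normalized, counts, design, contrasts[[nm]], params = par_i,
              p_cut = config$p_cut, fdr_cut = config$fdr_cut)
    })
  })
  names(de) <- names(contrasts)
  log_stage("differential", nrow(counts),
            sum(vapply(de, function(r) sum(r$selected), integer(1))))

  # ---- absolute GSEA ---------------------------------------------------
  gsea <- run_stage("gsea", {
    out <- list()
    for (nm in names(de)) {
      ranked <- build_ranked_list(de[[nm]])
      for (coll in names(collections)) {
        out[[paste(nm, coll, sep = ".")]] <- run_gsea_collection(
          ranked, collections[[coll]], P = config$gsea_P,
          weight_p = config$weight_p,
          seed = substream_seed(config$seed, paste0("gsea_", nm, "_", coll)))
      }
    }
    out
  })
  n_sig_pathways <- sum(vapply(gsea, function(g) sum(g$significant),
                               integer(1)))
  log_stage("gsea", sum(vapply(gsea, nrow, integer(1))), n_sig_pathways)

  # ---- prioritize ------------------------------------------------------
  freq <- run_stage("frequency", frequency_table(gsea))
  log_stage("frequency", n_sig_pathways, nrow(freq))

  candidates <- run_stage("filter_cascade", {
    if (nrow(freq) == 0) {
      empty <- data.frame(protein_id = character(0), frequency = integer(0),
                          fold_change = numeric(0), total_spectra = numeric(0),
                          direction = character(0),
                          passed_percentile = logical(0),
                          passed_fc = logical(0), passed_spectra = logical(0),
                          candidate = logical(0), stringsAsFactors = FALSE)
      class(empty) <- c("candidate_list", class(empty))
      empty
    } else {
      # across contrasts, score each protein by its largest-magnitude
      # signed fold change; total spectra are pooled over all samples
      fc_mat <- vapply(de, function(r) r$fold_change, numeric(nrow(counts)))
      fc_mat <- matrix(fc_mat, nrow = nrow(counts))
      pick <- apply(abs(fc_mat), 1, which.max)
      fc <- stats::setNames(fc_mat[cbind(seq_len(nrow(counts)), pick)],
                            rownames(counts))
      spectra <- stats::setNames(rowSums(counts), rownames(counts))
      filter_cascade(freq, fc, spectra, percentile = config$percentile,
                     fc_cut = config$fc_cut,
                     spectra_cut = config$spectra_cut)
    }
  })
  final <- candidates$protein_id[candidates$candidate]
  log_stage("filter_cascade", nrow(freq), length(final))

  disease <- run_stage("disease", {
    if (length(final) == 0 || length(disease_libs) == 0) NULL else
      disease_frequency(final, disease_libs, rownames(counts))
  })

  # ---- report data -----------------------------------------------------
  report <- run_stage("report", {
    list(pca = pca_scores(normalized),
         sample_clustering = ward_clustering(normalized, "columns"),
         reproducibility = lapply(de, function(r)
           reproducibility_plot_data(attr(r, "fit"))),
         volcano = lapply(de, volcano_data))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("spectralcounts")),
    seed = config$seed,
    thresholds = config[c("min_peptides", "min_detected_samples", "p_cut",
                          "fdr_cut", "percentile", "fc_cut", "spectra_cut",
                          "weight_p", "gsea_P")],
    rots = lapply(de, function(r) {
      fit <- attr(r, "fit")
      list(alpha1 = fit$alpha1, alpha2 = fit$alpha2, k = fit$k, Z = fit$Z)
    }),
    stage_counts = stage_counts,
    n_candidates = length(final),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(counts = counts, design = design, normalized = normalized,
                 collections = collections, disease_libs = disease_libs,
                 de = de, gsea = gsea, frequency = freq,
                 candidates = candidates, final_candidates = final,
                 disease = disease, report = report, truth = truth,
                 manifest = manifest)

  if (!is.null(config$outdir)) {
    run_stage("write_outputs", write_pipeline_outputs(result, config$outdir))
  }
  invisible(result)
}

# Atomic write helper: write to a temporary sibling, then rename.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  wt <- function(df, path) {
    write_atomic(path, function(tmp) {
      utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  write_atomic(p("counts.tsv"),
               function(tmp) write_count_matrix(result$counts, tmp))
  write_atomic(p("design.tsv"),
               function(tmp) write_design(result$design, tmp))
  write_atomic(p("normalized.tsv"), function(tmp)
    write_count_matrix(round(result$normalized$values, 6), tmp))
  write_atomic(p("normalization_params.json"), function(tmp)
    write_json_file(list(params = result$normalized$params,
                         phi = result$normalized$phi), tmp))
  for (nm in names(result$de)) {
    df <- result$de[[nm]]
    wt(df[, setdiff(names(df), "component")], p(sprintf("de_%s.tsv", nm)))
    wt(volcano_data(df), p(sprintf("volcano_%s.tsv", nm)))
  }
  for (nm in names(result$gsea)) {
    g <- result$gsea[[nm]]
    flat <- g[, setdiff(names(g), "component")]
    flat$component <- vapply(g$component, paste, character(1), collapse = ",")
    wt(flat, p(sprintf("gsea_%s.tsv", nm)))
  }
  wt(result$frequency, p("frequency.tsv"))
  wt(result$candidates, p("candidates.tsv"))
  if (!is.null(result$disease)) {
    prot <- result$disease$proteins
    flat <- prot[, c("protein_id", "n_terms")]
    flat$terms <- vapply(prot$terms, paste, character(1), collapse = ",")
    wt(flat, p("disease_frequency.tsv"))
    for (nm in names(result$disease$tests)) {
      wt(result$disease$tests[[nm]], p(sprintf("overrep_%s.tsv", nm)))
    }
  }
  if (!is.null(result$truth)) {
    write_atomic(p("truth.json"),
                 function(tmp) write_json_file(result$truth, tmp))
  }
  write_atomic(p("manifest.json"),
               function(tmp) write_json_file(result$manifest, tmp))
  invisible(outdir)
}
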