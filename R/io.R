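# Plain-text readers/writers: TSV count matrices, peptide tables, study
# designs, GMT gene-set collections, JSON manifests.

#' Write / read a protein-by-sample count matrix as TSV
#'
#' The first column holds protein ids, remaining columns one sample each,
#' with a header row.
#'
#' @param m numeric matrix with row and column names.
#' @param path output file.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @return `read_count_matrix()` returns the matrix.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df)) {
    stop(sprintf("%s: expected a 'protein_id' column", path), call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  rownames(m) <- df$protein_id
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("%s: duplicate protein ids", path), call. = FALSE)
  }
  m
}

#' Read a peptide-evidence table from TSV
#'
#' Expects columns protein_id, peptide_id, sample_id, spectral_count.
#' Malformed rows (missing fields, negative or non-numeric counts) raise an
#' error naming the first offending line.
#'
#' @param path TSV file.
#' @return a data.frame of peptide evidence.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide_id", "sample_id", "spectral_count")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  counts <- suppressWarnings(as.numeric(df$spectral_count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts) |
                 !nzchar(df$protein_id) | !nzchar(df$peptide_id) |
                 !nzchar(df$sample_id))
  if (length(bad)) {
    stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L),
         call. = FALSE)
  }
  df$spectral_count <- as.integer(counts)
  df
}

#' Write / read a two-column study design (sample_id, condition)
#' @param design data.frame with sample_id and condition columns.
#' @param path TSV file.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample_id", "condition")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  check_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' Collections are represented as named lists of character vectors; the
#' optional `source` attribute carries a collection tag (e.g. "c5_bp").
#'
#' @param sets named list of character member vectors.
#' @param path GMT file.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param source optional collection tag attached to the result.
#' @return `read_gmt()` returns a named list of member vectors.
#' @export
read_gmt <- function(path, source = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, short[1]),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop(sprintf("%s: duplicate set names", path), call. = FALSE)
  }
  if (!is.null(source)) attr(sets, "source") <- source
  sets
}

# JSON helpers for manifests / truth sidecars.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
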