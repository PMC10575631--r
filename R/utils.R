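# Internal helpers: seed substreams, validation, matrix coercion.

#' Derive a reproducible substream seed from a root seed and a stage name
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams, so individual stages can be re-run independently yet
#' reproducibly. The derivation is a small deterministic string hash folded
#' into the root seed, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed integer root seed.
#' @param stream character stage name, e.g. "counts" or "gsea".
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L, nzchar(stream))
  seed <- as_count(seed, "seed", min = 0)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483629
  as.integer((seed + h) %% 2147483629)
}

# Run code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validation helpers -- errors name the offending field.
as_count <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("field '%s' must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

as_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  bad <- length(x) != 1L || !is.numeric(x) || is.na(x) ||
    x < lo || x > hi || (lo_open && x <= lo)
  if (bad) {
    stop(sprintf("field '%s' must be a single number in %s%s, %s]",
                 name, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
  as.numeric(x)
}

as_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stop(sprintf("field '%s' must be a single positive number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

# Accept either a plain matrix or a normalized_matrix and return the values.
as_values <- function(x) {
  if (inherits(x, "normalized_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a matrix or a 'normalized_matrix' object", call. = FALSE)
}

# Two-column study design validation; returns a data.frame with
# sample_id and condition columns.
check_design <- function(design, sample_ids = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "condition") %in% names(design))) {
    stop("design must be a data.frame with columns sample_id, condition",
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("design has duplicated sample_id entries", call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    if (length(missing)) {
      stop(sprintf("samples missing from design: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  design
}

# Sample ids of the two sides of a contrast, in matrix column order.
contrast_samples <- function(design, contrast, sample_ids) {
  ref <- design$sample_id[design$condition == contrast[1]]
  tst <- design$sample_id[design$condition == contrast[2]]
  list(reference = intersect(sample_ids, ref),
       test = intersect(sample_ids, tst))
}
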