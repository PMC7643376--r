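#' @keywords internal
"_PACKAGE"

# Run code with a private RNG stream; the caller's global RNG state is
# untouched. All stochastic functions in the package funnel through this so
# a `seed` argument fully determines their output.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconcile sample identifiers with patient identifiers
#'
#' TCGA-style sample barcodes (e.g. `TCGA-05-4244-01A`) extend the patient
#' barcode; matching is done on a configurable prefix. When identifiers do
#' not look TCGA-like the match is exact.
#'
#' @param sample_ids character vector of sample-level identifiers.
#' @param patient_ids character vector of patient-level identifiers.
#' @param prefix integer prefix length used for matching, or `NULL` to
#'   auto-detect (12 characters when all identifiers start with `"TCGA"`,
#'   exact match otherwise).
#' @return integer vector of length `length(sample_ids)`: the index into
#'   `patient_ids` each sample maps to, `NA` when unmatched.
#' @export
match_patient_ids <- function(sample_ids, patient_ids, prefix = NULL) {
  if (is.null(prefix)) {
    tcga_like <- all(startsWith(sample_ids, "TCGA")) &&
      all(startsWith(patient_ids, "TCGA"))
    prefix <- if (tcga_like) 12L else NA_integer_
  }
  if (is.na(prefix)) {
    match(sample_ids, patient_ids)
  } else {
    match(substr(sample_ids, 1L, prefix), substr(patient_ids, 1L, prefix))
  }
}

parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("pairsig_parse_error", "error")))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
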