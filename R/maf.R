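.maf_required <- c("Hugo_Symbol", "Variant_Classification",
                   "Tumor_Sample_Barcode", "Chromosome", "Start_Position")

#' Read somatic mutation records from a MAF file
#'
#' Tab-delimited Mutation Annotation Format; leading comment lines starting
#' with `#` (e.g. `#version 2.4`) are skipped. Only the columns needed for
#' mutation counting are retained; sample barcodes are kept verbatim.
#'
#' @param path MAF file path.
#' @return a data frame of class `mutation_records` with one row per called
#'   mutation and columns `sample_id`, `gene_symbol`,
#'   `variant_classification`, `chrom`, `pos`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(.maf_required, names(df))
  if (length(missing_cols)) {
    stopf("MAF '%s' is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene_symbol = as.character(df$Hugo_Symbol),
    variant_classification = as.character(df$Variant_Classification),
    chrom = as.character(df$Chromosome),
    pos = as.integer(df$Start_Position),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$sample_id))) stopf("MAF '%s' has empty sample barcodes", path)
  if (any(is.na(out$pos) | out$pos <= 0)) {
    stopf("MAF '%s' has non-positive or missing Start_Position", path)
  }
  class(out) <- c("mutation_records", "data.frame")
  out
}
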