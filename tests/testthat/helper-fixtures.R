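# Small in-code fixtures shared across test files.

make_expr <- function(values, group = "tumor") {
  expression_matrix(values, group)
}

# gene-by-sample matrix with named dims from a vector (byrow)
mat <- function(x, genes, samples) {
  matrix(x, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

make_clin <- function(...) {
  clinical_table(data.frame(..., stringsAsFactors = FALSE))
}

# random positive expression matrix without ties (a.s.)
random_expr <- function(n_genes, n_samples, seed, group = "tumor") {
  set.seed(seed)
  v <- matrix(exp(rnorm(n_genes * n_samples, 2, 1)), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(v, group)
}

# write a small delimited file, returning its path
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_maf_lines <- c(
  "#version 2.4",
  paste("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode",
        "Chromosome", "Start_Position", sep = "\t"),
  paste("TP53", "Missense_Mutation", "S1", "17", "7578406", sep = "\t"),
  paste("KRAS", "Missense_Mutation", "S1", "12", "25398284", sep = "\t"),
  paste("EGFR", "Silent", "S1", "7", "55249071", sep = "\t"),
  paste("TP53", "Nonsense_Mutation", "S2", "17", "7577538", sep = "\t")
)
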