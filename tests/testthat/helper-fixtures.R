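# small in-code fixtures shared across test files

toy_matrix <- function(values, genes, samples, group, cls = "mRNA") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, group, cls)
}

write_expr_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_design <- function(samples, n_control = length(samples) %/% 2) {
  stats::setNames(rep(c("control", "case"),
                      c(n_control, length(samples) - n_control)), samples)
}

# deterministic small pipeline run used by orchestration tests
tiny_pipeline_config <- function(outdir, seed = 3, ...) {
  pipeline_config(outdir = outdir, seed = seed,
                  synthetic = list(n_mrna = 120, n_lncrna = 60, n_mirna = 80,
                                   n_de_mrna = 24, n_de_lncrna = 12, n_de_mirna = 24,
                                   n_planted_triads = 5),
                  ...)
}
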