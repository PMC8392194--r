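# Small in-code fixtures: a hand-sized CNA TSV, MAF and metadata file.

write_tiny_cna <- function(path,
                           symbols = c("GA", "GB", "GC"),
                           cytobands = c("1p11.1", "1p11.2", "1q21"),
                           states = matrix(c(0L, 1L, -2L, 1L, 0L, 2L), 3, 2),
                           samples = c("S1", "S2")) {
  df <- data.frame(symbols, seq_along(symbols), cytobands, states,
                   check.names = FALSE)
  names(df) <- c("Gene Symbol", "Locus ID", "Cytoband", samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_tiny_maf <- function(path, rows) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a deterministic toy arm-count vector shared by feature tests
toy_counts <- c(`1p` = 10, `1q` = 1, `2p` = 1, `2q` = 0)
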