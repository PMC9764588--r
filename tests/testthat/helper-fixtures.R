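# write a flow matrix + metadata pair to temporary CSV files
write_flow_csvs <- function(w, roles, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  labels <- rownames(w)
  matrix_path <- file.path(dir, "matrix.csv")
  df <- data.frame(node = labels, w, check.names = FALSE)
  colnames(df) <- c("node", labels)
  utils::write.csv(df, matrix_path, row.names = FALSE, quote = TRUE)
  metadata_path <- file.path(dir, "metadata.csv")
  utils::write.csv(
    data.frame(id = seq_along(labels), label = labels,
      role = unname(roles[labels])),
    metadata_path, row.names = FALSE, quote = TRUE
  )
  list(matrix = matrix_path, metadata = metadata_path)
}

# small labelled matrix builder
named_matrix <- function(values, labels) {
  m <- matrix(values, length(labels), length(labels), byrow = TRUE,
    dimnames = list(labels, labels))
  m
}
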