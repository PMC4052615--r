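# Small in-code fixtures shared across test files.

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# edge matrix (2 columns of symbols) -> graph, via the package reader
edges_to_graph <- function(edges) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("gene_a\tgene_b", paste(edges[, 1], edges[, 2], sep = "\t")), path)
  read_edge_list(path)
}

# 6-sample toy: 3 ER+ and 3 ER- samples, 2 pairs with printed values
toy_dataset <- function() {
  samples <- sprintf("s%d", 1:6)
  mirna <- matrix(c(1, 2, 3, 3, 2, 1,
                    2, 4, 8, 1, 1, 3), nrow = 2, byrow = TRUE,
                  dimnames = list(c("hsa-miR-1", "hsa-miR-375"), samples))
  mrna <- matrix(c(2, 4, 6, 1, 5, 9,
                   1, 3, 2, 6, 4, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("CA3", "FOLR1"), samples))
  annotation <- tibble::tibble(sample_id = samples, feature = "ER",
                               status = rep(c("ER+", "ER-"), each = 3))
  pairs <- tibble::tibble(mirna_id = c("hsa-miR-1", "hsa-miR-375"),
                          mrna_id = c("CA3", "FOLR1"),
                          healthy_sign = c("D", "D"))
  list(mirna = mirna, mrna = mrna, annotation = annotation, pairs = pairs)
}
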