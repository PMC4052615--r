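#' Read an expression matrix from TSV
#'
#' Expression tables are genes/miRNAs in rows, samples in columns, on a log
#' scale. The first header cell is `id`, the remaining header cells are
#' sample ids; empty cells or `"."` are missing values. Duplicate row ids
#' (multiple probes per gene) are either an error (`collapse = "none"`) or
#' collapsed row-wise by the stated rule.
#'
#' @param path Path to a tab-separated file.
#' @param collapse How to handle duplicate row ids: `"none"` (error),
#'   `"mean"` (element-wise mean across duplicate rows), or
#'   `"max_variance"` (keep the duplicate row with the largest variance;
#'   the default choice preserves correlation signal).
#' @param normalize_ids If `TRUE`, row ids are passed through
#'   [normalize_mirna_ids()] after trimming.
#'
#' @return A named numeric matrix (rows = entities, columns = samples).
#' @seealso [write_expression_matrix()], [collapse_probes()]
#' @export
read_expression_matrix <- function(path, collapse = c("none", "mean", "max_variance"),
                                   normalize_ids = FALSE) {
  collapse <- match.arg(collapse)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (ncol(raw) < 2L) {
    abort("Expression TSV needs an id column and at least one sample column.",
          class = "mmpv_error_parse")
  }
  ids <- stringr::str_trim(raw[[1L]])
  if (normalize_ids) ids <- normalize_mirna_ids(ids)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  body[body == "" | body == "."] <- NA_character_
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(values) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("Non-numeric expression value '%s' at row %d (id '%s'), column '%s'.",
                  body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
                  colnames(body)[bad[1L, 2L]]),
          class = "mmpv_error_parse")
  }
  dimnames(values) <- list(ids, colnames(raw)[-1L])
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample ids in expression header.", class = "mmpv_error_duplicate")
  }
  collapse_probes(values, collapse)
}

#' Collapse duplicate probe rows of an expression matrix
#'
#' @param mat Named numeric matrix.
#' @inheritParams read_expression_matrix
#' @return A matrix with unique row ids. Idempotent on already-unique input.
#' @export
collapse_probes <- function(mat, collapse = c("none", "mean", "max_variance")) {
  collapse <- match.arg(collapse)
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  if (collapse == "none") {
    abort(sprintf("Duplicate row ids (e.g. '%s') with collapse = \"none\".",
                  ids[duplicated(ids)][1L]),
          class = "mmpv_error_duplicate")
  }
  groups <- split(seq_along(ids), factor(ids, levels = unique(ids)))
  rows <- purrr::map(groups, function(idx) {
    block <- mat[idx, , drop = FALSE]
    if (length(idx) == 1L) return(block[1L, ])
    if (collapse == "mean") {
      colMeans(block, na.rm = TRUE)
    } else {
      vars <- apply(block, 1L, stats::var, na.rm = TRUE)
      vars[is.na(vars)] <- -Inf
      block[which.max(vars), ]
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(groups)
  # colMeans over all-NA cells yields NaN; keep missing as NA
  out[is.nan(out)] <- NA_real_
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first header cell `id`, missing
#' values written as empty cells. Reading the file back with
#' `collapse = "none"` reproduces ids and values exactly.
#'
#' @param mat Named numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "id")
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Normalize miRNA identifiers
#'
#' Trims whitespace and unifies the species/case variants of the
#' `hsa-miR-...` prefix (`hsa-mir`, `HSA-MIR`, and the common `has-mir`
#' typo) so that pair lists and expression rows match exactly.
#'
#' @param ids Character vector.
#' @return Character vector of the same length.
#' @examples
#' normalize_mirna_ids(c(" has-mir-375", "hsa-mir-1", "hsa-miR-155"))
#' @export
normalize_mirna_ids <- function(ids) {
  ids <- stringr::str_trim(ids)
  stringr::str_replace(ids, stringr::regex("^(hsa|has)-mir-", ignore_case = TRUE),
                       "hsa-miR-")
}

#' Read sample annotations from TSV
#'
#' Expects columns `sample_id`, `feature`, `status`. Every status string is
#' validated against the feature registry; samples missing a feature are
#' simply absent for that feature.
#'
#' @param path Path to a tab-separated file.
#' @param registry Feature registry tibble, see [feature_registry()].
#' @return A tibble with columns `sample_id`, `feature`, `status`.
#' @export
read_sample_annotations <- function(path, registry = default_feature_registry()) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "feature", "status")
  if (!all(need %in% names(ann))) {
    abort("Annotation TSV must have columns sample_id, feature, status.",
          class = "mmpv_error_parse")
  }
  ann <- dplyr::select(ann, dplyr::all_of(need)) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), stringr::str_trim))
  validate_annotation(ann, registry)
  ann
}

validate_annotation <- function(annotation, registry) {
  checked <- dplyr::left_join(annotation, registry, by = "feature")
  bad <- checked[is.na(checked$status1) |
                   (checked$status != checked$status1 & checked$status != checked$status2), ]
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Annotation row (sample '%s', feature '%s', status '%s') does not match the registry.",
      bad$sample_id[1L], bad$feature[1L], bad$status[1L]),
      class = "mmpv_error_validation")
  }
  dup <- dplyr::count(annotation, .data$sample_id, .data$feature) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("Sample '%s' has more than one status for feature '%s'.",
                  dup$sample_id[1L], dup$feature[1L]),
          class = "mmpv_error_validation")
  }
  invisible(annotation)
}

#' Read a validated targeting-pair list from TSV
#'
#' Expects columns `mirna_id`, `mrna_id`, `healthy_sign`, where the healthy
#' sign is `U` (positive regulation in the healthy population) or `D`
#' (negative regulation). Pairs are kept in file order.
#'
#' @param path Path to a tab-separated file.
#' @param normalize If `TRUE` (default), [normalize_mirna_ids()] is applied
#'   to the miRNA column so ids match expression rows.
#' @return A tibble with columns `mirna_id`, `mrna_id`, `healthy_sign`.
#' @export
read_pair_list <- function(path, normalize = TRUE) {
  pairs <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  need <- c("mirna_id", "mrna_id", "healthy_sign")
  if (!all(need %in% names(pairs))) {
    abort("Pair TSV must have columns mirna_id, mrna_id, healthy_sign.",
          class = "mmpv_error_parse")
  }
  pairs <- dplyr::select(pairs, dplyr::all_of(need)) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), stringr::str_trim))
  if (normalize) pairs$mirna_id <- normalize_mirna_ids(pairs$mirna_id)
  validate_pair_list(pairs)
  pairs
}

validate_pair_list <- function(pairs) {
  bad <- which(!pairs$healthy_sign %in% c("U", "D"))
  if (length(bad) > 0L) {
    abort(sprintf("healthy_sign must be 'U' or 'D'; got '%s' for pair (%s, %s).",
                  pairs$healthy_sign[bad[1L]], pairs$mirna_id[bad[1L]],
                  pairs$mrna_id[bad[1L]]),
          class = "mmpv_error_validation")
  }
  key <- paste(pairs$mirna_id, pairs$mrna_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    abort(sprintf("Duplicated targeting pair (%s, %s).",
                  pairs$mirna_id[d], pairs$mrna_id[d]),
          class = "mmpv_error_duplicate")
  }
  invisible(pairs)
}

#' Read a protein-protein interaction edge list from TSV
#'
#' Expects two gene-symbol columns (`gene_a`, `gene_b`). The graph is
#' undirected, repeated edges are deduplicated, and self-loops are kept
#' (a self-loop contributes 1 to a node's degree, see [ppi_degrees()]).
#'
#' @param path Path to a tab-separated file.
#' @return An undirected [igraph][igraph::graph_from_data_frame] graph.
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) <= 1L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- stringr::str_split(lines[-1L], "\t")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    abort(sprintf("Edge list line %d has %d fields; expected 2.",
                  which(nf != 2L)[1L] + 1L, nf[nf != 2L][1L]),
          class = "mmpv_error_parse")
  }
  edges <- do.call(rbind, fields)
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
}

#' Read a term-to-gene annotation map from TSV
#'
#' Expects columns `term_id`, `term_name`, `gene` (one gene per line).
#' Genes are aggregated into sets per term; duplicate lines are harmless.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `term_id`, `term_name`, `genes`
#'   (a list-column of character vectors).
#' @export
read_term_map <- function(path) {
  tm <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("term_id", "term_name", "gene")
  if (!all(need %in% names(tm))) {
    abort("Term TSV must have columns term_id, term_name, gene.",
          class = "mmpv_error_parse")
  }
  tm <- dplyr::mutate(tm, dplyr::across(dplyr::all_of(need), stringr::str_trim))
  if (any(is.na(tm$gene) | tm$gene == "")) {
    abort("Blank gene symbol in term map.", class = "mmpv_error_validation")
  }
  out <- tm |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$gene) |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(genes = list(sort(unique(.data$gene))), .groups = "drop")
  if (anyDuplicated(out$term_id)) {
    abort("A term_id maps to more than one term_name.", class = "mmpv_error_validation")
  }
  out
}
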