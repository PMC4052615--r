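#' Node degrees under the distinct-neighbour convention
#'
#' Degree of a node = number of distinct neighbours, with a self-loop
#' contributing 1 (not the usual 2). Repeated edges have already been
#' deduplicated by [read_edge_list()].
#'
#' @param graph Undirected igraph graph.
#' @return Named integer vector of degrees for all nodes.
#' @export
ppi_degrees <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  deg <- igraph::degree(graph, loops = FALSE)
  loops <- igraph::which_loop(graph)
  if (any(loops)) {
    ends <- igraph::ends(graph, igraph::E(graph)[loops], names = TRUE)[, 1L]
    loop_counts <- table(ends)
    deg[names(loop_counts)] <- deg[names(loop_counts)] + as.integer(loop_counts)
  }
  stats::setNames(as.integer(deg), names(deg))
}

#' Mean node degree of a PPI network
#'
#' @inheritParams ppi_degrees
#' @return Mean of [ppi_degrees()] over all nodes.
#' @export
network_mean_degree <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    abort("Cannot take the mean degree of an empty graph.",
          class = "mmpv_error_degenerate")
  }
  mean(ppi_degrees(graph))
}

#' Map a gene set onto a PPI network
#'
#' Returns the degree of each gene found in the graph; genes absent from
#' the network are reported as unmapped and excluded from downstream
#' testing (absence from the database is missingness, not isolation).
#'
#' @param genes Character vector of gene symbols.
#' @param graph Undirected igraph graph.
#' @return A list with `mapped` (tibble `gene`, `degree`) and `unmapped`
#'   (character vector).
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, A - C)
#' degree_map(c("A", "Z"), g)
#' @export
degree_map <- function(genes, graph) {
  genes <- unique(genes)
  deg <- ppi_degrees(graph)
  present <- genes[genes %in% names(deg)]
  list(mapped = tibble::tibble(gene = present,
                               degree = unname(deg[present])),
       unmapped = setdiff(genes, present))
}

#' One-sample degree test against the network mean
#'
#' Tests whether a gene set's mean degree exceeds the network-wide mean
#' degree: a one-sample, one-tailed Student t-test of the gene degrees
#' against the fixed constant `network_mean`, with alternative
#' `mean_degree > network_mean`.
#'
#' @param gene_degrees Numeric vector of degrees (>= 2 values, non-zero
#'   variance).
#' @param network_mean Network-wide mean degree (see
#'   [network_mean_degree()]).
#' @return A one-row tibble: `n`, `mean_degree`, `network_mean_degree`,
#'   `t`, `df`, `p_one_tailed`.
#' @examples
#' mean_degree_test(c(7, 8, 9), network_mean = 2)
#' @export
mean_degree_test <- function(gene_degrees, network_mean) {
  if (length(gene_degrees) < 2L) {
    abort("Need at least 2 mapped degrees.", class = "mmpv_error_degenerate")
  }
  if (stats::sd(gene_degrees) == 0) {
    abort("Degree variance is zero; the t statistic is undefined.",
          class = "mmpv_error_degenerate")
  }
  n <- length(gene_degrees)
  t_stat <- (mean(gene_degrees) - network_mean) / (stats::sd(gene_degrees) / sqrt(n))
  tibble::tibble(n = n,
                 mean_degree = mean(gene_degrees),
                 network_mean_degree = network_mean,
                 t = t_stat, df = n - 1,
                 p_one_tailed = stats::pt(t_stat, df = n - 1, lower.tail = FALSE))
}

#' Degree report for MMPV gene sets across features
#'
#' For each feature's MMPV mRNA set, maps the genes onto the network and
#' runs [mean_degree_test()] against the network mean degree; features
#' whose mapped set is too small or degenerate get `NA` statistics.
#'
#' @param mmpvs_by_feature Named list of `mmpv_result`s or tibbles with an
#'   `mrna_id` column.
#' @param graph Undirected igraph PPI network.
#' @return Tibble `feature`, `n_mapped`, `n_unmapped`, `mean_degree`,
#'   `network_mean_degree`, `t`, `p_one_tailed`.
#' @export
degree_report <- function(mmpvs_by_feature, graph) {
  net_mean <- network_mean_degree(graph)
  purrr::imap(mmpvs_by_feature, function(x, feat) {
    tab <- if (inherits(x, "mmpv_result")) x$mmpvs else x
    dm <- degree_map(unique(tab$mrna_id), graph)
    base <- tibble::tibble(feature = feat,
                           n_mapped = nrow(dm$mapped),
                           n_unmapped = length(dm$unmapped))
    test <- tryCatch(
      mean_degree_test(dm$mapped$degree, net_mean),
      mmpv_error_degenerate = function(e) {
        tibble::tibble(n = nrow(dm$mapped),
                       mean_degree = if (nrow(dm$mapped) > 0) mean(dm$mapped$degree) else NA_real_,
                       network_mean_degree = net_mean,
                       t = NA_real_, df = NA_real_, p_one_tailed = NA_real_)
      })
    dplyr::bind_cols(base, dplyr::select(test, -"n", -"df"))
  }) |>
    dplyr::bind_rows()
}
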