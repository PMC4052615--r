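#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of at least
#' `k` successes when drawing `n` genes from a background of `N` of which
#' `K` belong to the term.
#'
#' @param k Observed overlap (`0 <= k <= min(K, n)`).
#' @param K Term size within the background.
#' @param n Target-set size within the background.
#' @param N Background size.
#' @return Probability in (0, 1\].
#' @examples
#' hypergeometric_p(4, K = 5, n = 4, N = 10)  # 5/210
#' @export
hypergeometric_p <- function(k, K, n, N) {
  vals <- c(k, K, n, N)
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("Counts must be non-negative integers.", class = "mmpv_error_domain")
  }
  if (K > N || n > N || k > min(K, n)) {
    abort("Inconsistent counts: need k <= min(K, n) and K, n <= N.",
          class = "mmpv_error_domain")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric term enrichment of a gene set
#'
#' Tests every term of a term map for over-representation in the target
#' set relative to the background (the union of mRNAs of the supplied
#' targeting-pair list, in the standard workflow). Terms are intersected
#' with the background before counting. Raw p-values are thresholded at
#' `p_threshold` with no multiple-testing correction; a Benjamini-Hochberg
#' column `q_info` over all tested terms is attached for information only.
#'
#' @param target_genes Character vector, a subset of `background_genes`.
#' @param background_genes Character vector of background gene symbols.
#' @param term_map Term map tibble from [read_term_map()] (columns
#'   `term_id`, `term_name`, `genes` list-column).
#' @param p_threshold Report terms with `p < p_threshold` (default 1e-3).
#' @return Tibble `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`,
#'   `q_info`, sorted by ascending p.
#' @export
enrich_terms <- function(target_genes, background_genes, term_map,
                         p_threshold = 1e-3) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (!all(target_genes %in% background_genes)) {
    abort(sprintf("Target gene '%s' is not in the background.",
                  setdiff(target_genes, background_genes)[1L]),
          class = "mmpv_error_validation")
  }
  N <- length(background_genes)
  n <- length(target_genes)
  res <- term_map |>
    dplyr::mutate(
      term_genes = purrr::map(.data$genes, intersect, background_genes),
      K = lengths(.data$term_genes),
      k = purrr::map_int(.data$term_genes, ~ length(intersect(.x, target_genes))),
      n = n, N = N) |>
    dplyr::filter(.data$K > 0L) |>
    dplyr::mutate(p = purrr::pmap_dbl(list(.data$k, .data$K, .data$n, .data$N),
                                      hypergeometric_p))
  if (nrow(res) == 0L || n == 0L) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = double(), q_info = double()))
  }
  res$q_info <- bh_adjust(res$p)
  res |>
    dplyr::filter(.data$p < p_threshold) |>
    dplyr::arrange(.data$p) |>
    dplyr::select("term_id", "term_name", "k", "K", "n", "N", "p", "q_info")
}
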