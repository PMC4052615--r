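#' Cross-feature MMPV overlap counts
#'
#' Counts, for every pair of features, how many (miRNA, mRNA) pairs are
#' MMPVs under both. Overlap is on pair identity, not mRNA identity; set
#' `level = "mrna"` for a gene-level variant.
#'
#' @param mmpvs_by_feature Named list, one element per feature, each an
#'   `mmpv_result` or a tibble with `mirna_id` and `mrna_id` columns.
#' @param level `"pair"` (default) or `"mrna"`.
#' @return An object of class `mmpv_overlap`; [tidy()] gives the long form
#'   (`feature_1`, `feature_2`, `overlap`, self rows = per-feature counts),
#'   and `$counts` holds the symmetric matrix whose diagonal is the
#'   per-feature MMPV count.
#' @examples
#' sets <- list(A = tibble::tibble(mirna_id = c("m1", "m2"), mrna_id = c("G1", "G2")),
#'              B = tibble::tibble(mirna_id = "m1", mrna_id = "G1"))
#' tidy(overlap_counts(sets))
#' @export
overlap_counts <- function(mmpvs_by_feature, level = c("pair", "mrna")) {
  level <- match.arg(level)
  if (length(mmpvs_by_feature) < 1L || is.null(names(mmpvs_by_feature))) {
    abort("`mmpvs_by_feature` must be a non-empty named list.",
          class = "mmpv_error_validation")
  }
  sets <- purrr::map(mmpvs_by_feature, function(x) {
    tab <- if (inherits(x, "mmpv_result")) x$mmpvs else x
    if (level == "pair") {
      unique(paste(tab$mirna_id, tab$mrna_id, sep = "\r"))
    } else {
      unique(tab$mrna_id)
    }
  })
  feats <- names(sets)
  k <- length(feats)
  counts <- matrix(0L, k, k, dimnames = list(feats, feats))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      counts[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  structure(list(features = feats, counts = counts, level = level,
                 sets = sets),
            class = "mmpv_overlap")
}

#' @export
print.mmpv_overlap <- function(x, ...) {
  cat(sprintf("<mmpv_overlap> %d features, %s-level\n", length(x$features), x$level))
  print(x$counts)
  invisible(x)
}

#' @rdname overlap_counts
#' @param x An `mmpv_overlap`.
#' @param ... Unused.
#' @export
tidy.mmpv_overlap <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    rlang::set_names(c("feature_1", "feature_2", "overlap")) |>
    dplyr::mutate(overlap = as.integer(.data$overlap)) |>
    dplyr::filter(match(.data$feature_1, x$features) <=
                    match(.data$feature_2, x$features))
}

#' @rdname overlap_counts
#' @param object An `mmpv_overlap`.
#' @export
autoplot.mmpv_overlap <- function(object, ...) {
  long <- tibble::as_tibble(as.table(object$counts), .name_repair = "minimal") |>
    rlang::set_names(c("feature_1", "feature_2", "overlap"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature_1, y = .data$feature_2,
                                     fill = as.integer(.data$overlap))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$overlap), colour = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("MMPV overlap (%s level)", object$level)) +
    ggplot2::theme_minimal()
}

#' mRNAs shared by the MMPVs of two features
#'
#' Extracts the mRNAs of pairs that are MMPVs under both `feature_a` and
#' `feature_b`. With `exclude_others = TRUE`, mRNAs are dropped when any of
#' their pairs' miRNAs also appears in an MMPV of a third feature — an
#' exclusivity reading of the shared-gene filter; the inclusive reading is
#' the default.
#'
#' @inheritParams overlap_counts
#' @param feature_a,feature_b Two feature names present in the list.
#' @param exclude_others Apply the miRNA exclusivity filter (default
#'   `FALSE`).
#' @return Character vector of mRNA ids (sorted).
#' @export
two_feature_genes <- function(mmpvs_by_feature, feature_a, feature_b,
                              exclude_others = FALSE) {
  tabs <- purrr::map(mmpvs_by_feature, function(x) {
    if (inherits(x, "mmpv_result")) x$mmpvs else x
  })
  missing <- setdiff(c(feature_a, feature_b), names(tabs))
  if (length(missing) > 0L) {
    abort(sprintf("Feature '%s' is not in `mmpvs_by_feature`.", missing[1L]),
          class = "mmpv_error_config")
  }
  key <- function(tab) paste(tab$mirna_id, tab$mrna_id, sep = "\r")
  a <- tabs[[feature_a]]
  b <- tabs[[feature_b]]
  shared <- a[key(a) %in% key(b), , drop = FALSE]
  if (exclude_others) {
    other_mirnas <- unique(unlist(purrr::map(
      tabs[setdiff(names(tabs), c(feature_a, feature_b))], "mirna_id")))
    shared <- shared[!shared$mirna_id %in% other_mirnas, , drop = FALSE]
  }
  sort(unique(shared$mrna_id))
}
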