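#' Pearson correlation of two expression vectors
#'
#' Pairwise-complete Pearson correlation, the statistic used to quantify a
#' pair's regulatory pattern within one status. The result is clamped to
#' \[-1, 1\] against floating-point overshoot.
#'
#' @param x,y Numeric vectors of equal length; missing entries are dropped
#'   pairwise before computing.
#' @return A single correlation in \[-1, 1\].
#' @section Errors: fewer than 2 complete observations signals
#'   `mmpv_error_insufficient_data`; a constant vector signals
#'   `mmpv_error_constant_input` (callers drop such pairs and count them).
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6))
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "mmpv_error_domain")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) {
    abort("Fewer than 2 pairwise-complete observations.",
          class = "mmpv_error_insufficient_data")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for constant input.",
          class = "mmpv_error_constant_input")
  }
  clamp1(stats::cor(x, y))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Exact test under bivariate normality: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom. `r = +/-1` returns `p = 0` as the
#' degenerate limit.
#'
#' @param r Correlation in \[-1, 1\].
#' @param n Number of observations used (`>= 3`).
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' correlation_p_value(0, 10)
#' correlation_p_value(0.8, 4)
#' @export
correlation_p_value <- function(r, n) {
  assert_scalar_number(r, "r")
  if (abs(r) > 1) abort("`r` must lie in [-1, 1].", class = "mmpv_error_domain")
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    abort("`n` must be at least 3.", class = "mmpv_error_insufficient_data")
  }
  if (abs(r) == 1) return(0)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: values are returned in the input order and
#' satisfy `p <= q <= 1`.
#'
#' @param pvals Non-empty numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `pvals`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) {
    abort("`pvals` must be non-empty.", class = "mmpv_error_domain")
  }
  assert_prob(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-stratum correlations for every targeting pair
#'
#' For one binary feature, splits the samples into its two statuses and
#' computes, per targeting pair and per stratum, the pairwise-complete
#' Pearson correlation between the miRNA and mRNA expression rows, its
#' two-sided p-value, and a Benjamini-Hochberg q-value adjusted per stratum
#' across all retained pairs.
#'
#' Pairs are dropped (and counted, never silently) when an id is missing
#' from the matrices (`unresolved_pairs`), a stratum has fewer than
#' `min_n` pairwise-complete samples (`small_n_pairs`), or a member is
#' constant within a stratum (`degenerate_pairs`). The counts are attached
#' as the `"dropped"` attribute of the result.
#'
#' @param pairs Tibble of targeting pairs (`mirna_id`, `mrna_id`,
#'   `healthy_sign`), see [read_pair_list()].
#' @param mirna_matrix,mrna_matrix Named numeric matrices
#'   (entities x samples), see [read_expression_matrix()].
#' @param annotation Sample annotation tibble, see
#'   [read_sample_annotations()].
#' @param feature_name One feature of the registry.
#' @param registry Feature registry, see [feature_registry()].
#' @param min_n Minimum pairwise-complete samples per stratum (default 3,
#'   the minimum for a correlation p-value).
#' @return A tibble with one row per retained pair: the pair columns plus
#'   `r1`, `n1`, `p1`, `q1`, `r2`, `n2`, `p2`, `q2` (status1 and status2
#'   statistics, in registry order).
#' @export
stratified_pair_correlations <- function(pairs, mirna_matrix, mrna_matrix,
                                         annotation, feature_name,
                                         registry = default_feature_registry(),
                                         min_n = 3L) {
  reg <- registry_row(registry, feature_name)
  if (!feature_name %in% annotation$feature) {
    abort(sprintf("Feature '%s' is absent from the annotation.", feature_name),
          class = "mmpv_error_config")
  }
  validate_annotation(annotation[annotation$feature == feature_name, ], registry)
  strata <- list(
    intersect(stratum_samples(annotation, feature_name, reg$status1),
              intersect(colnames(mirna_matrix), colnames(mrna_matrix))),
    intersect(stratum_samples(annotation, feature_name, reg$status2),
              intersect(colnames(mirna_matrix), colnames(mrna_matrix)))
  )

  dropped <- c(unresolved_pairs = 0L, small_n_pairs = 0L, degenerate_pairs = 0L)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mi <- pairs$mirna_id[i]
    ge <- pairs$mrna_id[i]
    if (!mi %in% rownames(mirna_matrix) || !ge %in% rownames(mrna_matrix)) {
      dropped[["unresolved_pairs"]] <- dropped[["unresolved_pairs"]] + 1L
      next
    }
    stat <- rep(NA_real_, 6L) # r1 n1 p1 r2 n2 p2
    ok <- TRUE
    for (s in 1:2) {
      x <- mirna_matrix[mi, strata[[s]]]
      y <- mrna_matrix[ge, strata[[s]]]
      cc <- stats::complete.cases(x, y)
      n <- sum(cc)
      if (n < min_n) {
        dropped[["small_n_pairs"]] <- dropped[["small_n_pairs"]] + 1L
        ok <- FALSE
        break
      }
      if (stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) {
        warn(sprintf("Pair (%s, %s) is constant in stratum %s; dropped.",
                     mi, ge, if (s == 1) reg$status1 else reg$status2),
             class = "mmpv_warning_degenerate")
        dropped[["degenerate_pairs"]] <- dropped[["degenerate_pairs"]] + 1L
        ok <- FALSE
        break
      }
      r <- pearson_r(x, y)
      stat[(s - 1L) * 3L + 1:3] <- c(r, n, correlation_p_value(r, n))
    }
    if (ok) {
      rows[[i]] <- tibble::tibble(
        mirna_id = mi, mrna_id = ge, healthy_sign = pairs$healthy_sign[i],
        r1 = stat[1L], n1 = as.integer(stat[2L]), p1 = stat[3L],
        r2 = stat[4L], n2 = as.integer(stat[5L]), p2 = stat[6L])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out$q1 <- bh_adjust(out$p1)
    out$q2 <- bh_adjust(out$p2)
    out <- dplyr::relocate(out, "q1", .after = "p1") |>
      dplyr::relocate("q2", .after = "p2")
  } else {
    out <- tibble::tibble(mirna_id = character(), mrna_id = character(),
                          healthy_sign = character(),
                          r1 = double(), n1 = integer(), p1 = double(), q1 = double(),
                          r2 = double(), n2 = integer(), p2 = double(), q2 = double())
  }
  attr(out, "dropped") <- dropped
  out
}

#' Classify a pair's correlation change between strata
#'
#' The decision rule at the heart of MMPV detection. A pair whose two
#' stratum correlations are both insignificant (`q1 >= alpha` and
#' `q2 >= alpha`) is `"none"`. Otherwise: opposite algebraic signs give
#' `"sign_change"`; equal nonzero signs with a between-stratum ratio
#' `r1/r2 >= fold` or `<= 1/fold` give `"fold_change"`; exactly one zero
#' correlation is treated as an infinite ratio (`"fold_change"`); anything
#' else is `"none"`.
#'
#' @param r1,r2 Stratum correlations in \[-1, 1\] (vectorized).
#' @param q1,q2 Matching FDR q-values in \[0, 1\].
#' @param alpha Significance level for the "both insignificant" removal
#'   (default 0.05).
#' @param fold Ratio threshold (> 1, default 2).
#' @return Character vector over `{"sign_change", "fold_change", "none"}`.
#' @examples
#' classify_pair(0.5, -0.5, 0.01, 0.5)   # sign_change
#' classify_pair(0.6, 0.2, 0.01, 0.6)    # fold_change (ratio 3)
#' classify_pair(0.5, 0.4, 0.01, 0.01)   # none (ratio 1.25)
#' @export
classify_pair <- function(r1, r2, q1, q2, alpha = 0.05, fold = 2.0) {
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1) {
    abort("`fold` must be a single number > 1.", class = "mmpv_error_domain")
  }
  if (any(abs(c(r1, r2)) > 1, na.rm = TRUE)) {
    abort("Correlations must lie in [-1, 1].", class = "mmpv_error_domain")
  }
  assert_prob(c(q1, q2), "q")
  n <- max(length(r1), length(r2), length(q1), length(q2))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  q1 <- rep_len(q1, n); q2 <- rep_len(q2, n)
  ratio <- r1 / r2
  dplyr::case_when(
    q1 >= alpha & q2 >= alpha            ~ "none",
    sign(r1) * sign(r2) < 0              ~ "sign_change",
    xor(r1 == 0, r2 == 0)                ~ "fold_change",
    r1 == 0 & r2 == 0                    ~ "none",
    ratio >= fold | ratio <= 1 / fold    ~ "fold_change",
    TRUE                                 ~ "none"
  )
}

#' Encode a regulatory-pattern string
#'
#' Builds the `H_S1_S2` pattern: the healthy-population sign (`U` positive,
#' `D` negative), then the status1 and status2 regulation letters, with
#' `*` appended to a stratum token when that stratum's q-value is below
#' `alpha`. For example, a pair negatively regulated in the healthy
#' population, positive in status1, and significantly positive in status2
#' encodes as `"D_U_U*"`.
#'
#' @param healthy_sign `"U"` or `"D"` (vectorized).
#' @param r1,r2 Stratum correlations; an exact zero is encoded as `U` with
#'   a warning (a measure-zero tie that still needs a total function).
#' @param q1,q2 Stratum q-values.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of pattern strings matching
#'   `^[UD]_[UD]\*?_[UD]\*?$`.
#' @examples
#' encode_pattern("D", r1 = 0.1, q1 = 0.3, r2 = 0.6, q2 = 0.001)  # "D_U_U*"
#' @export
encode_pattern <- function(healthy_sign, r1, q1, r2, q2, alpha = 0.05) {
  if (any(!healthy_sign %in% c("U", "D"))) {
    abort("healthy_sign must be 'U' or 'D'.", class = "mmpv_error_domain")
  }
  if (any(r1 == 0, na.rm = TRUE) || any(r2 == 0, na.rm = TRUE)) {
    warn("Correlation exactly 0 encoded as 'U' (tie convention).",
         class = "mmpv_warning_tie")
  }
  token <- function(r, q) {
    paste0(ifelse(r > 0 | r == 0, "U", "D"), ifelse(q < alpha, "*", ""))
  }
  paste(healthy_sign, token(r1, q1), token(r2, q2), sep = "_")
}

#' Detect miRNA-mRNA paired variations for one feature
#'
#' The full detection stage: per-stratum correlations
#' ([stratified_pair_correlations()]), classification ([classify_pair()]),
#' and pattern encoding ([encode_pattern()]). Only pairs classed
#' `sign_change` or `fold_change` are returned.
#'
#' @inheritParams stratified_pair_correlations
#' @inheritParams classify_pair
#' @return An object of class `mmpv_result`: use [tidy()] for the per-pair
#'   table, [glance()] for the summary counts (`n_fold_change`,
#'   `n_sign_change`, `n_total`), and [autoplot()] for an r1-vs-r2 view.
#' @examples
#' sim <- simulate_dataset(demo_dataset_spec(seed = 1))
#' res <- detect_mmpvs(sim$pairs, sim$mirna, sim$mrna, sim$annotation, "ER",
#'                     registry = sim$registry)
#' glance(res)
#' @export
detect_mmpvs <- function(pairs, mirna_matrix, mrna_matrix, annotation,
                         feature_name, registry = default_feature_registry(),
                         alpha = 0.05, fold = 2.0, min_n = 3L) {
  corr <- stratified_pair_correlations(pairs, mirna_matrix, mrna_matrix,
                                       annotation, feature_name,
                                       registry = registry, min_n = min_n)
  tab <- corr |>
    dplyr::mutate(
      mmpv_class = classify_pair(.data$r1, .data$r2, .data$q1, .data$q2,
                                 alpha = alpha, fold = fold)) |>
    dplyr::filter(.data$mmpv_class != "none") |>
    dplyr::mutate(
      pattern = encode_pattern(.data$healthy_sign, .data$r1, .data$q1,
                               .data$r2, .data$q2, alpha = alpha),
      feature = feature_name)
  counts <- tibble::tibble(
    feature = feature_name,
    n_fold_change = sum(tab$mmpv_class == "fold_change"),
    n_sign_change = sum(tab$mmpv_class == "sign_change"),
    n_total = nrow(tab))
  structure(
    list(mmpvs = tab, counts = counts, dropped = attr(corr, "dropped"),
         n_tested = nrow(corr), feature = feature_name,
         alpha = alpha, fold = fold),
    class = "mmpv_result")
}

#' @export
print.mmpv_result <- function(x, ...) {
  cat(sprintf("<mmpv_result> feature %s: %d MMPVs (%d sign-change, %d fold-change) among %d tested pairs\n",
              x$feature, x$counts$n_total, x$counts$n_sign_change,
              x$counts$n_fold_change, x$n_tested))
  cat(sprintf("  alpha = %g, fold = %g; dropped: %s\n", x$alpha, x$fold,
              paste(names(x$dropped), x$dropped, sep = "=", collapse = ", ")))
  print(x$mmpvs, ...)
  invisible(x)
}

#' @rdname detect_mmpvs
#' @param x An `mmpv_result`.
#' @param ... Unused.
#' @export
tidy.mmpv_result <- function(x, ...) x$mmpvs

#' @rdname detect_mmpvs
#' @export
glance.mmpv_result <- function(x, ...) {
  dplyr::mutate(x$counts, n_tested = x$n_tested, alpha = x$alpha, fold = x$fold)
}

#' @rdname detect_mmpvs
#' @param object An `mmpv_result`.
#' @export
autoplot.mmpv_result <- function(object, ...) {
  ggplot2::ggplot(object$mmpvs,
                  ggplot2::aes(x = .data$r1, y = .data$r2,
                               colour = .data$mmpv_class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "r (status1)", y = "r (status2)", colour = "class",
                  title = sprintf("MMPVs for %s", object$feature)) +
    ggplot2::theme_minimal()
}
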