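#' SAM d statistic for two groups
#'
#' Moderated two-sample statistic `d = (mean1 - mean2) / (s + s0)`, where
#' `s` is the unpaired pooled standard error of the mean difference and
#' `s0` is a small positive "exchangeability" constant that damps the
#' statistic for entities with tiny variance.
#'
#' @param group1,group2 Numeric vectors (length >= 2 each).
#' @param s0 Positive additive constant; see [choose_s0()].
#' @return The d statistic (a single number).
#' @examples
#' sam_d_statistic(c(3, 4, 5), c(1, 2, 3), s0 = 0.1)
#' @export
sam_d_statistic <- function(group1, group2, s0) {
  if (length(group1) < 2L || length(group2) < 2L) {
    abort("Each group needs at least 2 observations.",
          class = "mmpv_error_insufficient_data")
  }
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0) {
    abort("`s0` must be a single positive number.", class = "mmpv_error_domain")
  }
  (mean(group1) - mean(group2)) / (pooled_se(group1, group2) + s0)
}

pooled_se <- function(group1, group2) {
  n1 <- length(group1)
  n2 <- length(group2)
  ss <- sum((group1 - mean(group1))^2) + sum((group2 - mean(group2))^2)
  sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
}

#' Choose the SAM exchangeability constant s0
#'
#' The median of the per-entity pooled standard errors; if the median is 0
#' (many zero-variance rows), falls back to the smallest strictly positive
#' value.
#'
#' @param standard_errors Non-empty numeric vector of per-entity standard
#'   errors (>= 0).
#' @return A single positive number.
#' @examples
#' choose_s0(c(1, 2, 9))
#' @export
choose_s0 <- function(standard_errors) {
  if (length(standard_errors) == 0L) {
    abort("`standard_errors` must be non-empty.", class = "mmpv_error_domain")
  }
  if (any(standard_errors < 0)) {
    abort("Standard errors cannot be negative.", class = "mmpv_error_domain")
  }
  s0 <- stats::median(standard_errors)
  if (s0 > 0) return(s0)
  pos <- standard_errors[standard_errors > 0]
  if (length(pos) == 0L) {
    abort("All standard errors are zero; data are degenerate.",
          class = "mmpv_error_degenerate")
  }
  min(pos)
}

# Row-wise d statistics for a matrix given a logical status1 indicator.
# Returns list(d, se) so s0 can be chosen once from the observed labels.
row_d_statistics <- function(mat, in1, s0 = NULL) {
  m1 <- rowMeans(mat[, in1, drop = FALSE])
  m2 <- rowMeans(mat[, !in1, drop = FALSE])
  n1 <- sum(in1)
  n2 <- sum(!in1)
  ss <- rowSums((mat[, in1, drop = FALSE] - m1)^2) +
    rowSums((mat[, !in1, drop = FALSE] - m2)^2)
  se <- sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  if (is.null(s0)) s0 <- choose_s0(se)
  list(d = (m1 - m2) / (se + s0), se = se, s0 = s0, diff = m1 - m2)
}

#' Permutation p-values for SAM d statistics
#'
#' For every row of the expression matrix, computes the observed d
#' statistic between the two statuses of `feature_name` (s0 fixed at the
#' median per-row standard error of the observed labelling) and an
#' empirical two-sided p-value from `n_perm` uniformly random permutations
#' of the status labels:
#' `p = (1 + #\{b : |d_b| >= |d_obs|\}) / (n_perm + 1)`.
#'
#' @param mat Named numeric matrix (entities x samples), no missing values.
#' @param annotation Sample annotation tibble.
#' @param feature_name One feature of the registry.
#' @param registry Feature registry.
#' @param n_perm Number of label permutations (>= 1, default 200).
#' @param seed Integer seed making the permutations reproducible.
#' @return A tibble with columns `entity_id`, `d`, `p_perm`, `direction`
#'   (`"U"` when `mean(status1) > mean(status2)`, else `"D"`).
#' @export
permutation_p_values <- function(mat, annotation, feature_name,
                                 registry = default_feature_registry(),
                                 n_perm = 200L, seed = 1L) {
  if (n_perm < 1L) abort("`n_perm` must be >= 1.", class = "mmpv_error_domain")
  reg <- registry_row(registry, feature_name)
  # sorted so that results do not depend on column order within a stratum
  s1 <- sort(intersect(colnames(mat), stratum_samples(annotation, feature_name, reg$status1)))
  s2 <- sort(intersect(colnames(mat), stratum_samples(annotation, feature_name, reg$status2)))
  if (length(s1) < 2L || length(s2) < 2L) {
    abort(sprintf("Feature '%s' needs at least 2 samples per status (have %d and %d).",
                  feature_name, length(s1), length(s2)),
          class = "mmpv_error_config")
  }
  sub <- mat[, c(s1, s2), drop = FALSE]
  if (anyNA(sub)) {
    abort("Differential testing requires complete expression values.",
          class = "mmpv_error_validation")
  }
  in1 <- c(rep(TRUE, length(s1)), rep(FALSE, length(s2)))
  obs <- row_d_statistics(sub, in1)

  set.seed(seed)
  exceed <- integer(nrow(sub))
  for (b in seq_len(n_perm)) {
    perm <- sample(in1)
    db <- row_d_statistics(sub, perm, s0 = obs$s0)$d
    exceed <- exceed + (abs(db) >= abs(obs$d))
  }
  tibble::tibble(entity_id = rownames(sub),
                 d = unname(obs$d),
                 p_perm = unname((1 + exceed) / (n_perm + 1)),
                 direction = ifelse(obs$diff > 0, "U", "D"))
}

#' Full differential-expression table for one feature
#'
#' [permutation_p_values()] plus a Benjamini-Hochberg q-value computed
#' across the rows of the matrix.
#'
#' @inheritParams permutation_p_values
#' @param alpha Kept in the result's attributes for downstream selection
#'   (default 0.05).
#' @return Tibble `entity_id`, `d`, `p_perm`, `q`, `direction`.
#' @export
differential_table <- function(mat, annotation, feature_name,
                               registry = default_feature_registry(),
                               n_perm = 200L, alpha = 0.05, seed = 1L) {
  out <- permutation_p_values(mat, annotation, feature_name,
                              registry = registry, n_perm = n_perm, seed = seed)
  out$q <- bh_adjust(out$p_perm)
  out <- dplyr::relocate(out, "q", .after = "p_perm")
  attr(out, "alpha") <- alpha
  out
}

#' Select differentially expressed MMPVs (DE-MMPVs)
#'
#' Keeps MMPVs whose miRNA and mRNA are both significantly differentially
#' expressed (`q < alpha` in their respective differential tables) and
#' renders the conventional display label
#' `"mirna(dir) mrna(dir) pattern"`.
#'
#' @param mmpvs An `mmpv_result` from [detect_mmpvs()] or its [tidy()]
#'   tibble.
#' @param mirna_table,mrna_table Differential tables from
#'   [differential_table()] for the miRNA and mRNA matrices.
#' @param alpha Significance level on the differential q-values
#'   (default 0.05).
#' @return A tibble of retained MMPVs with the differential statistics of
#'   both members (`mirna_d`, `mirna_q`, `mirna_direction`, likewise for
#'   `mrna_`) and a `label` column.
#' @export
select_de_mmpvs <- function(mmpvs, mirna_table, mrna_table, alpha = 0.05) {
  tab <- if (inherits(mmpvs, "mmpv_result")) mmpvs$mmpvs else mmpvs
  if (nrow(tab) == 0L) {
    return(tibble::tibble(mirna_id = character(), mrna_id = character(),
                          pattern = character(), feature = character(),
                          mirna_d = double(), mirna_q = double(),
                          mirna_direction = character(),
                          mrna_d = double(), mrna_q = double(),
                          mrna_direction = character(), label = character()))
  }
  missing_mi <- setdiff(tab$mirna_id, mirna_table$entity_id)
  missing_ge <- setdiff(tab$mrna_id, mrna_table$entity_id)
  if (length(missing_mi) > 0L || length(missing_ge) > 0L) {
    abort(sprintf("MMPV entity '%s' is missing from its differential table.",
                  c(missing_mi, missing_ge)[1L]),
          class = "mmpv_error_consistency")
  }
  mi <- dplyr::select(mirna_table, mirna_id = "entity_id", mirna_d = "d",
                      mirna_q = "q", mirna_direction = "direction")
  ge <- dplyr::select(mrna_table, mrna_id = "entity_id", mrna_d = "d",
                      mrna_q = "q", mrna_direction = "direction")
  tab |>
    dplyr::inner_join(mi, by = "mirna_id") |>
    dplyr::inner_join(ge, by = "mrna_id") |>
    dplyr::filter(.data$mirna_q < alpha, .data$mrna_q < alpha) |>
    dplyr::mutate(label = sprintf("%s(%s) %s(%s) %s",
                                  .data$mirna_id, .data$mirna_direction,
                                  .data$mrna_id, .data$mrna_direction,
                                  .data$pattern))
}
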