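#' Binary feature registry
#'
#' A feature registry fixes, for each binary biopathological feature, the
#' display names of its two statuses and which of them is "status1". The
#' status1/status2 order matters downstream: status1 always occupies the
#' middle token of a pattern string, and the differential-expression
#' direction is the sign of `mean(status1) - mean(status2)`.
#'
#' `default_feature_registry()` returns the five breast-cancer stratifiers
#' commonly used in this analysis: oestrogen receptor (ER), TP53 mutation,
#' five-year survival, HER2, and basal-like subtype.
#'
#' @param feature Character vector of feature names.
#' @param status1,status2 Display names of the first and second status of
#'   each feature (same length as `feature`).
#'
#' @return A tibble with columns `feature`, `status1`, `status2`.
#' @examples
#' default_feature_registry()
#' feature_registry("ER", "ER+", "ER-")
#' @export
feature_registry <- function(feature, status1, status2) {
  if (anyDuplicated(feature)) {
    abort("Feature names in a registry must be unique.", class = "mmpv_error_validation")
  }
  if (any(status1 == status2)) {
    abort("The two statuses of a feature must be distinct.", class = "mmpv_error_validation")
  }
  tibble::tibble(feature = as.character(feature),
                 status1 = as.character(status1),
                 status2 = as.character(status2))
}

#' @rdname feature_registry
#' @export
default_feature_registry <- function() {
  feature_registry(
    feature = c("ER", "TP53", "survival5", "HER2", "subtype"),
    status1 = c("ER+", "TP53+", "survival5+", "HER2+", "basal"),
    status2 = c("ER-", "TP53-", "survival5-", "HER2-", "nonbasal")
  )
}

registry_row <- function(registry, feature_name) {
  row <- dplyr::filter(registry, .data$feature == feature_name)
  if (nrow(row) != 1L) {
    abort(sprintf("Feature '%s' is not in the registry.", feature_name),
          class = "mmpv_error_config")
  }
  row
}

# sample ids of one stratum of a feature, in annotation order
stratum_samples <- function(annotation, feature_name, status_name) {
  annotation$sample_id[annotation$feature == feature_name &
                         annotation$status == status_name]
}
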