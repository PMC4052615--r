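#' Draw a correlated bivariate-normal regulator/target sample
#'
#' One stratum's worth of expression for a single miRNA-mRNA pair: `n`
#' draws from a bivariate normal with the given means, a common standard
#' deviation, and population correlation `rho`. Deterministic for a given
#' seed.
#'
#' @param rho Population correlation, strictly inside (-1, 1).
#' @param n Number of samples (>= 2).
#' @param mean_x,mean_y Means of the miRNA (x) and mRNA (y) components.
#' @param sd Common standard deviation (> 0).
#' @param seed Integer seed for this draw.
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @examples
#' s <- sample_bivariate_pair(0.9, 100, seed = 7)
#' cor(s$x, s$y)
#' @export
sample_bivariate_pair <- function(rho, n, mean_x = 0, mean_y = 0, sd = 1,
                                  seed = NULL) {
  assert_scalar_number(rho, "rho")
  if (abs(rho) >= 1) {
    abort("`rho` must lie strictly inside (-1, 1).", class = "mmpv_error_domain")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("`n` must be at least 2.", class = "mmpv_error_domain")
  }
  if (sd <= 0) abort("`sd` must be positive.", class = "mmpv_error_domain")
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  list(x = mean_x + sd * z1,
       y = mean_y + sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Specify one simulated targeting pair
#'
#' A pair specification fixes the population correlation in each stratum,
#' the between-status mean shifts (differential expression), and the noise
#' level for one miRNA-mRNA pair. The expected MMPV class implied by the
#' population correlations (significance ignored) is computed with the same
#' rule as [classify_pair()].
#'
#' @param mirna_id,mrna_id Entity identifiers.
#' @param healthy_sign `"U"` or `"D"`: the pair's regulatory sign in the
#'   healthy population.
#' @param rho_status1,rho_status2 Population correlations per stratum,
#'   inside (-1, 1).
#' @param delta_mirna,delta_mrna Mean of status1 minus mean of status2 for
#'   each entity (0 = no differential expression).
#' @param noise_sd Common standard deviation of the draws (> 0).
#' @return A one-row tibble.
#' @export
pair_spec <- function(mirna_id, mrna_id, healthy_sign = "D",
                      rho_status1 = 0, rho_status2 = 0,
                      delta_mirna = 0, delta_mrna = 0, noise_sd = 1) {
  if (abs(rho_status1) >= 1 || abs(rho_status2) >= 1) {
    abort("Population correlations must lie strictly inside (-1, 1).",
          class = "mmpv_error_domain")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.", class = "mmpv_error_domain")
  if (!healthy_sign %in% c("U", "D")) {
    abort("healthy_sign must be 'U' or 'D'.", class = "mmpv_error_domain")
  }
  tibble::tibble(mirna_id = mirna_id, mrna_id = mrna_id,
                 healthy_sign = healthy_sign,
                 rho_status1 = rho_status1, rho_status2 = rho_status2,
                 delta_mirna = delta_mirna, delta_mrna = delta_mrna,
                 noise_sd = noise_sd)
}

#' Specify a simulated dataset
#'
#' @param pair_specs Tibble of pair specifications (rows from
#'   [pair_spec()], bound together).
#' @param n_status1,n_status2 Samples per stratum (>= 3 each, the minimum
#'   for a correlation p-value).
#' @param feature_name Feature the strata belong to (must be in
#'   `registry`).
#' @param seed Master seed; per-pair substreams are derived from
#'   `(seed, pair index)` so adding pairs never perturbs earlier pairs.
#' @param registry Feature registry, see [feature_registry()].
#' @param alpha,fold Passed to the truth-label rule (see [pair_spec()]).
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(pair_specs, n_status1, n_status2,
                         feature_name = "ER", seed = 1L,
                         registry = default_feature_registry(),
                         alpha = 0.05, fold = 2.0) {
  if (n_status1 < 3 || n_status2 < 3) {
    abort("Each stratum needs at least 3 samples.", class = "mmpv_error_domain")
  }
  ids <- c(pair_specs$mirna_id, pair_specs$mrna_id)
  if (anyDuplicated(pair_specs$mirna_id) || anyDuplicated(pair_specs$mrna_id)) {
    abort("Entity ids must be distinct across pair specs (one expression row per entity).",
          class = "mmpv_error_spec")
  }
  registry_row(registry, feature_name)
  structure(list(pair_specs = pair_specs,
                 n_status1 = as.integer(n_status1),
                 n_status2 = as.integer(n_status2),
                 feature_name = feature_name, seed = as.integer(seed),
                 registry = registry, alpha = alpha, fold = fold),
            class = "dataset_spec")
}

#' Bundled demonstration dataset specification
#'
#' A small mixed design used by examples and the pipeline demo: a handful
#' of sign-change, fold-change, differentially expressed, and null pairs
#' for the ER feature.
#'
#' @param seed Master seed.
#' @param n Samples per stratum.
#' @return A `dataset_spec`.
#' @export
demo_dataset_spec <- function(seed = 20140518L, n = 50L) {
  specs <- dplyr::bind_rows(
    pair_spec("hsa-miR-1",   "CA3",   "D", rho_status1 =  0.7, rho_status2 = -0.7),
    pair_spec("hsa-miR-375", "FOLR1", "D", rho_status1 =  0.6, rho_status2 = -0.8,
              delta_mirna = -2, delta_mrna = 2),
    pair_spec("hsa-miR-155", "CBFB",  "D", rho_status1 =  0.8, rho_status2 =  0.3),
    pair_spec("hsa-miR-29c", "DNMT3B", "U", rho_status1 = -0.2, rho_status2 = -0.75,
              delta_mirna = 1.5, delta_mrna = -1.5),
    pair_spec("hsa-miR-107", "CDK6",  "D", rho_status1 =  0.5, rho_status2 =  0.5),
    pair_spec("hsa-let-7b",  "CCND1", "D", rho_status1 = -0.4, rho_status2 = -0.4)
  )
  dataset_spec(specs, n_status1 = n, n_status2 = n, feature_name = "ER",
               seed = seed)
}

#' Benchmark dataset specification for detection calibration
#'
#' The mixed design used to measure detection operating characteristics:
#' `n_sign` sign-change pairs (population correlations +0.7 / -0.7),
#' `n_fold` fold-change pairs (0.6 / 0.2, a population ratio of 3), and
#' `n_null` null pairs with no regulatory coupling in either stratum
#' (rho 0 / 0), at `n` samples per stratum.
#'
#' @param seed Master seed.
#' @param n_sign,n_fold,n_null Pairs of each kind.
#' @param n Samples per stratum.
#' @return A `dataset_spec`.
#' @export
benchmark_dataset_spec <- function(seed = 1L, n_sign = 100L, n_fold = 100L,
                                   n_null = 1000L, n = 60L) {
  k <- n_sign + n_fold + n_null
  kind <- rep(c("sign", "fold", "null"), c(n_sign, n_fold, n_null))
  specs <- tibble::tibble(
    mirna_id = sprintf("mir%04d", seq_len(k)),
    mrna_id = sprintf("gene%04d", seq_len(k)),
    healthy_sign = "D",
    rho_status1 = c(sign = 0.7, fold = 0.6, null = 0)[kind],
    rho_status2 = c(sign = -0.7, fold = 0.2, null = 0)[kind],
    delta_mirna = 0, delta_mrna = 0, noise_sd = 1)
  dataset_spec(specs, n_status1 = n, n_status2 = n, feature_name = "ER",
               seed = seed)
}

#' Simulate a paired miRNA/mRNA expression dataset
#'
#' Generates, per pair and per stratum, bivariate-normal expression with
#' the specified population correlation and per-status mean shift, and
#' assembles the miRNA and mRNA expression matrices, the sample
#' annotation, the pair list, and a ground-truth table whose
#' `expected_class` applies the [classify_pair()] rule to the population
#' correlations with significance ignored.
#'
#' Samples `s1 .. s(n1)` carry status1; the remainder carry status2.
#'
#' @param spec A [dataset_spec()].
#' @return A list: `mirna`, `mrna` (matrices), `annotation`, `pairs`,
#'   `truth` (tibbles), `feature`, `registry`.
#' @examples
#' sim <- simulate_dataset(demo_dataset_spec(seed = 1, n = 30))
#' dim(sim$mirna)
#' sim$truth
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  ps <- spec$pair_specs
  n1 <- spec$n_status1
  n2 <- spec$n_status2
  samples <- sprintf("s%d", seq_len(n1 + n2))
  reg <- registry_row(spec$registry, spec$feature_name)

  mirna <- matrix(NA_real_, nrow(ps), n1 + n2,
                  dimnames = list(ps$mirna_id, samples))
  mrna <- matrix(NA_real_, nrow(ps), n1 + n2,
                 dimnames = list(ps$mrna_id, samples))
  half <- function(delta) delta / 2
  for (i in seq_len(nrow(ps))) {
    d1 <- sample_bivariate_pair(ps$rho_status1[i], n1,
                                mean_x = half(ps$delta_mirna[i]),
                                mean_y = half(ps$delta_mrna[i]),
                                sd = ps$noise_sd[i],
                                seed = substream_seed(spec$seed, 2L * i - 1L))
    d2 <- sample_bivariate_pair(ps$rho_status2[i], n2,
                                mean_x = -half(ps$delta_mirna[i]),
                                mean_y = -half(ps$delta_mrna[i]),
                                sd = ps$noise_sd[i],
                                seed = substream_seed(spec$seed, 2L * i))
    mirna[i, ] <- c(d1$x, d2$x)
    mrna[i, ] <- c(d1$y, d2$y)
  }

  annotation <- tibble::tibble(
    sample_id = samples,
    feature = spec$feature_name,
    status = c(rep(reg$status1, n1), rep(reg$status2, n2)))

  truth <- ps |>
    dplyr::transmute(
      .data$mirna_id, .data$mrna_id, .data$rho_status1, .data$rho_status2,
      expected_class = classify_pair(.data$rho_status1, .data$rho_status2,
                                     q1 = 0, q2 = 0,
                                     alpha = spec$alpha, fold = spec$fold))

  list(mirna = mirna, mrna = mrna, annotation = annotation,
       pairs = dplyr::select(ps, "mirna_id", "mrna_id", "healthy_sign"),
       truth = truth, feature = spec$feature_name, registry = spec$registry)
}

#' Write or read a simulation ground-truth table
#'
#' TSV with columns `mirna_id`, `mrna_id`, `rho_status1`, `rho_status2`,
#' `expected_class`; a read-back equals the written table.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param path Output path.
#' @return `path` invisibly (writer); the truth tibble (reader).
#' @export
write_truth_table <- function(truth, path) {
  need <- c("mirna_id", "mrna_id", "rho_status1", "rho_status2", "expected_class")
  if (!all(need %in% names(truth))) {
    abort("Truth table must have columns mirna_id, mrna_id, rho_status1, rho_status2, expected_class.",
          class = "mmpv_error_validation")
  }
  bad <- setdiff(truth$expected_class, c("sign_change", "fold_change", "none"))
  if (length(bad) > 0L) {
    abort(sprintf("Invalid expected_class '%s'.", bad[1L]),
          class = "mmpv_error_validation")
  }
  readr::write_tsv(dplyr::select(truth, dplyr::all_of(need)), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), mrna_id = readr::col_character(),
    rho_status1 = readr::col_double(), rho_status2 = readr::col_double(),
    expected_class = readr::col_character()), progress = FALSE)
}
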