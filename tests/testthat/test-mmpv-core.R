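test_that("pearson_r matches its definition and handles degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # hand evaluation: cov-sum 4, variance-sums 5 and 5 -> 4/5
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  # property: agrees with the brute-force formula on random inputs
  set.seed(401)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }

  # pairwise-complete filtering
  expect_equal(pearson_r(c(1, 2, 3, NA), c(2, 4, 6, 1)), 1.0)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "mmpv_error_constant_input")
  expect_error(pearson_r(c(1, NA, NA), c(2, 4, 6)),
               class = "mmpv_error_insufficient_data")
})

test_that("correlation p-values follow the exact t-test under normality", {
  expect_equal(correlation_p_value(0, 10), 1.0)
  expect_equal(correlation_p_value(1, 5), 0.0)
  expect_equal(correlation_p_value(-1, 5), 0.0)
  # r = 0.8, n = 4: t = 1.8856, df = 2; exact two-sided tail = 0.2
  expect_equal(correlation_p_value(0.8, 4), 0.2, tolerance = 1e-10)
  # cross-check against quadrature of the t density at another point
  r <- 0.5; n <- 12
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(correlation_p_value(r, n), 2 * oracle_t_tail(t_stat, n - 2),
               tolerance = 1e-8)
  expect_error(correlation_p_value(0.5, 2), class = "mmpv_error_insufficient_data")
})

test_that("BH adjustment equals the step-up oracle and keeps its invariants", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(402)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    # monotone: smaller p never gets a larger q
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mmpv_error_domain")
  expect_error(bh_adjust(numeric(0)), class = "mmpv_error_domain")
})

test_that("stratified correlations equal brute-force per-stratum values on the toy data", {
  toy <- toy_dataset()
  out <- stratified_pair_correlations(toy$pairs, toy$mirna, toy$mrna,
                                      toy$annotation, "ER")
  expect_equal(nrow(out), 2L)
  for (i in 1:2) {
    mi <- toy$mirna[toy$pairs$mirna_id[i], ]
    ge <- toy$mrna[toy$pairs$mrna_id[i], ]
    expect_equal(out$r1[i], oracle_pearson(mi[1:3], ge[1:3]), tolerance = 1e-12)
    expect_equal(out$r2[i], oracle_pearson(mi[4:6], ge[4:6]), tolerance = 1e-12)
  }
  expect_equal(out$q1, oracle_bh(out$p1), tolerance = 1e-12)

  # reordering sample columns (annotation unchanged) leaves the table identical
  shuffle <- c(4, 1, 6, 2, 5, 3)
  out2 <- stratified_pair_correlations(toy$pairs,
                                       toy$mirna[, shuffle], toy$mrna[, shuffle],
                                       toy$annotation, "ER")
  expect_equal(out, out2, ignore_attr = TRUE)
})

test_that("unresolvable, small, and degenerate pairs are dropped with counters", {
  toy <- toy_dataset()
  pairs <- dplyr::bind_rows(toy$pairs,
                            tibble::tibble(mirna_id = "hsa-miR-999",
                                           mrna_id = "CA3", healthy_sign = "D"))
  out <- stratified_pair_correlations(pairs, toy$mirna, toy$mrna,
                                      toy$annotation, "ER")
  expect_equal(attr(out, "dropped")[["unresolved_pairs"]], 1L)

  flat <- toy$mirna
  flat["hsa-miR-1", 1:3] <- 5  # constant in ER+
  expect_warning(
    out2 <- stratified_pair_correlations(toy$pairs, flat, toy$mrna,
                                         toy$annotation, "ER"),
    class = "mmpv_warning_degenerate")
  expect_equal(attr(out2, "dropped")[["degenerate_pairs"]], 1L)
  expect_equal(nrow(out2), 1L)

  expect_error(
    stratified_pair_correlations(toy$pairs, toy$mirna, toy$mrna,
                                 toy$annotation, "HER2"),
    class = "mmpv_error_config")
})

test_that("classify_pair implements the sign/fold/none decision rule", {
  expect_identical(classify_pair(0.5, -0.5, 0.01, 0.5), "sign_change")
  expect_identical(classify_pair(0.6, 0.2, 0.01, 0.6), "fold_change")
  expect_identical(classify_pair(0.5, 0.4, 0.01, 0.01), "none")
  # both insignificant -> removed regardless of the correlations
  expect_identical(classify_pair(0.9, -0.9, 0.2, 0.9), "none")
  # zero-r conventions
  expect_identical(classify_pair(0, 0.5, 0.01, 0.01), "fold_change")
  expect_identical(classify_pair(0, 0, 0.01, 0.01), "none")
  # negative same-sign ratio
  expect_identical(classify_pair(-0.6, -0.2, 0.01, 0.01), "fold_change")
  expect_error(classify_pair(0.5, 0.5, 0.1, 0.1, fold = 1), class = "mmpv_error_domain")
  expect_error(classify_pair(1.5, 0.5, 0.1, 0.1), class = "mmpv_error_domain")
})

test_that("classification is an exhaustive mutually exclusive partition on a grid", {
  grid <- expand.grid(r1 = seq(-0.9, 0.9, by = 0.1),
                      r2 = seq(-0.9, 0.9, by = 0.1),
                      q1 = c(0.001, 0.04, 0.05, 0.5),
                      q2 = c(0.001, 0.04, 0.05, 0.5))
  labels <- classify_pair(grid$r1, grid$r2, grid$q1, grid$q2)
  expect_true(all(labels %in% c("sign_change", "fold_change", "none")))
  expect_length(labels, nrow(grid))
  expect_false(anyNA(labels))
  both_insig <- grid$q1 >= 0.05 & grid$q2 >= 0.05
  expect_true(all(labels[both_insig] == "none"))
})

test_that("pattern encoding reproduces the worked examples and the grammar", {
  expect_identical(encode_pattern("D", r1 = 0.1, q1 = 0.3, r2 = 0.6, q2 = 0.001),
                   "D_U_U*")
  expect_identical(encode_pattern("D", r1 = 0.1, q1 = 0.3, r2 = -0.6, q2 = 0.001),
                   "D_U_D*")
  expect_identical(encode_pattern("U", r1 = 0.5, q1 = 0.01, r2 = 0.5, q2 = 0.01),
                   "U_U*_U*")
  expect_warning(tie <- encode_pattern("D", r1 = 0, q1 = 0.3, r2 = 0.6, q2 = 0.001),
                 class = "mmpv_warning_tie")
  expect_identical(tie, "D_U_U*")
  expect_error(encode_pattern("X", 0.5, 0.1, 0.5, 0.1), class = "mmpv_error_domain")

  set.seed(403)
  pats <- encode_pattern(sample(c("U", "D"), 200, TRUE),
                         r1 = runif(200, -1, 1), q1 = runif(200),
                         r2 = runif(200, -1, 1), q2 = runif(200))
  expect_true(all(grepl("^[UD]_[UD]\\*?_[UD]\\*?$", pats)))
})

test_that("detect_mmpvs returns only variant pairs with conserved counts", {
  # all pairs equal rho in both strata -> nothing reported
  specs <- dplyr::bind_rows(
    pair_spec("m1", "G1", rho_status1 = 0.5, rho_status2 = 0.5),
    pair_spec("m2", "G2", rho_status1 = -0.3, rho_status2 = -0.3))
  sim <- simulate_dataset(dataset_spec(specs, 40, 40, seed = 9))
  res <- detect_mmpvs(sim$pairs, sim$mirna, sim$mrna, sim$annotation, "ER")
  g <- glance(res)
  expect_true(g$n_total <= 1)  # sampling noise may promote at most the odd pair
  expect_equal(g$n_total, g$n_fold_change + g$n_sign_change)

  sim2 <- simulate_dataset(demo_dataset_spec(seed = 1, n = 50))
  res2 <- detect_mmpvs(sim2$pairs, sim2$mirna, sim2$mrna, sim2$annotation, "ER")
  g2 <- glance(res2)
  expect_equal(g2$n_total, g2$n_fold_change + g2$n_sign_change)
  tab <- tidy(res2)
  expect_true(all(tab$mmpv_class %in% c("sign_change", "fold_change")))
  # every reported pattern is grammatical and carries >= 1 asterisk
  expect_true(all(grepl("^[UD]_[UD]\\*?_[UD]\\*?$", tab$pattern)))
  expect_true(all(grepl("\\*", tab$pattern)))
  # the removal rule guarantees >= 1 significant stratum
  expect_true(all(tab$q1 < 0.05 | tab$q2 < 0.05))
})

test_that("swapping the registry status order swaps strata but not classes", {
  sim <- simulate_dataset(demo_dataset_spec(seed = 21, n = 40))
  fwd <- detect_mmpvs(sim$pairs, sim$mirna, sim$mrna, sim$annotation, "ER")
  swapped_registry <- feature_registry("ER", "ER-", "ER+")
  rev <- detect_mmpvs(sim$pairs, sim$mirna, sim$mrna, sim$annotation, "ER",
                      registry = swapped_registry)
  f <- dplyr::arrange(tidy(fwd), mirna_id)
  r <- dplyr::arrange(tidy(rev), mirna_id)
  expect_identical(f$mirna_id, r$mirna_id)
  expect_identical(f$mmpv_class, r$mmpv_class)
  expect_equal(f$r1, r$r2)
  expect_equal(f$r2, r$r1)
  # second and third pattern tokens swap
  tok <- function(p) do.call(rbind, strsplit(p, "_"))
  expect_identical(tok(f$pattern)[, 2:3], tok(r$pattern)[, 3:2])
})
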