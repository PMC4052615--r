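test_that("bivariate draws hit the requested correlation and are deterministic", {
  a <- sample_bivariate_pair(0.9, 1e4, seed = 11)
  b <- sample_bivariate_pair(0.9, 1e4, seed = 11)
  expect_identical(a, b)

  # Fisher-z interval for rho = 0.9 at n = 1e4
  expect_gt(cor(a$x, a$y), 0.88)
  expect_lt(cor(a$x, a$y), 0.92)

  # normal-theory bound under independence
  nullr <- sample_bivariate_pair(0, 1e4, seed = 12)
  expect_lt(abs(cor(nullr$x, nullr$y)), 0.05)

  expect_error(sample_bivariate_pair(1, 10), class = "mmpv_error_domain")
  expect_error(sample_bivariate_pair(0.5, 1), class = "mmpv_error_domain")
  expect_error(sample_bivariate_pair(0.5, 10, sd = 0), class = "mmpv_error_domain")
})

test_that("simulated datasets are reproducible and match their spec's marginals", {
  spec <- demo_dataset_spec(seed = 42, n = 200)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$mirna, s2$mirna)
  expect_identical(s1$mrna, s2$mrna)
  expect_identical(s1$annotation, s2$annotation)

  # per entity per stratum, sample mean within 4*sd/sqrt(n) of spec mean
  ps <- spec$pair_specs
  n <- spec$n_status1
  in1 <- s1$annotation$status == "ER+"
  for (i in seq_len(nrow(ps))) {
    tol <- 4 * ps$noise_sd[i] / sqrt(n)
    expect_lt(abs(mean(s1$mirna[i, in1]) - ps$delta_mirna[i] / 2), tol)
    expect_lt(abs(mean(s1$mirna[i, !in1]) + ps$delta_mirna[i] / 2), tol)
    expect_lt(abs(mean(s1$mrna[i, in1]) - ps$delta_mrna[i] / 2), tol)
    expect_lt(abs(mean(s1$mrna[i, !in1]) + ps$delta_mrna[i] / 2), tol)
  }
})

test_that("per-pair substreams make earlier pairs invariant to added pairs", {
  base <- dplyr::bind_rows(pair_spec("m1", "G1", rho_status1 = 0.7, rho_status2 = -0.7),
                           pair_spec("m2", "G2", rho_status1 = 0.2, rho_status2 = 0.2))
  extended <- dplyr::bind_rows(base, pair_spec("m3", "G3", rho_status1 = 0.5))
  a <- simulate_dataset(dataset_spec(base, 10, 10, seed = 5))
  b <- simulate_dataset(dataset_spec(extended, 10, 10, seed = 5))
  expect_identical(a$mirna, b$mirna[1:2, ])
  expect_identical(a$mrna, b$mrna[1:2, ])
})

test_that("truth labels follow the population classification rule", {
  specs <- dplyr::bind_rows(
    pair_spec("m1", "G1", rho_status1 = 0.7, rho_status2 = -0.7),
    pair_spec("m2", "G2", rho_status1 = 0.6, rho_status2 = 0.2),
    pair_spec("m3", "G3", rho_status1 = 0.5, rho_status2 = 0.5))
  sim <- simulate_dataset(dataset_spec(specs, 5, 5, seed = 1))
  expect_identical(sim$truth$expected_class,
                   c("sign_change", "fold_change", "none"))
  # shared code path with classify_pair at population level
  expect_identical(sim$truth$expected_class,
                   classify_pair(specs$rho_status1, specs$rho_status2, 0, 0))
})

test_that("duplicate entity ids in a spec are rejected", {
  dup <- dplyr::bind_rows(pair_spec("m1", "G1"), pair_spec("m1", "G2"))
  expect_error(dataset_spec(dup, 5, 5), class = "mmpv_error_spec")
})

test_that("truth tables round-trip through TSV and validate class strings", {
  sim <- simulate_dataset(demo_dataset_spec(seed = 3, n = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(sim$truth, path)
  expect_equal(read_truth_table(path), sim$truth)

  empty <- sim$truth[0, ]
  write_truth_table(empty, path)
  expect_identical(readLines(path),
                   "mirna_id\tmrna_id\trho_status1\trho_status2\texpected_class")

  bad <- dplyr::mutate(sim$truth, expected_class = "weird")
  expect_error(write_truth_table(bad, path), class = "mmpv_error_validation")
})
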