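test_that("the SAM d statistic matches the pooled-SE definition", {
  expect_equal(sam_d_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.5), 0)
  # antisymmetry
  g1 <- c(2.2, 3.1, 4.4); g2 <- c(0.5, 1.9, 1.1)
  expect_equal(sam_d_statistic(g1, g2, 0.2), -sam_d_statistic(g2, g1, 0.2))
  # hand/oracle evaluation: s = sqrt(((2+2)/4) * (2/3)) = sqrt(2/3)
  expect_equal(sam_d_statistic(c(3, 4, 5), c(1, 2, 3), s0 = 0.1),
               2 / (sqrt(2 / 3) + 0.1), tolerance = 1e-12)
  expect_equal(sam_d_statistic(c(3, 4, 5), c(1, 2, 3), s0 = 0.1), 2.1822230891,
               tolerance = 1e-8)

  set.seed(404)
  for (i in 1:30) {
    a <- rnorm(sample(2:20, 1)); b <- rnorm(sample(2:20, 1)); s0 <- runif(1, 0.01, 1)
    expect_equal(sam_d_statistic(a, b, s0), oracle_sam_d(a, b, s0),
                 tolerance = 1e-12)
  }
  expect_error(sam_d_statistic(1, c(1, 2), 0.1), class = "mmpv_error_insufficient_data")
  expect_error(sam_d_statistic(c(1, 2), c(1, 2), 0), class = "mmpv_error_domain")
})

test_that("s0 is the median standard error with a positive fallback", {
  expect_equal(choose_s0(c(1, 1, 1)), 1)
  expect_equal(choose_s0(c(1, 2, 9)), 2)
  expect_equal(choose_s0(c(0, 0, 3)), 3)
  expect_error(choose_s0(c(0, 0, 0)), class = "mmpv_error_degenerate")
  expect_error(choose_s0(numeric(0)), class = "mmpv_error_domain")
})

perm_fixture <- function(n_rows = 20, n_per = 8, seed = 500, shift_rows = 0,
                         delta = 0) {
  set.seed(seed)
  samples <- sprintf("s%d", seq_len(2 * n_per))
  mat <- matrix(rnorm(n_rows * 2 * n_per), n_rows,
                dimnames = list(sprintf("e%d", seq_len(n_rows)), samples))
  if (shift_rows > 0) mat[seq_len(shift_rows), seq_len(n_per)] <-
      mat[seq_len(shift_rows), seq_len(n_per)] + delta
  ann <- tibble::tibble(sample_id = samples, feature = "ER",
                        status = rep(c("ER+", "ER-"), each = n_per))
  list(mat = mat, ann = ann)
}

test_that("permutation p-values are floored, deterministic, and order-invariant", {
  fx <- perm_fixture()
  # a row identical across all samples gives |d| = 0 under every labelling
  fx$mat[1, ] <- 3
  p <- permutation_p_values(fx$mat, fx$ann, "ER", n_perm = 50, seed = 2)
  expect_equal(p$p_perm[1], 1)
  expect_true(all(p$p_perm >= 1 / 51))
  expect_identical(p, permutation_p_values(fx$mat, fx$ann, "ER",
                                           n_perm = 50, seed = 2))

  # shuffling samples inside each stratum changes nothing
  shuffle <- c(sample(1:8), sample(9:16))
  p2 <- permutation_p_values(fx$mat[, shuffle],
                             fx$ann[match(colnames(fx$mat)[shuffle], fx$ann$sample_id), ],
                             "ER", n_perm = 50, seed = 2)
  expect_equal(p$p_perm, p2$p_perm)
  expect_error(permutation_p_values(fx$mat[, 1:9], fx$ann[1:9, ], "ER"),
               class = "mmpv_error_config")
})

test_that("differential tables carry BH q-values and a registry-driven direction", {
  fx <- perm_fixture(n_rows = 1, seed = 501)
  one <- differential_table(fx$mat, fx$ann, "ER", n_perm = 30, seed = 3)
  expect_equal(one$q, one$p_perm)  # m = 1 identity

  fx2 <- perm_fixture(n_rows = 10, seed = 502, shift_rows = 2, delta = 3)
  fwd <- differential_table(fx2$mat, fx2$ann, "ER", n_perm = 50, seed = 3)
  rev <- differential_table(fx2$mat, fx2$ann, "ER", n_perm = 50, seed = 3,
                            registry = feature_registry("ER", "ER-", "ER+"))
  expect_identical(fwd$direction,
                   ifelse(rev$direction == "U", "D", "U"))
  expect_equal(fwd$q, oracle_bh(fwd$p_perm), tolerance = 1e-12)
})

test_that("DE-MMPV selection requires both members significant", {
  mmpvs <- tibble::tibble(mirna_id = c("m1", "m2"), mrna_id = c("G1", "G2"),
                          healthy_sign = "D", mmpv_class = "sign_change",
                          pattern = "D_U_D*", feature = "ER")
  mi <- tibble::tibble(entity_id = c("m1", "m2"), d = c(3, 3),
                       p_perm = 0.01, q = c(0.01, 0.01), direction = "U")
  ge <- tibble::tibble(entity_id = c("G1", "G2"), d = c(-2, -2),
                       p_perm = 0.01, q = c(0.2, 0.01), direction = "D")
  out <- select_de_mmpvs(mmpvs, mi, ge)
  expect_equal(out$mirna_id, "m2")
  expect_identical(out$label, "m2(U) G2(D) D_U_D*")

  expect_equal(nrow(select_de_mmpvs(mmpvs[0, ], mi, ge)), 0L)
  expect_error(select_de_mmpvs(mmpvs, mi[1, ], ge),
               class = "mmpv_error_consistency")
})

test_that("planted mean shifts are recovered and nulls stay controlled", {
  fx <- perm_fixture(n_rows = 120, n_per = 30, seed = 503,
                     shift_rows = 20, delta = 2)
  tab <- differential_table(fx$mat, fx$ann, "ER", n_perm = 200, seed = 7)
  planted <- tab$q[1:20] < 0.05
  expect_gte(mean(planted), 0.9)
  null_fp <- mean(tab$p_perm[21:120] < 0.05)
  expect_lte(null_fp, 0.05 + 0.05)
  expect_true(all(tab$direction[1:20][planted] == "U"))
})
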