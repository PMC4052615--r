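# Independent brute-force oracles. These deliberately avoid the package's
# own code paths and the library calls standing behind them (cor, p.adjust,
# phyper, igraph::degree), so that oracle-equivalence tests are two-route.

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# BH step-up: q(i) = min_{j >= i} p_(j) * m / j, returned in input order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    q[i] <- running
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

oracle_sam_d <- function(g1, g2, s0) {
  n1 <- length(g1)
  n2 <- length(g2)
  ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  s <- sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  (mean(g1) - mean(g2)) / (s + s0)
}

# P(X >= k) by explicit summation of the hypergeometric pmf
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# degree by manual neighbour counting on an edge matrix (2 columns),
# distinct neighbours, self-loop adds 1
oracle_degrees <- function(edges) {
  nodes <- sort(unique(c(edges)))
  vapply(nodes, function(v) {
    nb <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
    length(setdiff(nb, v)) + as.integer(v %in% nb)
  }, integer(1))
}

# numeric t-distribution tail by quadrature, independent of stats::pt
oracle_t_tail <- function(t, df) {
  stats::integrate(function(u) (1 + u^2 / df)^(-(df + 1) / 2), t, Inf,
                   rel.tol = 1e-10)$value /
    stats::integrate(function(u) (1 + u^2 / df)^(-(df + 1) / 2), -Inf, Inf,
                     rel.tol = 1e-10)$value
}
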