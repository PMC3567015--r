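# Monte-Carlo checks against closed-form coalescent expectations, plus
# structural invariants of the genealogy and mutation machinery.

# earliest node (backward time) whose descendant tips span both
# populations; Inf if none
cross_coal_time <- function(g) {
  n <- g$n_tip
  nnode <- 2 * n - 1
  desc <- vector("list", nnode)
  for (v in 1:n) desc[[v]] <- g$tip_pop[v]
  ord <- order(g$node_time)  # children always precede parents in time
  for (v in ord) {
    p <- g$parent[v] + 1
    if (g$parent[v] >= 0)
      desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  times <- g$node_time[(n + 1):nnode]
  spans <- vapply((n + 1):nnode,
                  function(v) length(unique(desc[[v]])) > 1, TRUE)
  if (!any(spans)) Inf else min(times[spans])
}

test_that("pairwise TMRCA matches the closed form E[T2] = theta/theta_ref", {
  set.seed(101)
  p <- pair_model_params(theta_1 = 0.01, theta_A = 0.005, tau = 100,
                         n1 = 2, n2 = 0, L = 100)
  tm <- replicate(20000, simulate_genealogy(p, theta_ref = 0.005)$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2), 3 * se)  # theta_1/theta_ref = 2
})

test_that("expected pairwise diversity equals theta in the panmictic limit", {
  set.seed(102)
  p <- pair_model_params(theta_1 = 0.01, theta_A = 0.01, tau = 100,
                         n1 = 2, n2 = 0, L = 1000)
  pis <- replicate(20000, simulate_pair_stats(p, theta_ref = 0.005)[["pi_1"]])
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 0.01), 3 * se)
})

test_that("tau = 0 with equal thetas leaves populations exchangeable", {
  set.seed(103)
  p <- pair_model_params(theta_1 = 0.004, theta_2 = 0.004,
                         theta_A = 0.004, tau = 0, n1 = 4, n2 = 4, L = 600)
  nets <- replicate(5000, simulate_pair_stats(p, theta_ref = 0.005)[["pi_net"]])
  se <- sd(nets) / sqrt(length(nets))
  expect_lt(abs(mean(nets)), 3 * se)
})

test_that("without migration no cross-population coalescence predates tau", {
  set.seed(104)
  p <- pair_model_params(theta_1 = 0.005, theta_2 = 0.005,
                         theta_A = 0.005, tau = 5, n1 = 3, n2 = 3, L = 100)
  for (i in 1:200) {
    g <- simulate_genealogy(p, theta_ref = 0.005)
    expect_gt(cross_coal_time(g), 5)
  }
})

test_that("migration events do allow pre-tau cross-population coalescence", {
  set.seed(105)
  p <- pair_model_params(theta_1 = 0.005, theta_2 = 0.005,
                         theta_A = 0.005, tau = 50, m_1 = 5, m_2 = 5,
                         n1 = 3, n2 = 3, L = 100)
  crossed <- replicate(200, {
    g <- simulate_genealogy(p, theta_ref = 0.005)
    cross_coal_time(g) < 50
  })
  expect_gt(mean(crossed), 0.5)
})

test_that("doubling the locus rate multiplier doubles expected segregating sites", {
  set.seed(106)
  base <- function(mult) {
    p <- pair_model_params(theta_1 = 0.002, theta_A = 0.002, tau = 100,
                           n1 = 6, n2 = 0, L = 1000,
                           rate_multiplier = mult)
    replicate(5000, simulate_pair_stats(p, theta_ref = 0.005)[["theta_w_1"]])
  }
  s1 <- base(1); s2 <- base(2)
  ratio <- mean(s2) / mean(s1)
  se <- ratio * sqrt((sd(s1) / mean(s1))^2 + (sd(s2) / mean(s2))^2) /
    sqrt(5000)
  expect_lt(abs(ratio - 2), max(4 * se, 0.05))
})

test_that("migration homogenises net divergence at fixed tau", {
  set.seed(107)
  mean_net <- function(m) {
    p <- pair_model_params(theta_1 = 0.002, theta_A = 0.001, tau = 1,
                           m_1 = m, m_2 = m, n1 = 4, n2 = 4, L = 600,
                           rate_multiplier = 20)
    x <- replicate(10000, simulate_pair_stats(p, theta_ref = 0.005)[["pi_net"]])
    c(mean(x), sd(x) / sqrt(length(x)))
  }
  r0 <- mean_net(0); r1 <- mean_net(0.5); r2 <- mean_net(2)
  expect_lt(r1[1], r0[1] + 2 * (r0[2] + r1[2]))
  expect_lt(r2[1], r1[1] + 2 * (r1[2] + r2[2]))
  expect_lt(r2[1], r0[1])  # strong migration clearly erodes divergence
})

test_that("identical seeds reproduce genealogies, alignments and statistics", {
  p <- pair_model_params(theta_1 = 0.004, theta_A = 0.002, tau = 1.5,
                         n1 = 5, n2 = 5, L = 400, rate_multiplier = 20)
  run <- function() {
    set.seed(2024)
    g <- simulate_genealogy(p, theta_ref = 0.005)
    a <- sprinkle_mutations(g, p)
    set.seed(77)
    s <- simulate_pair_stats(p, theta_ref = 0.005)
    list(g = g, a = a, s = s)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$a, r2$a)
  expect_identical(r1$g$node_time, r2$g$node_time)
  expect_identical(r1$s, r2$s)
})

test_that("the fused statistic path agrees with the R statistics on alignments", {
  set.seed(108)
  for (i in 1:15) {
    p <- pair_model_params(theta_1 = runif(1, 0.001, 0.008),
                           theta_A = 0.002, tau = runif(1, 0, 2),
                           n1 = sample(2:6, 1), n2 = sample(2:6, 1),
                           L = 300, rate_multiplier = sample(c(1, 20), 1))
    g <- simulate_genealogy(p, theta_ref = 0.005)
    aln <- sprinkle_mutations(g, p)
    codes <- attr(aln, "codes")
    pops <- attr(aln, "tip_pop")
    cpp <- codiverge:::cpp_aln_stats(codes, sum(pops == 1), sum(pops == 2))
    names(cpp) <- codiverge:::STAT_NAMES
    for (side in 1:2) {
      nn <- sum(pops == side)
      nm <- paste0("tajd_", side)
      if (nn >= 3 && is.na(cpp[[nm]])) cpp[[nm]] <- 0
    }
    rvec <- pair_summary_vector(make_pair(aln[pops == 1, , drop = FALSE],
                                          aln[pops == 2, , drop = FALSE]))
    expect_equal(unname(cpp), unname(rvec), tolerance = 1e-12)
  }
})

test_that("genealogies convert to valid ultrametric ape trees", {
  set.seed(109)
  p <- pair_model_params(theta_1 = 0.005, theta_A = 0.0025, tau = 1,
                         n1 = 4, n2 = 3, L = 100)
  g <- simulate_genealogy(p, theta_ref = 0.005)
  tr <- genealogy_to_phylo(g)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 7)
  expect_true(all(tr$edge.length >= 0))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  depth <- max(ape::node.depth.edgelength(tr))
  expect_equal(depth, g$tmrca, tolerance = 1e-10)
})
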