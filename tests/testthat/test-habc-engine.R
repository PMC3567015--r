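# Hyperprior draws, rejection machinery, regression adjustment and
# posterior summaries.

small_meta <- function(Y = 3, n = 6, L = 300, mult = 20) {
  data.frame(pair_id = sprintf("m%02d", seq_len(Y)), n1 = n, n2 = n,
             L = L, rate_multiplier = mult, stringsAsFactors = FALSE)
}

test_that("the dispersion index Omega matches hand arithmetic", {
  expect_equal(omega(c(1, 1, 1)), 0)
  expect_equal(omega(c(0, 2)), 1)       # population variance 1, mean 1
  expect_equal(omega(c(2, 2, 8, 8)), 1.8)  # Var = 9, E = 5
  expect_equal(omega(c(0, 0, 0)), 0)    # simultaneous at time zero
  expect_equal(omega(c(0, 2), variance = "sample"), 2)
  # scale covariance: multiplying times by c multiplies Omega by c
  set.seed(21)
  for (i in 1:20) {
    tau <- runif(sample(2:10, 1), 0, 3)
    cc <- runif(1, 0.1, 5)
    expect_equal(omega(cc * tau), cc * omega(tau))
  }
})

test_that("hyperprior draws have the intended structure", {
  meta <- small_meta(Y = 4)
  prior1 <- hyper_prior(Y = 4, psi_max = 1, theta_max = 0.01, n_sims = 100,
                        n_accept = 10)
  set.seed(31)
  for (i in 1:20) {
    d <- draw_hyper(prior1, meta)
    expect_equal(d$psi, 1)
    expect_equal(length(unique(vapply(d$pair_params, `[[`, 0, "tau"))), 1L)
    expect_equal(omega(vapply(d$pair_params, `[[`, 0, "tau")), 0)
  }
  # psi uniform on 1..psi_max (chi-square at alpha = 0.01)
  prior4 <- hyper_prior(Y = 4, theta_max = 0.01, n_sims = 100, n_accept = 10)
  set.seed(32)
  draws <- codiverge:::.draw_hyper_matrix(prior4, meta, 10000)
  expect_gt(chisq.test(table(factor(draws$psi, levels = 1:4)))$p.value, 0.01)
  # every pair's tau equals the class time it was assigned
  idx <- cbind(seq_len(10000), draws$assignment[, 2])
  expect_identical(draws$tau_pair[, 2], draws$tau_values[idx])
  # under independent-uniform assignment,
  # P(both pairs share a class | psi = 2) = 1/2
  meta2 <- small_meta(Y = 2)
  prior2 <- hyper_prior(Y = 2, theta_max = 0.01, n_sims = 100,
                        n_accept = 10, assignment = "uniform")
  set.seed(33)
  d2 <- codiverge:::.draw_hyper_matrix(prior2, meta2, 20000)
  sel <- d2$psi == 2
  p_same <- mean(d2$assignment[sel, 1] == d2$assignment[sel, 2])
  expect_lt(abs(p_same - 0.5), 3 * sqrt(0.25 / sum(sel)))
})

test_that("constrained assignment draws uniform surjections", {
  meta <- small_meta(Y = 3)
  prior <- hyper_prior(Y = 3, theta_max = 0.01, n_sims = 100, n_accept = 10)
  set.seed(34)
  d <- codiverge:::.draw_hyper_matrix(prior, meta, 12000)
  # every pulse drawn is realised
  realized <- vapply(seq_len(nrow(d$assignment)),
                     function(i) length(unique(d$assignment[i, ])), 0L)
  expect_identical(realized, d$psi)
  # psi = 2, Y = 3: uniform over the 6 surjections onto two classes
  sel <- which(d$psi == 2L)
  key <- apply(d$assignment[sel, ], 1L, paste, collapse = "")
  expect_equal(length(unique(key)), 6L)
  expect_gt(chisq.test(table(key))$p.value, 0.01)
  # psi = 3, Y = 3: assignments are the 6 permutations, uniformly
  sel3 <- which(d$psi == 3L)
  key3 <- apply(d$assignment[sel3, ], 1L, paste, collapse = "")
  expect_equal(length(unique(key3)), 6L)
  expect_gt(chisq.test(table(key3))$p.value, 0.01)
})

test_that("rejection keeps the closest rows deterministically", {
  meta <- small_meta(Y = 2, n = 5, L = 200)
  prior <- hyper_prior(Y = 2, theta_max = 0.01, n_sims = 600, n_accept = 50)
  set.seed(41)
  tab <- run_simulations(prior, meta, n_sims = 600)
  stat_cols <- attr(tab, "stat_cols")
  # observed = one simulated row: it is accepted at distance zero
  obs <- unlist(tab[137, stat_cols])
  acc <- abc_reject(obs, tab, 50)
  expect_equal(min(acc$.dist), 0)
  expect_equal(acc$psi[which.min(acc$.dist)], tab$psi[137])
  # n_accept = n_sims is the identity (posterior = prior)
  acc_all <- abc_reject(obs, tab, nrow(tab))
  expect_equal(sort(acc_all$omega), sort(tab$omega))
  # threshold property: worst accepted <= best rejected
  expect_equal(nrow(acc), 50)
  rejected_best <- sort(abc_reject(obs, tab, nrow(tab))$.dist)[51]
  expect_lte(max(acc$.dist), rejected_best)
})

test_that("zero-variance statistic columns are excluded with a warning", {
  meta <- small_meta(Y = 2, n = 5, L = 200)
  prior <- hyper_prior(Y = 2, theta_max = 0.01, n_sims = 200, n_accept = 20)
  set.seed(42)
  tab <- run_simulations(prior, meta, n_sims = 200)
  cols <- attr(tab, "stat_cols")
  tab[[cols[1]]] <- 1  # degenerate column
  obs <- unlist(tab[7, cols])
  expect_warning(acc <- abc_reject(obs, tab, 20), "zero-variance")
  expect_false(cols[1] %in% attr(acc, "cols_used"))
})

test_that("regression adjustment collapses a perfectly linear relation and is inert otherwise", {
  set.seed(51)
  n <- 400
  s <- rnorm(n)
  tab <- data.frame(psi = sample(1:2, n, TRUE), psi_realized = 1L,
                    e_tau = 1.5 + 0.8 * s, var_tau = 0,
                    omega = pmax(0.5 + 0.2 * s, 0))
  tab$stat <- s
  attr(tab, "stat_cols") <- "stat"
  attr(tab, "prior") <- hyper_prior(Y = 2, theta_max = 0.01, tau_max = 3,
                                    n_sims = 1000, n_accept = 10)
  class(tab) <- c("sim_table", "data.frame")
  obs <- c(stat = 0.3)
  acc <- abc_reject(obs, tab, 100)
  adj <- regression_adjust(acc)
  # e_tau is exactly linear in the statistic: all draws collapse to the
  # value at the observed point
  expect_equal(adj$e_tau_adj, rep(1.5 + 0.8 * 0.3, 100), tolerance = 1e-8)
  expect_true(all(adj$omega_adj >= 0))
  # uncorrelated parameter: slope ~ 0, adjustment changes nothing
  set.seed(52)
  tab2 <- tab
  tab2$e_tau <- rep(2, n)  # constant: zero slope exactly
  class(tab2) <- c("sim_table", "data.frame")
  attr(tab2, "stat_cols") <- "stat"
  attr(tab2, "prior") <- attr(tab, "prior")
  acc2 <- abc_reject(obs, tab2, 100)
  adj2 <- regression_adjust(acc2)
  expect_equal(adj2$e_tau_adj, acc2$e_tau, tolerance = 1e-10)
})

test_that("posterior summaries match hand-computed cases and a KDE oracle", {
  acc <- data.frame(psi = c(1L, 1L, 1L, 2L), psi_realized = 1L,
                    e_tau = c(1, 1, 1, 1), var_tau = 0,
                    omega = rep(0.4, 4), .dist = 1:4)
  attr(acc, "prior") <- list(psi_max = 3L, tau_max = 3)
  class(acc) <- c("abc_accepted", "data.frame")
  ps <- summarize_posterior(acc)
  expect_equal(ps$psi_mode, 1L)
  expect_equal(ps$psi_mean, 1.25)
  expect_equal(ps$omega_mode, 0.4)
  expect_equal(ps$omega_mean, 0.4)
  expect_equal(ps$omega_q025, 0.4)
  expect_equal(ps$omega_q975, 0.4)
  # KDE mode of a unimodal sample sits near its peak (within a bandwidth)
  set.seed(61)
  x <- rnorm(2000, mean = 1.7, sd = 0.3)
  m <- codiverge:::.kde_mode(x)
  expect_lt(abs(m - 1.7), stats::bw.nrd0(x) + 3 * 0.3 / sqrt(2000))
})

test_that("effective migrant conversion follows the 2Nm convention", {
  expect_equal(effective_migrants(0, 1.3), 0)
  expect_equal(effective_migrants(0.5, 2), 0.5)
  expect_equal(effective_migrants(0.5, 4), 2 * effective_migrants(0.5, 2))
})

test_that("with every simulation accepted the psi posterior reproduces the prior", {
  meta <- small_meta(Y = 3, n = 6, L = 200)
  prior <- hyper_prior(Y = 3, theta_max = 0.01, n_sims = 5000,
                       n_accept = 4999)
  set.seed(71)
  tab <- run_simulations(prior, meta, n_sims = 5000)
  obs <- unlist(tab[sample(nrow(tab), 1), attr(tab, "stat_cols")])
  acc <- abc_reject(obs, tab, nrow(tab))
  ps <- summarize_posterior(acc)
  expect_gt(chisq.test(table(factor(acc$psi, levels = 1:3)))$p.value, 0.01)
  expect_lt(abs(ps$psi_mean - 2), 0.1)
})

test_that("the end-to-end test is deterministic given a seed", {
  gs <- generate_study(tiny_truth(seed = 5))
  prior <- hyper_prior(Y = 2, theta_max = 0.01, n_sims = 1500,
                       n_accept = 60)
  f1 <- test_codivergence(gs$study, prior, seed = 99)
  f2 <- test_codivergence(gs$study, prior, seed = 99)
  expect_identical(f1$posterior$omega_mode, f2$posterior$omega_mode)
  expect_identical(f1$accepted$.dist, f2$accepted$.dist)
  expect_identical(f1$sim_table$omega, f2$sim_table$omega)
})
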