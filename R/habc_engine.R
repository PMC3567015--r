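# Hierarchical ABC over taxon pairs: hyperparameters (number of
# divergence pulses Psi, their times tau) sit above per-pair demographic
# sub-parameters (theta, migration) that are integrated out by
# simulation.

#' Hyperprior for the co-divergence test
#'
#' @param Y number of taxon pairs in the barrier set.
#' @param psi_max maximum number of divergence pulses; set equal to the
#'   number of lineage pairs, as in the study design this package
#'   implements.
#' @param tau_max upper bound of the uniform prior on divergence times
#'   (coalescent units; default 3).
#' @param theta_max upper bound of the uniform prior on per-pair theta;
#'   the default 0.15816 is an mtDNA-scale value. It also fixes the time
#'   unit through `theta_ref = theta_max / 2`.
#' @param theta_min lower bound of the theta prior (default 1e-4).
#' @param theta_anc_ratio ancestral theta as a fraction of the pair's
#'   drawn theta (default 0.5).
#' @param mig_mean mean scaled migration rate for the barrier (e.g. an
#'   IMa posterior-mean summary); `m_1` and `m_2` are each drawn
#'   `U(0, 2 * mig_mean)` so the prior mean matches. 0 disables
#'   migration.
#' @param n_sims simulated datasets in the reference table (study-scale
#'   value 1e6).
#' @param n_accept retained draws (study-scale value 2000).
#' @param kappa HKY transition/transversion parameter (default 4).
#' @param assignment how pairs are mapped to divergence pulses:
#'   `"constrained"` (default) draws a uniformly random surjection, so a
#'   draw with psi pulses realises exactly psi distinct times and psi is
#'   the number of divergence times actually present; `"uniform"`
#'   assigns each pair to one of the psi pulses independently, which
#'   can leave pulses unused (the realised count is then recorded per
#'   draw as `psi_realized`).
#' @return object of class `hyper_prior` (includes the derived
#'   `theta_ref`).
#' @export
hyper_prior <- function(Y, psi_max = Y, tau_max = 3, theta_max = 0.15816,
                        theta_min = 1e-4, theta_anc_ratio = 0.5,
                        mig_mean = 0, n_sims = 1e6, n_accept = 2000,
                        kappa = 4,
                        assignment = c("constrained", "uniform")) {
  assignment <- match.arg(assignment)
  stopifnot(Y >= 1, psi_max >= 1, psi_max <= Y, tau_max > 0,
            theta_max > 0, theta_min > 0, theta_min < theta_max,
            theta_anc_ratio > 0, mig_mean >= 0, n_accept < n_sims,
            kappa > 0)
  structure(list(Y = as.integer(Y), psi_max = as.integer(psi_max),
                 tau_max = tau_max, theta_max = theta_max,
                 theta_min = theta_min, theta_anc_ratio = theta_anc_ratio,
                 mig_mean = mig_mean, n_sims = as.integer(n_sims),
                 n_accept = as.integer(n_accept), kappa = kappa,
                 assignment = assignment,
                 theta_ref = theta_max / 2),
            class = "hyper_prior")
}

#' @export
print.hyper_prior <- function(x, ...) {
  cat("<hyper_prior> Y =", x$Y, " psi_max =", x$psi_max,
      " tau ~ U(0,", x$tau_max, ")  theta ~ U(", x$theta_min, ",",
      x$theta_max, ")  theta_ref =", x$theta_ref,
      "\n  mig_mean =", x$mig_mean, " n_sims =", x$n_sims,
      " n_accept =", x$n_accept, "\n")
  invisible(x)
}

#' Dispersion index of divergence times
#'
#' `Omega = Var(tau) / E(tau)` across the taxon pairs of a barrier set:
#' 0 under strictly simultaneous divergence, growing with temporal
#' discordance. The population variance (divide by Y) is the default; if
#' every time is 0 the index is defined as 0 (simultaneous at time
#' zero).
#'
#' @param tau_per_pair numeric vector of per-pair divergence times.
#' @param variance `"population"` (default) or `"sample"`.
#' @return Omega (scalar).
#' @export
omega <- function(tau_per_pair, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  stopifnot(length(tau_per_pair) >= 1, all(tau_per_pair >= 0))
  e <- mean(tau_per_pair)
  if (e == 0) return(0)
  v <- if (variance == "population") {
    mean(tau_per_pair^2) - e^2
  } else {
    var(tau_per_pair)
  }
  v / e
}

# number of ways to assign r labelled pairs to k classes such that e
# designated currently-empty classes all end up occupied
.surj_count <- function(r, e, k) {
  j <- 0:e
  sum((-1)^j * choose(e, j) * (k - j)^r)
}

# uniformly random surjections of Y pairs onto psi classes, drawn
# sequentially with occupancy-conditional probabilities (vectorised over
# draws sharing one psi value)
.sample_surjections <- function(n, psi, Y) {
  out <- matrix(0L, n, Y)
  occupied <- matrix(FALSE, n, psi)
  e <- rep(psi, n)
  for (j in seq_len(Y)) {
    r_after <- Y - j
    # weight of landing in one empty class vs one occupied class
    w_emp <- vapply(e, function(ei)
      if (ei > 0) .surj_count(r_after, ei - 1L, psi) else 0, 0)
    w_occ <- vapply(e, function(ei) .surj_count(r_after, ei, psi), 0)
    p_empty <- ifelse(e > 0, e * w_emp / (e * w_emp + (psi - e) * w_occ), 0)
    take_empty <- runif(n) < p_empty
    u <- runif(n)
    for (i in seq_len(n)) {
      pool <- if (take_empty[i]) which(!occupied[i, ]) else
        which(occupied[i, ])
      cls <- pool[1L + floor(u[i] * length(pool))]
      out[i, j] <- cls
      if (!occupied[i, cls]) {
        occupied[i, cls] <- TRUE
        e[i] <- e[i] - 1L
      }
    }
  }
  out
}

# vectorised hyperprior draws: one row per simulated dataset
.draw_hyper_matrix <- function(prior, meta, n) {
  Y <- nrow(meta)
  stopifnot(Y == prior$Y)
  psi <- sample.int(prior$psi_max, n, replace = TRUE)
  tau_values <- matrix(runif(n * prior$psi_max, 0, prior$tau_max),
                       nrow = n)
  assignment <- matrix(0L, n, Y)
  if (identical(prior$assignment %||% "constrained", "uniform")) {
    for (j in seq_len(Y))
      assignment[, j] <- as.integer(ceiling(runif(n) * psi))
  } else {
    for (k in sort(unique(psi))) {
      rows <- which(psi == k)
      assignment[rows, ] <- .sample_surjections(length(rows), k, Y)
    }
  }
  tau_pair <- matrix(0, n, Y)
  for (j in seq_len(Y))
    tau_pair[, j] <- tau_values[cbind(seq_len(n), assignment[, j])]
  theta <- matrix(runif(n * Y, prior$theta_min, prior$theta_max), n, Y)
  m1 <- matrix(runif(n * Y, 0, 2 * prior$mig_mean), n, Y)
  m2 <- matrix(runif(n * Y, 0, 2 * prior$mig_mean), n, Y)
  list(psi = psi, tau_values = tau_values, assignment = assignment,
       tau_pair = tau_pair, theta = theta, m1 = m1, m2 = m2)
}

#' Draw one set of hyperparameters and pair sub-parameters
#'
#' `psi` is discrete-uniform on `1..psi_max`; `psi` pulse times are
#' iid `U(0, tau_max)`; pairs are mapped to pulses according to the
#' prior's `assignment` scheme — a uniformly random surjection by
#' default, so every drawn pulse is realised and `psi_realized == psi`,
#' or independent uniform assignment (`"uniform"`), which can leave
#' pulses unused. Per-pair theta is uniform on the prior range with
#' ancestral theta a fixed ratio, and migration rates are uniform with
#' mean `mig_mean`.
#'
#' @param prior a [hyper_prior()] object.
#' @param meta pair metadata ([pair_meta()]).
#' @return object of class `hyper_draw`: `psi`, `tau_values`,
#'   `assignment`, `psi_realized`, and `pair_params` (a list of
#'   [pair_model_params()]).
#' @export
draw_hyper <- function(prior, meta) {
  d <- .draw_hyper_matrix(prior, meta, 1L)
  Y <- nrow(meta)
  pair_params <- lapply(seq_len(Y), function(j) {
    pair_model_params(theta_1 = d$theta[1, j], theta_2 = d$theta[1, j],
                      theta_A = prior$theta_anc_ratio * d$theta[1, j],
                      tau = d$tau_pair[1, j],
                      m_1 = d$m1[1, j], m_2 = d$m2[1, j],
                      n1 = meta$n1[j], n2 = meta$n2[j], L = meta$L[j],
                      rate_multiplier = meta$rate_multiplier[j],
                      kappa = prior$kappa)
  })
  names(pair_params) <- meta$pair_id
  structure(list(psi = d$psi[1],
                 tau_values = d$tau_values[1, seq_len(d$psi[1])],
                 assignment = structure(d$assignment[1, ],
                                        names = meta$pair_id),
                 psi_realized = length(unique(d$assignment[1, ])),
                 pair_params = pair_params),
            class = "hyper_draw")
}

.stat_col_names <- function(meta) {
  as.vector(t(outer(meta$pair_id, STAT_NAMES, paste, sep = ".")))
}

.hyper_col_names <- function() {
  c(paste0("mean_", STAT_NAMES), paste0("var_", STAT_NAMES))
}

# rowwise across-pair means and population variances of each statistic
.hyper_summarise_matrix <- function(stats, Y) {
  n <- nrow(stats)
  out <- matrix(NA_real_, n, 16L,
                dimnames = list(NULL, .hyper_col_names()))
  for (s in seq_along(STAT_NAMES)) {
    cols <- seq.int(s, by = 8L, length.out = Y)
    x <- stats[, cols, drop = FALSE]
    k <- rowSums(!is.na(x))
    sx <- rowSums(x, na.rm = TRUE)
    sx2 <- rowSums(x^2, na.rm = TRUE)
    mu <- ifelse(k > 0, sx / k, NA_real_)
    vv <- ifelse(k > 0, pmax(sx2 / k - mu^2, 0), NA_real_)
    out[, s] <- mu
    out[, 8L + s] <- vv
  }
  out
}

#' Observed summary-statistic vector for a study
#'
#' Concatenates every pair's [pair_summary_vector()] (columns named
#' `<pair_id>.<stat>`, pairs in study order) with the across-pair
#' hyper-summaries of [hyper_summary()]. The layout is identical to the
#' statistic columns of the simulated reference table.
#'
#' @param study list of [taxon_pair_data()] objects.
#' @return named numeric vector.
#' @export
observed_summary <- function(study) {
  meta <- pair_meta(study)
  per_pair <- t(vapply(study, pair_summary_vector, numeric(8)))
  obs <- as.vector(t(per_pair))
  names(obs) <- .stat_col_names(meta)
  hyper <- .hyper_summarise_matrix(matrix(obs, nrow = 1L), nrow(meta))[1, ]
  c(obs, hyper)
}

#' Build the simulated reference table
#'
#' Draws `n_sims` hyperparameter sets, simulates every taxon pair under
#' the IM coalescent at each draw, and records the condensed
#' hyperparameters (`psi`, realised psi, `e_tau`, `var_tau`, `omega`)
#' next to the full summary-statistic vector.
#'
#' @param prior a [hyper_prior()] object.
#' @param meta pair metadata ([pair_meta()]).
#' @param n_sims number of rows (defaults to `prior$n_sims`).
#' @param max_events per-genealogy event cap.
#' @return data.frame of class `sim_table`; statistic column names are in
#'   `attr(, "stat_cols")`, the prior echo in `attr(, "prior")`.
#' @export
run_simulations <- function(prior, meta, n_sims = prior$n_sims,
                            max_events = 1e7) {
  stopifnot(inherits(prior, "hyper_prior"))
  n_sims <- as.integer(n_sims)
  Y <- nrow(meta)
  d <- .draw_hyper_matrix(prior, meta, n_sims)
  par <- matrix(0, n_sims, 6L * Y)
  for (j in seq_len(Y)) {
    o <- 6L * (j - 1L)
    par[, o + 1L] <- d$theta[, j]
    par[, o + 2L] <- d$theta[, j]
    par[, o + 3L] <- prior$theta_anc_ratio * d$theta[, j]
    par[, o + 4L] <- d$tau_pair[, j]
    par[, o + 5L] <- d$m1[, j]
    par[, o + 6L] <- d$m2[, j]
  }
  stats <- cpp_study_stats(par, meta$n1, meta$n2, meta$L,
                           meta$rate_multiplier, prior$theta_ref,
                           prior$kappa, max_events)
  colnames(stats) <- .stat_col_names(meta)
  # Tajima's D defined (n >= 3) but S = 0 -> encode 0, as in the
  # observed vectors
  for (j in seq_len(Y)) {
    if (meta$n1[j] >= 3L) {
      cn <- paste0(meta$pair_id[j], ".tajd_1")
      stats[is.na(stats[, cn]), cn] <- 0
    }
    if (meta$n2[j] >= 3L) {
      cn <- paste0(meta$pair_id[j], ".tajd_2")
      stats[is.na(stats[, cn]), cn] <- 0
    }
  }
  hyper <- .hyper_summarise_matrix(stats, Y)
  e_tau <- rowMeans(d$tau_pair)
  var_tau <- rowMeans(d$tau_pair^2) - e_tau^2
  om <- ifelse(e_tau > 0, pmax(var_tau, 0) / e_tau, 0)
  psi_realized <- vapply(seq_len(n_sims), function(i)
    length(unique(d$assignment[i, ])), 0L)
  out <- data.frame(psi = d$psi, psi_realized = psi_realized,
                    e_tau = e_tau, var_tau = pmax(var_tau, 0), omega = om)
  out <- cbind(out, as.data.frame(stats), as.data.frame(hyper))
  attr(out, "stat_cols") <- c(colnames(stats), colnames(hyper))
  attr(out, "prior") <- prior
  attr(out, "pair_meta") <- meta
  class(out) <- c("sim_table", "data.frame")
  out
}

#' Rejection step
#'
#' Standardises every usable statistic column by its standard deviation
#' across the simulated table, computes Euclidean distances between each
#' simulated row and the observed vector, and retains exactly
#' `n_accept` rows with the smallest distances (ties broken by row
#' index). Columns that are undefined in the observed data, contain
#' missing simulated values, or have zero variance are excluded (the
#' latter with a warning).
#'
#' @param obs observed vector from [observed_summary()].
#' @param table reference table from [run_simulations()].
#' @param n_accept number of draws to retain.
#' @return accepted rows with a `.dist` column; diagnostics in
#'   attributes (`obs`, `cols_used`, `col_sd`, `dist_max`, `prior`).
#' @export
abc_reject <- function(obs, table, n_accept) {
  stat_cols <- attr(table, "stat_cols") %||% intersect(names(obs),
                                                       names(table))
  n_accept <- as.integer(n_accept)
  stopifnot(n_accept >= 1, n_accept <= nrow(table))
  missing_cols <- setdiff(stat_cols, names(obs))
  if (length(missing_cols) > 0L)
    stop("observed vector lacks columns: ",
         paste(head(missing_cols, 5L), collapse = ", "), call. = FALSE)
  S <- as.matrix(table[, stat_cols, drop = FALSE])
  use <- !is.na(obs[stat_cols]) & colSums(is.na(S)) == 0L
  sds <- rep(NA_real_, length(stat_cols))
  sds[use] <- apply(S[, use, drop = FALSE], 2L, sd)
  zero_var <- use & !is.na(sds) & sds == 0
  if (any(zero_var)) {
    warning("excluding zero-variance statistic column(s): ",
            paste(stat_cols[zero_var], collapse = ", "))
    use <- use & !zero_var
  }
  if (!any(use))
    stop("no usable statistic columns for the rejection step",
         call. = FALSE)
  cols <- stat_cols[use]
  Z <- sweep(S[, cols, drop = FALSE], 2L, sds[use], `/`)
  zobs <- obs[cols] / sds[use]
  dist <- sqrt(rowSums(sweep(Z, 2L, zobs, `-`)^2))
  ord <- order(dist)[seq_len(n_accept)]
  acc <- table[ord, , drop = FALSE]
  acc$.dist <- dist[ord]
  rownames(acc) <- NULL
  attr(acc, "stat_cols") <- stat_cols
  attr(acc, "cols_used") <- cols
  attr(acc, "col_sd") <- structure(sds[use], names = cols)
  attr(acc, "obs") <- obs
  attr(acc, "dist_max") <- max(acc$.dist)
  attr(acc, "n_sims_total") <- nrow(table)
  attr(acc, "prior") <- attr(table, "prior")
  class(acc) <- c("abc_accepted", "data.frame")
  acc
}

#' Local-linear regression adjustment of accepted draws
#'
#' Beaumont-style post-rejection adjustment: each continuous
#' hyperparameter (`e_tau`, `var_tau`, `omega`) is regressed on the
#' standardised statistics with Epanechnikov weights at the acceptance
#' radius, and the draws are shifted to the observed statistics;
#' adjusted values are clamped to the prior support. For `psi` a
#' weighted multinomial-logit fit evaluated at the observed statistics
#' is attached (`attr(, "psi_prob_adj")`); if that fit fails, plain
#' weighted counts are used instead.
#'
#' @param accepted result of [abc_reject()].
#' @param psi_predictors statistics used in the multinomial-logit fit
#'   for psi: `"hyper"` (default) restricts to the across-pair
#'   mean/variance summaries, which carry the co-dispersion signal and
#'   keep the fit well-conditioned at typical acceptance sizes;
#'   `"all"` uses every statistic column.
#' @param psi_decay ridge (weight-decay) penalty passed to
#'   [nnet::multinom()]; 0 disables regularisation.
#' @return `accepted` with extra columns `e_tau_adj`, `var_tau_adj`,
#'   `omega_adj` and attributes `psi_prob_adj`, `weights`.
#' @export
regression_adjust <- function(accepted,
                              psi_predictors = c("hyper", "all"),
                              psi_decay = 0) {
  psi_predictors <- match.arg(psi_predictors)
  stopifnot(inherits(accepted, "abc_accepted"))
  cols <- attr(accepted, "cols_used")
  sds <- attr(accepted, "col_sd")
  obs <- attr(accepted, "obs")
  prior <- attr(accepted, "prior")
  dmax <- attr(accepted, "dist_max")
  Z <- sweep(as.matrix(accepted[, cols, drop = FALSE]), 2L, sds, `/`)
  X <- sweep(Z, 2L, obs[cols] / sds, `-`)  # 0 at the observed point
  w <- if (dmax > 0) 1 - (accepted$.dist / dmax)^2 else
    rep(1, nrow(accepted))
  w <- pmax(w, 1e-8)

  adjust_one <- function(y, lower = -Inf, upper = Inf) {
    fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, X), y, w)
    beta <- fit$coefficients[-1L]
    beta[is.na(beta)] <- 0
    adj <- y - drop(X %*% beta)
    pmin(pmax(adj, lower), upper)
  }
  tau_max <- if (!is.null(prior)) prior$tau_max else Inf
  accepted$e_tau_adj <- adjust_one(accepted$e_tau, 0, tau_max)
  accepted$var_tau_adj <- adjust_one(accepted$var_tau, 0)
  accepted$omega_adj <- adjust_one(accepted$omega, 0)
  attr(accepted, "weights") <- w

  psi_levels <- seq_len(if (!is.null(prior)) prior$psi_max
                        else max(accepted$psi))
  hyper_cols <- grepl("^(mean|var)_", colnames(X))
  Xpsi <- if (psi_predictors == "hyper" && any(hyper_cols))
    X[, hyper_cols, drop = FALSE] else X
  psi_prob <- NULL
  if (length(unique(accepted$psi)) > 1L) {
    psi_prob <- tryCatch({
      df <- data.frame(psi = factor(accepted$psi, levels = psi_levels),
                       Xpsi)
      fit <- nnet::multinom(psi ~ ., data = df, weights = w, trace = FALSE,
                            maxit = 200, decay = psi_decay)
      nd <- as.data.frame(matrix(0, 1L, ncol(Xpsi)))
      names(nd) <- colnames(Xpsi)
      p <- predict(fit, newdata = nd, type = "probs")
      full <- structure(rep(0, length(psi_levels)),
                        names = as.character(psi_levels))
      if (is.null(dim(p))) {
        if (length(p) == length(psi_levels)) full[] <- p
        else full[colnames(fit$fitted.values) %||% names(p)] <- p
      } else full[colnames(p)] <- p[1, ]
      full / sum(full)
    }, error = function(e) NULL)
  }
  if (is.null(psi_prob)) {
    tab <- tapply(w, factor(accepted$psi, levels = psi_levels), sum,
                  default = 0)
    psi_prob <- tab / sum(tab)
  }
  attr(accepted, "psi_prob_adj") <- psi_prob
  accepted
}

# kernel-density mode: Gaussian kernel, Silverman bandwidth, argmax on
# the density grid, clamped to the observed range
.kde_mode <- function(x, lower = 0) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(unique(x)) == 1L) return(x[1])
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(stats::median(x))
  d <- stats::density(x, bw = bw)
  m <- d$x[which.max(d$y)]
  min(max(m, max(min(x), lower)), max(x))
}

#' Posterior summaries of the hyperparameters
#'
#' Mode and mean of Psi, mode/mean/95% quantiles of Omega, and the mean
#' of E(tau) over accepted draws, mirroring the usual reporting of a
#' co-divergence ABC run. The Psi mode comes from (weighted) counts by
#' default; with `adjust = TRUE` the regression-adjusted Omega/E(tau)
#' draws and the multinomial-logit Psi probabilities from
#' [regression_adjust()] are summarised instead.
#'
#' @param accepted result of [abc_reject()] (or [regression_adjust()]).
#' @param adjust summarise regression-adjusted draws?
#' @return object of class `posterior_summary`.
#' @export
summarize_posterior <- function(accepted, adjust = FALSE) {
  prior <- attr(accepted, "prior")
  if (adjust && is.null(accepted$omega_adj))
    accepted <- regression_adjust(accepted)
  om <- if (adjust) accepted$omega_adj else accepted$omega
  et <- if (adjust) accepted$e_tau_adj else accepted$e_tau
  psi_levels <- seq_len(if (!is.null(prior)) prior$psi_max
                        else max(accepted$psi))
  if (adjust) {
    psi_prob <- attr(accepted, "psi_prob_adj")
    psi_mode <- as.integer(names(psi_prob)[which.max(psi_prob)])
    psi_mean <- sum(psi_levels * psi_prob)
  } else {
    tab <- table(factor(accepted$psi, levels = psi_levels))
    psi_prob <- as.numeric(tab) / sum(tab)
    names(psi_prob) <- psi_levels
    psi_mode <- as.integer(names(tab)[which.max(tab)])
    psi_mean <- mean(accepted$psi)
  }
  q <- quantile(om, c(0.025, 0.975), names = FALSE)
  structure(list(psi_mode = psi_mode, psi_mean = psi_mean,
                 psi_posterior = psi_prob,
                 omega_mode = .kde_mode(om), omega_mean = mean(om),
                 omega_q025 = q[1], omega_q975 = q[2],
                 e_tau_mean = mean(et),
                 n_accept = nrow(accepted),
                 adjusted = adjust,
                 provenance = list(
                   prior = prior,
                   cols_used = attr(accepted, "cols_used"),
                   n_sims_total = attr(accepted, "n_sims_total"))),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>", if (x$adjusted) "(regression-adjusted)" else "",
      "\n  Psi mode  =", x$psi_mode,
      "\n  Psi mean  =", round(x$psi_mean, 3),
      "\n  Omega mode =", signif(x$omega_mode, 4),
      "\n  Omega mean =", signif(x$omega_mean, 4),
      paste0(" (95% quantiles ", signif(x$omega_q025, 4), "-",
             signif(x$omega_q975, 4), ")"),
      "\n  E(tau) mean =", signif(x$e_tau_mean, 4),
      "\n  accepted draws =", x$n_accept, "\n")
  invisible(x)
}

#' Effective number of migrants per generation
#'
#' Converts a scaled migration rate and a theta estimate into the
#' effective number of immigrants per generation for the receiving
#' population, `theta * m / 2` (the 2Nm convention used by IM-style
#' analyses, with theta = 4Nmu).
#'
#' @param m scaled migration rate.
#' @param theta scaled mutation parameter of the receiving population.
#' @export
effective_migrants <- function(m, theta) {
  stopifnot(all(m >= 0), all(theta >= 0))
  theta * m / 2
}

#' End-to-end co-divergence test
#'
#' Runs the three stages of the hierarchical ABC test: observed summary
#' statistics, simulated reference table under the hyperprior, and
#' rejection (optionally regression-adjusted) followed by posterior
#' summarisation. Fully deterministic given `seed`.
#'
#' @param study list of [taxon_pair_data()] objects (one barrier set).
#' @param prior a [hyper_prior()] object; `prior$Y` must match the
#'   number of pairs.
#' @param seed integer seed (optional; the caller may also set the RNG
#'   state).
#' @param n_sims,n_accept override the prior's table sizes.
#' @param adjust apply [regression_adjust()] before summarising?
#' @param out_dir if non-`NULL`, checkpoints are written there:
#'   `sim_table.tsv`, `accepted.tsv`, `observed.tsv`,
#'   `posterior.json`.
#' @return object of class `codiverge_fit`: `posterior`, `accepted`,
#'   `sim_table`, `obs`, `prior`, `seed`.
#' @export
test_codivergence <- function(study, prior, seed = NULL,
                              n_sims = prior$n_sims,
                              n_accept = prior$n_accept,
                              adjust = FALSE, out_dir = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  meta <- pair_meta(study)
  if (nrow(meta) != prior$Y)
    stop("prior$Y (", prior$Y, ") does not match the number of pairs (",
         nrow(meta), ")", call. = FALSE)
  obs <- observed_summary(study)
  tab <- run_simulations(prior, meta, n_sims = n_sims)
  acc <- abc_reject(obs, tab, n_accept)
  if (adjust) acc <- regression_adjust(acc)
  post <- summarize_posterior(acc, adjust = adjust)
  post$provenance$seed <- seed
  fit <- structure(list(posterior = post, accepted = acc, sim_table = tab,
                        obs = obs, prior = prior, seed = seed),
                   class = "codiverge_fit")
  if (!is.null(out_dir)) write_fit_checkpoint(fit, out_dir)
  fit
}

#' @export
print.codiverge_fit <- function(x, ...) {
  cat("<codiverge_fit> ", length(x$obs), " observed statistics, ",
      nrow(x$sim_table), " simulations, seed = ",
      x$seed %||% NA, "\n", sep = "")
  print(x$posterior)
  invisible(x)
}
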