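# Two-population isolation-with-migration coalescent for a single taxon
# pair, and finite-sites HKY mutation sprinkling. See the package help
# page for the time/rate scaling convention (theta_ref = theta_max / 2;
# E[pi] = theta; E[pi_net] = rate_multiplier * theta_ref * tau at m = 0).

#' Demographic parameters for one taxon pair
#'
#' @param theta_1,theta_2 per-site scaled mutation rates (4N mu) of the
#'   two descendant populations.
#' @param theta_A ancestral per-site theta.
#' @param tau divergence time in coalescent units (see package help).
#' @param m_1,m_2 per-lineage scaled migration rates: the rate, backward
#'   in time, at which a lineage currently in population 1 (resp. 2)
#'   jumps to the other population, per coalescent unit.
#' @param n1,n2 sample sizes; `n1 + n2 >= 2`.
#' @param L locus length in sites.
#' @param rate_multiplier dimensionless locus rate scaling (mtDNA 20,
#'   cpDNA/ITS 1).
#' @param kappa transition/transversion parameter of the HKY mutation
#'   kernel.
#' @return object of class `pair_model_params`.
#' @export
pair_model_params <- function(theta_1, theta_2 = theta_1,
                              theta_A = theta_1 / 2, tau,
                              m_1 = 0, m_2 = 0, n1, n2, L,
                              rate_multiplier = 1, kappa = 4) {
  stopifnot(theta_1 > 0, theta_2 > 0, theta_A > 0, tau >= 0,
            m_1 >= 0, m_2 >= 0, n1 >= 0, n2 >= 0, n1 + n2 >= 2,
            L >= 1, rate_multiplier > 0, kappa > 0)
  structure(list(theta_1 = theta_1, theta_2 = theta_2, theta_A = theta_A,
                 tau = tau, m_1 = m_1, m_2 = m_2,
                 n1 = as.integer(n1), n2 = as.integer(n2), L = as.integer(L),
                 rate_multiplier = rate_multiplier, kappa = kappa),
            class = "pair_model_params")
}

#' Simulate a genealogy under the IM model
#'
#' Structured coalescent for `n1 + n2` lineages in two populations that
#' merge (backward in time) into the ancestral population at `tau`.
#' Within population i a pair of lineages coalesces at rate
#' `theta_ref / theta_i`; migration moves single lineages between
#' populations at rates `m_1`, `m_2` until `tau`.
#'
#' @param params a [pair_model_params()] object.
#' @param theta_ref reference theta fixing the time unit
#'   (`theta_max / 2` in an ABC analysis).
#' @param max_events guard cap on simulation events; exceeding it is an
#'   error (pathological parameters).
#' @return object of class `genealogy`: `n_tip`, `parent` (0-based,
#'   -1 at root), `node_time`, `tip_pop`, `migrations` table, `tmrca`.
#' @export
simulate_genealogy <- function(params, theta_ref, max_events = 1e7) {
  stopifnot(inherits(params, "pair_model_params"), theta_ref > 0)
  g <- cpp_sim_genealogy(params$n1, params$n2, params$theta_1,
                         params$theta_2, params$theta_A, params$tau,
                         params$m_1, params$m_2, theta_ref, max_events)
  g$params <- params
  g$theta_ref <- theta_ref
  class(g) <- "genealogy"
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy> ", x$n_tip, " tips, TMRCA = ", signif(x$tmrca, 4),
      " coalescent units, ", nrow(x$migrations), " migration events\n",
      sep = "")
  invisible(x)
}

#' Convert a genealogy to an ape \code{phylo} tree
#'
#' @param g a [simulate_genealogy()] result.
#' @return an `ape::phylo` object with branch lengths in coalescent units.
#' @export
genealogy_to_phylo <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  n <- g$n_tip
  nnode <- 2L * n - 1L
  root0 <- which(g$parent == -1L) - 1L  # 0-based root id
  # ape numbering: tips 1..n, root n+1, remaining internals n+2..2n-1
  map <- integer(nnode)
  map[seq_len(n)] <- seq_len(n)
  internals <- setdiff(seq_len(nnode) - 1L, c(seq_len(n) - 1L, root0))
  map[root0 + 1L] <- n + 1L
  map[internals + 1L] <- n + 1L + seq_along(internals)
  child <- which(g$parent >= 0L) - 1L
  edge <- cbind(map[g$parent[child + 1L] + 1L], map[child + 1L])
  len <- g$node_time[g$parent[child + 1L] + 1L] - g$node_time[child + 1L]
  phy <- structure(list(edge = matrix(as.integer(edge), ncol = 2L),
                        edge.length = len,
                        tip.label = paste0("t", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy)
}

#' Sprinkle mutations on a genealogy
#'
#' Drops Poisson-distributed mutations on every branch at per-site rate
#' `(theta_ref / 2) * rate_multiplier` per coalescent unit, drawing a
#' uniform ancestral sequence and substituting bases under an HKY kernel
#' with parameter `kappa` (uniform base frequencies), and returns the
#' resulting tip alignment.
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @param params a [pair_model_params()] object (for `L`,
#'   `rate_multiplier`, `kappa`).
#' @param theta_ref reference theta (defaults to the one stored in the
#'   genealogy).
#' @return character matrix of A/C/G/T with one row per tip, rows named
#'   `p<pop>_<i>`; the integer-coded matrix is attached as attribute
#'   `"codes"` and tip populations as `"tip_pop"`.
#' @export
sprinkle_mutations <- function(genealogy, params,
                               theta_ref = genealogy$theta_ref) {
  stopifnot(inherits(genealogy, "genealogy"),
            inherits(params, "pair_model_params"))
  mu_site <- 0.5 * theta_ref * params$rate_multiplier
  codes <- cpp_mutate_on_tree(genealogy$parent, genealogy$node_time,
                              genealogy$n_tip, params$L, mu_site,
                              params$kappa)
  pops <- genealogy$tip_pop
  ids <- paste0("p", pops, "_",
                ave(seq_along(pops), pops, FUN = seq_along))
  rownames(codes) <- ids
  chars <- matrix(.BASE_CHARS[codes], nrow = nrow(codes),
                  dimnames = list(ids, NULL))
  attr(chars, "codes") <- codes
  attr(chars, "tip_pop") <- pops
  chars
}

#' Simulate the summary-statistic vector for one pair
#'
#' Fused genealogy + mutation + statistics path used to build the ABC
#' reference table: the structured coalescent is simulated, mutations are
#' placed, and the eight per-pair statistics are computed without
#' materialising a full alignment. Bit-reproducible under `set.seed()`.
#' Undefined statistics (side with n < 2; Tajima's D with n < 3) are
#' `NA`; a defined Tajima's D with zero segregating sites is encoded 0,
#' matching [pair_summary_vector()] defaults.
#'
#' @inheritParams simulate_genealogy
#' @return named numeric vector as [pair_summary_vector()].
#' @export
simulate_pair_stats <- function(params, theta_ref, max_events = 1e7) {
  stopifnot(inherits(params, "pair_model_params"), theta_ref > 0)
  x <- cpp_sim_pair_stats(params$n1, params$n2, params$L, params$theta_1,
                          params$theta_2, params$theta_A, params$tau,
                          params$m_1, params$m_2, params$rate_multiplier,
                          theta_ref, params$kappa, max_events)
  names(x) <- STAT_NAMES
  # NaN arises only from arithmetic on NA stats; normalise to NA
  x[is.nan(x)] <- NA_real_
  if (params$n1 >= 3L && is.na(x["tajd_1"]) && !is.na(x["pi_1"]))
    x["tajd_1"] <- 0
  if (params$n2 >= 3L && is.na(x["tajd_2"]) && !is.na(x["pi_2"]))
    x["tajd_2"] <- 0
  x
}
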