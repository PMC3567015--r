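# Per-pair population-genetic summary statistics and corrected distances.
# Missing data (N or gap) is excluded pairwise: each compared pair of
# sequences uses only the sites where both carry a base.

# mean proportion of differing sites and mean raw difference count over
# all unordered pairs within `mat` (integer codes, NA = missing)
.pairwise_within <- function(mat) {
  n <- nrow(mat)
  props <- numeric(0)
  diffs <- numeric(0)
  for (i in seq_len(n - 1L)) {
    xi <- mat[i, ]
    for (j in seq.int(i + 1L, n)) {
      xj <- mat[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      nv <- sum(ok)
      d <- sum(xi[ok] != xj[ok])
      props <- c(props, if (nv > 0L) d / nv else NA_real_)
      diffs <- c(diffs, d)
    }
  }
  if (anyNA(props))
    warning("some sequence pairs share no comparable sites; ",
            "they are excluded from the diversity average")
  list(prop = mean(props, na.rm = TRUE), diff = mean(diffs))
}

# number of segregating sites (>= 2 distinct non-missing bases)
.seg_sites <- function(mat) {
  sum(apply(mat, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}

.harmonic <- function(n) sum(1 / seq_len(n - 1L))

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites over all unordered pairs of
#' sequences, per site. Sites with N or a gap in either member of a
#' compared pair are excluded for that pair only.
#'
#' @param seqs aligned sequences (see [encode_alignment()]).
#' @return per-site diversity (scalar).
#' @export
nucleotide_diversity <- function(seqs) {
  mat <- .as_code_matrix(seqs)
  if (nrow(mat) < 2L)
    stop("nucleotide diversity is undefined for fewer than 2 sequences",
         call. = FALSE)
  .pairwise_within(mat)$prop
}

#' Watterson's theta
#'
#' `S / (a1 * L)` where `S` is the number of segregating sites,
#' `a1 = sum(1/i, i = 1..n-1)` and `L` the alignment length.
#'
#' @inheritParams nucleotide_diversity
#' @return per-site theta_W.
#' @export
watterson_theta <- function(seqs) {
  mat <- .as_code_matrix(seqs)
  n <- nrow(mat)
  if (n < 2L)
    stop("Watterson's theta is undefined for fewer than 2 sequences",
         call. = FALSE)
  .seg_sites(mat) / (.harmonic(n) * ncol(mat))
}

#' Tajima's D
#'
#' Standard Tajima (1989) test statistic contrasting mean pairwise
#' differences with the scaled number of segregating sites. Returns the
#' `NA` sentinel (not zero) when it is undefined: fewer than 3 sequences
#' or no segregating sites.
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA` when undefined.
#' @export
tajimas_d <- function(seqs) {
  mat <- .as_code_matrix(seqs)
  n <- nrow(mat)
  if (n < 3L) return(NA_real_)
  S <- .seg_sites(mat)
  if (S < 1L) return(NA_real_)
  khat <- .pairwise_within(mat)$diff
  a1 <- .harmonic(n)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom <= 0) return(NA_real_)
  (khat - S / a1) / denom
}

#' Between-population diversity
#'
#' Mean pairwise proportion of differing sites over all `n1 * n2`
#' between-population sequence pairs (pairwise deletion of missing data).
#'
#' @param pop1_seqs,pop2_seqs aligned sequences for each population.
#' @return per-site pi_b.
#' @export
between_diversity <- function(pop1_seqs, pop2_seqs) {
  m1 <- .as_code_matrix(pop1_seqs, "population 1")
  m2 <- .as_code_matrix(pop2_seqs, "population 2")
  if (ncol(m1) != ncol(m2))
    stop("the two populations have different alignment lengths",
         call. = FALSE)
  props <- numeric(nrow(m1) * nrow(m2))
  k <- 0L
  for (i in seq_len(nrow(m1))) {
    xi <- m1[i, ]
    for (j in seq_len(nrow(m2))) {
      xj <- m2[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      nv <- sum(ok)
      k <- k + 1L
      props[k] <- if (nv > 0L) sum(xi[ok] != xj[ok]) / nv else NA_real_
    }
  }
  if (anyNA(props))
    warning("some cross-population pairs share no comparable sites")
  mean(props, na.rm = TRUE)
}

#' Net divergence
#'
#' `pi_net = pi_b - (pi_1 + pi_2) / 2`.
#'
#' @param pi_b between-population diversity.
#' @param pi_1,pi_2 within-population diversities.
#' @export
net_divergence <- function(pi_b, pi_1, pi_2) pi_b - (pi_1 + pi_2) / 2

# transition / transversion count table for one sequence pair
.pair_subst_counts <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  a <- xi[ok]; b <- xj[ok]
  diff <- a != b
  ag <- sum(diff & ((a == 1L & b == 3L) | (a == 3L & b == 1L)))
  ct <- sum(diff & ((a == 2L & b == 4L) | (a == 4L & b == 2L)))
  list(n = sum(ok), P1 = ag, P2 = ct, Q = sum(diff) - ag - ct)
}

#' Tamura-Nei (TN93) corrected distance
#'
#' Corrected sequence divergence under the Tamura-Nei (1993) model,
#' distinguishing the two transition classes (A/G and C/T) from
#' transversions, with base frequencies estimated from the pooled
#' compared sequences. With one argument, the mean over all within-set
#' pairs; with two, the mean over all between-set pairs.
#'
#' @param seqs_a,seqs_b aligned sequences; `seqs_b` may be `NULL`.
#' @param base_freq optional length-4 vector of base frequencies
#'   (A, C, G, T) overriding the pooled estimate.
#' @return mean corrected distance.
#' @export
tn93_distance <- function(seqs_a, seqs_b = NULL, base_freq = NULL) {
  ma <- .as_code_matrix(seqs_a, "set A")
  mb <- if (is.null(seqs_b)) NULL else .as_code_matrix(seqs_b, "set B")
  pooled <- if (is.null(mb)) ma else rbind(ma, mb)
  if (is.null(base_freq)) {
    tab <- tabulate(pooled[!is.na(pooled)], nbins = 4L)
    base_freq <- tab / sum(tab)
  }
  if (length(base_freq) != 4L || any(base_freq < 0))
    stop("base_freq must be 4 non-negative frequencies", call. = FALSE)
  base_freq <- base_freq / sum(base_freq)
  gA <- base_freq[1]; gC <- base_freq[2]; gG <- base_freq[3]; gT <- base_freq[4]
  gR <- gA + gG; gY <- gC + gT

  # closed form: d = -k1 log(w1) - k2 log(w2) - k3 log(w3)
  one_pair <- function(xi, xj, label) {
    cnt <- .pair_subst_counts(xi, xj)
    if (cnt$n == 0L)
      stop("TN93: sequence pair ", label, " shares no comparable sites",
           call. = FALSE)
    P1 <- cnt$P1 / cnt$n; P2 <- cnt$P2 / cnt$n; Q <- cnt$Q / cnt$n
    if (P1 + P2 + Q == 0) return(0)
    k1 <- 2 * gA * gG / gR
    k2 <- 2 * gC * gT / gY
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
    if ((k1 == 0 && P1 > 0) || (k2 == 0 && P2 > 0))
      stop("TN93: observed transitions in pair ", label,
           " but the corresponding base frequencies are zero", call. = FALSE)
    w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
    w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0)
      stop("TN93 distance is undefined (saturation) for sequence pair ",
           label, call. = FALSE)
    -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  }

  ids_a <- rownames(ma) %||% paste0("A", seq_len(nrow(ma)))
  if (is.null(mb)) {
    if (nrow(ma) < 2L)
      stop("TN93 within-set distance needs at least 2 sequences",
           call. = FALSE)
    d <- numeric(0)
    for (i in seq_len(nrow(ma) - 1L))
      for (j in seq.int(i + 1L, nrow(ma)))
        d <- c(d, one_pair(ma[i, ], ma[j, ],
                           paste0("(", ids_a[i], ", ", ids_a[j], ")")))
    return(mean(d))
  }
  ids_b <- rownames(mb) %||% paste0("B", seq_len(nrow(mb)))
  d <- numeric(0)
  for (i in seq_len(nrow(ma)))
    for (j in seq_len(nrow(mb)))
      d <- c(d, one_pair(ma[i, ], mb[j, ],
                         paste0("(", ids_a[i], ", ", ids_b[j], ")")))
  mean(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tamura-Nei distance summary for a taxon pair
#'
#' Within-population corrected mean distances (`Dx`, `Dy`), the
#' between-population distance (`Dxy`), and the net corrected divergence
#' `Da = Dxy - (Dx + Dy) / 2`. Base frequencies are pooled over both
#' populations so the four numbers share one frequency estimate.
#'
#' @param pair a [taxon_pair_data()] object.
#' @return named numeric vector `c(Dx, Dy, Dxy, Da)`.
#' @export
distance_summary <- function(pair) {
  stopifnot(inherits(pair, "taxon_pair"))
  pooled <- rbind(pair$pop1, pair$pop2)
  tab <- tabulate(pooled[!is.na(pooled)], nbins = 4L)
  bf <- tab / sum(tab)
  Dx <- tn93_distance(pair$pop1, base_freq = bf)
  Dy <- tn93_distance(pair$pop2, base_freq = bf)
  Dxy <- tn93_distance(pair$pop1, pair$pop2, base_freq = bf)
  c(Dx = Dx, Dy = Dy, Dxy = Dxy, Da = Dxy - (Dx + Dy) / 2)
}

#' Per-pair summary-statistic vector
#'
#' The eight per-pair slots of the summary vector used throughout the
#' ABC machinery: `pi_1`, `pi_2`, `pi_b`, `pi_net`, `theta_w_1`,
#' `theta_w_2`, `tajd_1`, `tajd_2`. Statistics whose sample-size
#' precondition fails (a side with fewer than 2 sequences; Tajima's D
#' with fewer than 3) are `NA`. An alignment with no segregating sites
#' on a side makes that side's Tajima's D undefined; for use inside the
#' ABC vector it is encoded as 0 by default so observed and simulated
#' vectors stay numerically comparable (`tajd_undefined = "na"` keeps
#' the sentinel).
#'
#' @param pair a [taxon_pair_data()] object.
#' @param tajd_undefined `"zero"` (default) or `"na"`.
#' @return named numeric vector of length 8.
#' @export
pair_summary_vector <- function(pair, tajd_undefined = c("zero", "na")) {
  stopifnot(inherits(pair, "taxon_pair"))
  tajd_undefined <- match.arg(tajd_undefined)
  m1 <- pair$pop1; m2 <- pair$pop2
  n1 <- nrow(m1); n2 <- nrow(m2)
  pi_1 <- if (n1 >= 2L) nucleotide_diversity(m1) else NA_real_
  pi_2 <- if (n2 >= 2L) nucleotide_diversity(m2) else NA_real_
  pi_b <- between_diversity(m1, m2)
  tw1 <- if (n1 >= 2L) watterson_theta(m1) else NA_real_
  tw2 <- if (n2 >= 2L) watterson_theta(m2) else NA_real_
  d1 <- if (n1 >= 3L) tajimas_d(m1) else NA_real_
  d2 <- if (n2 >= 3L) tajimas_d(m2) else NA_real_
  if (tajd_undefined == "zero") {
    if (n1 >= 3L && is.na(d1)) d1 <- 0
    if (n2 >= 3L && is.na(d2)) d2 <- 0
  }
  out <- c(pi_1, pi_2, pi_b, net_divergence(pi_b, pi_1, pi_2),
           tw1, tw2, d1, d2)
  names(out) <- STAT_NAMES
  out
}

#' Across-pair hyper-summaries
#'
#' Means and population variances (divide by the number of pairs) of each
#' per-pair statistic across the pairs of a barrier set. With a single
#' pair all variances are 0. `NA` statistics (undefined for a pair's
#' sample sizes) are dropped from that statistic's mean/variance.
#'
#' @param vectors matrix with one row per pair, columns as
#'   [pair_summary_vector()], or a list of such vectors.
#' @return named numeric vector `mean_<stat>`, `var_<stat>`.
#' @export
hyper_summary <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L,
                                               dimnames = list(NULL, names(vectors)))
  mu <- apply(vectors, 2L, mean, na.rm = TRUE)
  vv <- apply(vectors, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    mean(x^2) - mean(x)^2
  })
  vv <- pmax(vv, 0)
  cn <- colnames(vectors) %||% STAT_NAMES
  out <- c(mu, vv)
  names(out) <- c(paste0("mean_", cn), paste0("var_", cn))
  out
}
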