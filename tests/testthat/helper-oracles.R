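# Independent naive oracles (O(n^2 L) double loops, direct formula
# transcriptions) used to validate the package's statistics, plus small
# fixture builders. Everything here is deliberately written without
# reference to the package internals.

BASES <- c("A", "C", "G", "T")

rand_alignment <- function(n, L, div = 0.05, miss = 0) {
  anc <- sample(BASES, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), n, L)
  mut <- matrix(runif(n * L) < div, n, L)
  mat[mut] <- sample(BASES, sum(mut), replace = TRUE)
  if (miss > 0) {
    gap <- matrix(runif(n * L) < miss, n, L)
    mat[gap] <- sample(c("N", "-"), sum(gap), replace = TRUE)
  }
  rownames(mat) <- paste0("s", seq_len(n))
  mat
}

oracle_codes <- function(chars) {
  map <- c(A = 1, C = 2, G = 3, T = 4)
  out <- matrix(unname(map[chars]), nrow = nrow(chars))
  rownames(out) <- rownames(chars)
  out
}

# mean pairwise proportion of differing sites, pairwise deletion
oracle_pi <- function(chars) {
  m <- oracle_codes(chars)
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  mean(vals)
}

# mean pairwise raw difference count
oracle_khat <- function(chars) {
  m <- oracle_codes(chars)
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    vals <- c(vals, sum(m[i, ok] != m[j, ok]))
  }
  mean(vals)
}

# independent segregating-site counter
oracle_S <- function(chars) {
  m <- oracle_codes(chars)
  sum(apply(m, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2
  }))
}

oracle_theta_w <- function(chars) {
  n <- nrow(chars)
  oracle_S(chars) / (sum(1 / (1:(n - 1))) * ncol(chars))
}

# Tajima (1989) D written straight from the published constants
oracle_tajd <- function(chars) {
  n <- nrow(chars)
  S <- oracle_S(chars)
  if (n < 3 || S == 0) return(NA_real_)
  k <- oracle_khat(chars)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  denom <- sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  if (denom <= 0) return(NA_real_)  # n = 3 degeneracy: c1 = c2 = 0
  (k - S / a1) / denom
}

oracle_pib <- function(chars1, chars2) {
  m1 <- oracle_codes(chars1); m2 <- oracle_codes(chars2)
  vals <- c()
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
    ok <- !is.na(m1[i, ]) & !is.na(m2[j, ])
    vals <- c(vals, sum(m1[i, ok] != m2[j, ok]) / sum(ok))
  }
  mean(vals)
}

# mean uncorrected p-distance over within-set pairs
oracle_pdist <- function(chars) oracle_pi(chars)

# Tamura-Nei (1993) corrected distance for one pair, direct
# transcription of the published equation from the count table
oracle_tn93_pair <- function(x, y, freq) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; nv <- length(x)
  is_ts_ag <- (x == 1 & y == 3) | (x == 3 & y == 1)
  is_ts_ct <- (x == 2 & y == 4) | (x == 4 & y == 2)
  P1 <- sum(is_ts_ag) / nv
  P2 <- sum(is_ts_ct) / nv
  Q <- sum(x != y) / nv - P1 - P2
  gA <- freq[1]; gC <- freq[2]; gG <- freq[3]; gT <- freq[4]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
}

oracle_tn93_within <- function(chars) {
  m <- oracle_codes(chars)
  tab <- tabulate(m[!is.na(m)], nbins = 4)
  freq <- tab / sum(tab)
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, oracle_tn93_pair(m[i, ], m[j, ], freq))
  mean(vals)
}

make_pair <- function(chars1, chars2, id = "pairX", barrier = "testbar",
                      mult = 1) {
  suppressWarnings(taxon_pair_data(id, barrier, chars1, chars2,
                                   rate_multiplier = mult))
}

# smallest usable synthetic study for fast end-to-end tests
tiny_truth <- function(seed = 1, Y = 2, tau = 0.5) {
  study_truth(sprintf("tp%02d", seq_len(Y)), "tiny",
              tau_class = tau, assignment = rep(1L, Y),
              theta = 0.002, n1 = 8, n2 = 8, L = 300,
              rate_multiplier = 20, seed = seed)
}
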