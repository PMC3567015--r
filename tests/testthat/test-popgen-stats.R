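test_that("diversity and theta_W match hand arithmetic on simple cases", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 98), "C", "G"), collapse = "")
  expect_equal(nucleotide_diversity(c(a, b)), 0.02)
  expect_equal(nucleotide_diversity(rep(a, 5)), 0)
  # n = 2, S = 5, L = 100 -> a1 = 1
  x <- paste(rep("A", 100), collapse = "")
  y <- paste(c(rep("A", 95), rep("C", 5)), collapse = "")
  expect_equal(watterson_theta(c(x, y)), 0.05)
  # n = 4, S = 11, L = 100 -> a1 = 11/6
  base <- rep("A", 100)
  m <- matrix(rep(base, each = 4), 4, 100)
  m[2, 1:5] <- "C"; m[3, 6:9] <- "G"; m[4, 10:11] <- "T"
  expect_equal(watterson_theta(m), 0.06)
  expect_error(nucleotide_diversity("ACGT"), "fewer than 2")
})

test_that("Tajima's D is zero on the numerator identity and NA when undefined", {
  # n = 4: 8 singleton + 3 doubleton sites give khat = 6 = S/a1 exactly
  m <- matrix("A", 4, 30)
  for (s in 1:8) m[(s %% 4) + 1, s] <- "G"
  m[1:2, 9:11] <- "C"
  expect_equal(tajimas_d(m), 0)
  expect_true(is.na(tajimas_d(matrix("A", 4, 30))))  # S = 0 sentinel
  expect_true(is.na(tajimas_d(matrix(c("A", "C"), 2, 10))))  # n < 3
  # n = 3 degeneracy: the variance constants vanish, D has no value
  m3 <- matrix("A", 3, 30); m3[3, 1] <- "G"
  expect_true(is.na(tajimas_d(m3)))
})

test_that("all statistics equal independent brute-force oracles on random alignments", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    L <- sample(20:200, 1)
    miss <- sample(c(0, 0.03), 1)
    a <- rand_alignment(n, L, div = runif(1, 0.01, 0.15), miss = miss)
    expect_equal(nucleotide_diversity(a), oracle_pi(a))
    expect_equal(watterson_theta(a), oracle_theta_w(a))
    if (n >= 3) {
      d <- tajimas_d(a)
      od <- oracle_tajd(a)
      if (is.na(od)) expect_true(is.na(d)) else expect_equal(d, od)
    }
    n2 <- sample(2:6, 1)
    b <- rand_alignment(n2, L, div = runif(1, 0.01, 0.15), miss = miss)
    expect_equal(between_diversity(a, b), oracle_pib(a, b))
  }
})

test_that("pi_net identity holds exactly and pi is relabeling-invariant", {
  set.seed(7)
  for (rep in 1:25) {
    a <- rand_alignment(5, 80, div = 0.1)
    b <- rand_alignment(4, 80, div = 0.1)
    pr <- make_pair(a, b)
    v <- pair_summary_vector(pr)
    expect_identical(v[["pi_net"]],
                     v[["pi_b"]] - (v[["pi_1"]] + v[["pi_2"]]) / 2)
    perm <- sample(nrow(a))
    expect_equal(nucleotide_diversity(a[perm, ]), nucleotide_diversity(a))
    expect_equal(between_diversity(a[perm, ], b), between_diversity(a, b))
  }
})

test_that("self-comparison obeys the exact all-pairs relations; fixed differences give f/L", {
  # feeding one sample in as both populations includes the n zero-distance
  # self pairings in pi_b, so pi_net = -pi_1/n exactly (and 0 as n grows)
  a <- rand_alignment(4, 60, div = 0.08)
  pr <- make_pair(a, a)
  v <- pair_summary_vector(pr)
  expect_equal(v[["pi_net"]], -v[["pi_1"]] / nrow(a))
  # two distinct but identical-content samples behave the same way
  expect_equal(between_diversity(a, a),
               (1 - 1 / nrow(a)) * nucleotide_diversity(a))
  # monomorphic populations fixed for different bases at f sites
  L <- 50; f <- 4
  p1 <- matrix("A", 3, L)
  p2 <- matrix("A", 3, L); p2[, 1:f] <- "G"
  expect_equal(between_diversity(p1, p2), f / L)
  v2 <- pair_summary_vector(make_pair(p1, p2))
  expect_equal(v2[["pi_net"]], f / L)
})

test_that("TN93 distance matches a direct formula transcription and ape", {
  set.seed(11)
  for (rep in 1:20) {
    a <- rand_alignment(5, 150, div = runif(1, 0.02, 0.12))
    expect_equal(tn93_distance(a), oracle_tn93_within(a))
  }
  # cross-check against an established implementation on the same set
  a <- rand_alignment(6, 300, div = 0.08)
  bin <- ape::as.DNAbin(matrix(tolower(a), nrow(a),
                               dimnames = list(rownames(a), NULL)))
  d_ape <- mean(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
  expect_equal(tn93_distance(a), d_ape, tolerance = 1e-8)
})

test_that("TN93 handles identity, inflates over p-distance, and errors on saturation", {
  a <- matrix("A", 3, 40); a[, 1:10] <- matrix(sample(BASES, 30, TRUE), 3)
  same <- rbind(a[1, , drop = FALSE], a[1, , drop = FALSE])
  expect_equal(tn93_distance(same), 0)
  set.seed(3)
  for (rep in 1:20) {
    x <- rand_alignment(2, 200, div = 0.1)
    if (oracle_pdist(x) > 0)
      expect_gt(tn93_distance(x), oracle_pdist(x) - 1e-12)
  }
  # population against itself: the n self pairings dilute Dxy by 1 - 1/n
  p <- rand_alignment(4, 100, div = 0.06)
  pr <- make_pair(p, p)
  ds <- distance_summary(pr)
  expect_equal(ds[["Dxy"]], (1 - 1 / nrow(p)) * ds[["Dx"]])
  expect_equal(ds[["Dy"]], ds[["Dx"]])
  expect_equal(ds[["Da"]], ds[["Dxy"]] - (ds[["Dx"]] + ds[["Dy"]]) / 2)
  # all-transversion pair: the Q log argument goes non-positive
  x <- c(paste(rep("A", 40), collapse = ""), paste(rep("C", 40), collapse = ""))
  expect_error(tn93_distance(x), "saturation")
})

test_that("hyper summaries are order-invariant with hand-computed moments", {
  set.seed(9)
  v1 <- pair_summary_vector(make_pair(rand_alignment(4, 60, div = 0.05),
                                      rand_alignment(4, 60, div = 0.05)))
  v2 <- pair_summary_vector(make_pair(rand_alignment(5, 60, div = 0.1),
                                      rand_alignment(3, 60, div = 0.1)))
  h1 <- hyper_summary(rbind(v1))
  expect_true(all(h1[grep("^var_", names(h1))] == 0))
  h12 <- hyper_summary(rbind(v1, v2))
  h21 <- hyper_summary(rbind(v2, v1))
  expect_equal(h12, h21)
  expect_equal(unname(h12["mean_pi_1"]), (v1[["pi_1"]] + v2[["pi_1"]]) / 2)
  expect_equal(unname(h12["var_pi_1"]),
               mean(c(v1[["pi_1"]], v2[["pi_1"]])^2) -
                 mean(c(v1[["pi_1"]], v2[["pi_1"]]))^2)
})

test_that("sequence encoding maps U to T and locates bad characters", {
  expect_equal(nucleotide_diversity(c("ACGU", "ACGT")), 0)
  expect_equal(nucleotide_diversity(c("acgt", "ACGT")), 0)
  expect_error(encode_alignment(c(one = "ACRT", two = "ACGT")),
               "'R' in sequence one at site 3")
})
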