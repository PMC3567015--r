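# Synthetic multi-pair studies with known truth, so every pipeline stage
# can be validated without downloading sequence data. Alignments are
# drawn from the same IM coalescent the engine simulates, at fixed
# (not prior-drawn) parameters.

#' Ground truth for a synthetic multi-pair study
#'
#' @param pair_id character vector of pair labels (length Y).
#' @param barrier_id single barrier label.
#' @param tau_class divergence time of each pulse (distinct values;
#'   coalescent units).
#' @param assignment integer vector mapping each pair to a pulse
#'   (index into `tau_class`).
#' @param theta per-pair theta (recycled).
#' @param m_1,m_2 per-pair scaled migration rates (recycled; default 0,
#'   clean vicariance).
#' @param n1,n2 per-pair sample sizes (recycled).
#' @param L per-pair locus length (recycled; default 600).
#' @param rate_multiplier per-pair locus rate scaling (recycled).
#' @param theta_anc_ratio ancestral theta as a fraction of theta.
#' @param theta_ref reference theta fixing the time unit of
#'   `tau_class` (default 0.005, i.e. a desk-scale theta_max of 0.01).
#' @param kappa HKY transition/transversion parameter.
#' @param seed integer seed used by [generate_study()].
#' @return object of class `study_truth`; `psi_true` is the number of
#'   distinct realised divergence times and `omega_true` the dispersion
#'   index of the true per-pair times.
#' @export
study_truth <- function(pair_id, barrier_id, tau_class, assignment,
                        theta = 0.002, m_1 = 0, m_2 = 0,
                        n1 = 10, n2 = 10, L = 600, rate_multiplier = 1,
                        theta_anc_ratio = 0.5, theta_ref = 0.005,
                        kappa = 4, seed = NULL) {
  Y <- length(pair_id)
  stopifnot(Y >= 1, length(assignment) == Y,
            all(assignment %in% seq_along(tau_class)),
            !anyDuplicated(tau_class), all(tau_class >= 0),
            theta_ref > 0)
  rec <- function(x) rep_len(x, Y)
  tau_pair <- tau_class[assignment]
  structure(list(Y = Y, pair_id = as.character(pair_id),
                 barrier_id = as.character(barrier_id),
                 tau_class = tau_class, assignment = as.integer(assignment),
                 tau_pair = tau_pair,
                 psi_true = length(unique(tau_class[assignment])),
                 omega_true = omega(tau_pair),
                 theta = rec(theta), m_1 = rec(m_1), m_2 = rec(m_2),
                 n1 = as.integer(rec(n1)), n2 = as.integer(rec(n2)),
                 L = as.integer(rec(L)),
                 rate_multiplier = rec(rate_multiplier),
                 theta_anc_ratio = theta_anc_ratio,
                 theta_ref = theta_ref, kappa = kappa, seed = seed),
            class = "study_truth")
}

#' @export
print.study_truth <- function(x, ...) {
  cat("<study_truth> barrier ", x$barrier_id, ": Y = ", x$Y,
      ", psi_true = ", x$psi_true,
      ", tau = {", paste(signif(x$tau_class, 3), collapse = ", "),
      "}, omega_true = ", signif(x$omega_true, 4), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic study
#'
#' Simulates one alignment per pair from the IM model at the true
#' parameters. With `dir` set, writes one FASTA per pair, a manifest TSV
#' mapping every sequence to its pair/population/barrier, and the truth
#' as JSON, in the layout [read_study()] consumes.
#'
#' @param truth a [study_truth()] object.
#' @param dir optional output directory (created if needed).
#' @return invisibly, a list with `study` (list of
#'   [taxon_pair_data()]), `truth`, and (when written) `manifest_path`.
#' @export
generate_study <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "study_truth"))
  if (!is.null(truth$seed)) set.seed(as.integer(truth$seed))
  study <- vector("list", truth$Y)
  for (j in seq_len(truth$Y)) {
    params <- pair_model_params(
      theta_1 = truth$theta[j], theta_2 = truth$theta[j],
      theta_A = truth$theta_anc_ratio * truth$theta[j],
      tau = truth$tau_pair[j], m_1 = truth$m_1[j], m_2 = truth$m_2[j],
      n1 = truth$n1[j], n2 = truth$n2[j], L = truth$L[j],
      rate_multiplier = truth$rate_multiplier[j], kappa = truth$kappa)
    g <- simulate_genealogy(params, truth$theta_ref)
    aln <- sprinkle_mutations(g, params)
    pops <- attr(aln, "tip_pop")
    ids <- paste0(truth$pair_id[j], "_", rownames(aln))
    rownames(aln) <- ids
    mult <- truth$rate_multiplier[j]
    study[[j]] <- suppressWarnings(taxon_pair_data(
      truth$pair_id[j], truth$barrier_id,
      aln[pops == 1L, , drop = FALSE], aln[pops == 2L, , drop = FALSE],
      rate_multiplier = mult,
      locus_type = if (mult >= 20) "mtDNA" else "cpDNA"))
  }
  names(study) <- truth$pair_id
  out <- list(study = study, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    for (j in seq_len(truth$Y)) {
      p <- study[[j]]
      fasta <- paste0(p$pair_id, ".fasta")
      seqs <- rbind(p$pop1, p$pop2)
      chars <- tolower(matrix(ifelse(is.na(seqs), "n", .BASE_CHARS[seqs]),
                              nrow = nrow(seqs),
                              dimnames = list(rownames(seqs), NULL)))
      ape::write.FASTA(ape::as.DNAbin(chars), file.path(dir, fasta))
      rows[[j]] <- data.frame(
        pair_id = p$pair_id, barrier_id = p$barrier_id, fasta_path = fasta,
        sequence_id = rownames(seqs),
        population = rep(c(1L, 2L), c(p$n1, p$n2)),
        locus_type = p$locus_type,
        rate_multiplier = p$rate_multiplier,
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    manifest_path <- file.path(dir, "manifest.tsv")
    write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    out$manifest_path <- manifest_path
  }
  invisible(out)
}

# migration prior means per barrier: means of the m1/m2 posterior means
# across that barrier's species in the IM analyses consumed as config
.PRESET_MIG_MEAN <- c(
  "isthmus-like" = 0.031648,
  "tuxtlas-like" = 0.022677,
  "isthmus2-like" = 0.6736667,
  "depression-like" = 0.0006825)

#' Preset synthetic scenarios
#'
#' Documented study shapes mirroring typical barrier sets of a
#' comparative cloud-forest phylogeography design: a 10-pair barrier
#' with three divergence pulses (`"isthmus-like"`), a 5-pair and a
#' 3-pair single-pulse barrier (`"tuxtlas-like"`, `"isthmus2-like"`)
#' and a 2-pair single-pulse barrier (`"depression-like"`). Sample
#' sizes echo real single-locus studies (e.g. 105/17 ... 23/7 sequences
#' per side); plant loci (cpDNA/ITS) carry rate multiplier 1 and mtDNA
#' loci 20. Truth thetas are 0.008 (cpDNA/ITS) and 0.002 (mtDNA), i.e.
#' realistic per-site diversities of roughly 0.8% and 4% after rate
#' scaling.
#'
#' @param name preset name; unknown names raise an error listing the
#'   presets.
#' @param seed seed stored in the truth (default 1).
#' @return a [study_truth()]; the barrier's migration prior mean is
#'   attached as attribute `"mig_prior_mean"`.
#' @export
preset_scenarios <- function(name, seed = 1) {
  presets <- names(.PRESET_MIG_MEAN)
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop("unknown preset '", name, "'; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  tr <- switch(name,
    "isthmus-like" = study_truth(
      pair_id = sprintf("pair%02d", 1:10), barrier_id = "isthmus-like",
      tau_class = c(0.5, 1.5, 2.5),
      assignment = c(3L, 3L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L),
      theta = c(0.008, 0.008, rep(0.002, 8)),
      n1 = c(105L, 134L, 138L, 77L, 76L, 45L, 51L, 21L, 20L, 23L),
      n2 = c(17L, 20L, 21L, 49L, 22L, 25L, 21L, 9L, 3L, 7L),
      rate_multiplier = c(1, 1, rep(20, 8)), seed = seed),
    "tuxtlas-like" = study_truth(
      pair_id = sprintf("pair%02d", 1:5), barrier_id = "tuxtlas-like",
      tau_class = 1.5, assignment = rep(1L, 5),
      theta = c(0.008, rep(0.002, 4)),
      n1 = c(125L, 126L, 13L, 15L, 137L), n2 = c(9L, 12L, 5L, 2L, 15L),
      rate_multiplier = c(1, rep(20, 4)), seed = seed),
    "isthmus2-like" = study_truth(
      pair_id = sprintf("pair%02d", 1:3), barrier_id = "isthmus2-like",
      tau_class = 1.0, assignment = rep(1L, 3),
      theta = c(0.008, 0.008, 0.002),
      n1 = c(127L, 133L, 130L), n2 = c(32L, 60L, 46L),
      rate_multiplier = c(1, 1, 20), seed = seed),
    "depression-like" = study_truth(
      pair_id = sprintf("pair%02d", 1:2), barrier_id = "depression-like",
      tau_class = 0.5, assignment = rep(1L, 2),
      theta = 0.002, n1 = c(16L, 10L), n2 = c(6L, 11L),
      rate_multiplier = 20, seed = seed))
  attr(tr, "mig_prior_mean") <- unname(.PRESET_MIG_MEAN[name])
  tr
}

#' Desk-scale analysis prior matching a preset
#'
#' The hyperprior used to analyse a preset scenario at desk scale:
#' `tau_max = 3` as in the study design, `theta_max = 0.01` (so
#' `theta_ref = 0.005`, the unit the preset truths are expressed in),
#' and the barrier's migration prior mean.
#'
#' @param name preset name (see [preset_scenarios()]).
#' @param n_sims,n_accept reference-table sizes (desk-scale defaults
#'   50,000 and 500).
#' @return a [hyper_prior()].
#' @export
preset_prior <- function(name, n_sims = 50000, n_accept = 500) {
  tr <- preset_scenarios(name)
  hyper_prior(Y = tr$Y, tau_max = 3, theta_max = 0.01,
              mig_mean = attr(tr, "mig_prior_mean"),
              n_sims = n_sims, n_accept = n_accept, kappa = tr$kappa)
}
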