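#' One taxon pair: two population samples across a barrier
#'
#' Container for a single species' aligned sequences split into the two
#' population samples flanking a named barrier, plus locus metadata.
#' Within-population statistics need at least 2 sequences per side;
#' smaller samples are allowed but flagged with a warning and yield `NA`
#' for the affected statistics.
#'
#' @param pair_id,barrier_id labels.
#' @param pop1_seqs,pop2_seqs aligned sequences (see [encode_alignment()]).
#' @param rate_multiplier dimensionless locus rate scaling; the package
#'   convention is 20 for mtDNA and 1 for cpDNA/ITS.
#' @param locus_type optional label (`"mtDNA"`, `"cpDNA"`, `"ITS"`, ...).
#' @return object of class `taxon_pair` with elements `pop1`, `pop2`
#'   (integer code matrices), `pair_id`, `barrier_id`, `L`, `n1`, `n2`,
#'   `rate_multiplier`, `locus_type`.
#' @export
taxon_pair_data <- function(pair_id, barrier_id, pop1_seqs, pop2_seqs,
                            rate_multiplier = 1, locus_type = NA_character_) {
  m1 <- .as_code_matrix(pop1_seqs, paste0(pair_id, "/pop1"))
  m2 <- .as_code_matrix(pop2_seqs, paste0(pair_id, "/pop2"))
  if (ncol(m1) != ncol(m2))
    stop("pair ", pair_id, ": population alignments differ in length (",
         ncol(m1), " vs ", ncol(m2), ")", call. = FALSE)
  if (!is.numeric(rate_multiplier) || rate_multiplier <= 0)
    stop("pair ", pair_id, ": rate_multiplier must be > 0", call. = FALSE)
  if (nrow(m1) < 2L || nrow(m2) < 2L)
    warning("pair ", pair_id, ": a population has fewer than 2 sequences; ",
            "its within-population statistics are undefined")
  structure(list(pair_id = as.character(pair_id),
                 barrier_id = as.character(barrier_id),
                 pop1 = m1, pop2 = m2,
                 L = ncol(m1), n1 = nrow(m1), n2 = nrow(m2),
                 rate_multiplier = rate_multiplier,
                 locus_type = locus_type),
            class = "taxon_pair")
}

#' @export
print.taxon_pair <- function(x, ...) {
  cat("<taxon_pair> ", x$pair_id, " (barrier ", x$barrier_id, ")\n",
      "  n1 = ", x$n1, ", n2 = ", x$n2, ", L = ", x$L,
      ", rate multiplier = ", x$rate_multiplier, "\n", sep = "")
  invisible(x)
}

# per-pair metadata table consumed by the simulation engine
#' Pair metadata table for a study
#'
#' Condenses a list of [taxon_pair_data()] objects (or a
#' [study_truth()]) into the metadata the simulator needs: sample sizes,
#' locus length and rate multiplier per pair.
#'
#' @param study list of `taxon_pair` objects or a `study_truth`.
#' @return data.frame with columns `pair_id`, `n1`, `n2`, `L`,
#'   `rate_multiplier`.
#' @export
pair_meta <- function(study) {
  if (inherits(study, "study_truth")) {
    return(data.frame(pair_id = study$pair_id, n1 = study$n1, n2 = study$n2,
                      L = study$L, rate_multiplier = study$rate_multiplier,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.list(study), all(vapply(study, inherits, TRUE, "taxon_pair")))
  data.frame(pair_id = vapply(study, `[[`, "", "pair_id"),
             n1 = vapply(study, `[[`, 0L, "n1"),
             n2 = vapply(study, `[[`, 0L, "n2"),
             L = vapply(study, `[[`, 0L, "L"),
             rate_multiplier = vapply(study, `[[`, 0, "rate_multiplier"),
             stringsAsFactors = FALSE)
}
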