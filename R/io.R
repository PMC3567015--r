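# Formats and configuration: FASTA + manifest input, TSV/JSON outputs,
# flat key=value config. Output headers carry the statistic-vector
# layout version so downstream files are self-describing.

.STATS_SCHEMA <- "codiverge-stats-v1"

.MANIFEST_COLS <- c("pair_id", "barrier_id", "fasta_path", "sequence_id",
                    "population", "locus_type")

#' Read a multi-pair study from a manifest
#'
#' The manifest is a TSV with columns `pair_id`, `barrier_id`,
#' `fasta_path` (relative to the manifest), `sequence_id`,
#' `population` (1 or 2), `locus_type` and optionally
#' `rate_multiplier` (defaults: 20 for mtDNA, 1 otherwise). Sequences
#' are read from the FASTA files, uppercased (U read as T), and
#' validated: unknown population codes, duplicated or missing sequence
#' ids, length mismatches within a pair and disallowed characters are
#' each a located error; a side with fewer than 2 sequences is a
#' warning and its within-population statistics are `NA`.
#'
#' @param manifest_path path to the manifest TSV.
#' @return named list of [taxon_pair_data()] objects, with the manifest
#'   attached as attribute `"manifest"` and a per-pair size report as
#'   attribute `"report"`.
#' @export
read_study <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- read.delim(manifest_path, stringsAsFactors = FALSE,
                    comment.char = "#")
  missing_cols <- setdiff(.MANIFEST_COLS, names(man))
  if (length(missing_cols) > 0L)
    stop("manifest ", manifest_path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(man$population %in% c(1L, 2L))) {
    bad <- which(!(man$population %in% c(1L, 2L)))[1L]
    stop("manifest row ", bad, " (sequence ", man$sequence_id[bad],
         "): unknown population code '", man$population[bad],
         "' (must be 1 or 2)", call. = FALSE)
  }
  dup <- duplicated(man[, c("pair_id", "sequence_id")])
  if (any(dup)) {
    bad <- which(dup)[1L]
    stop("manifest row ", bad, ": sequence ", man$sequence_id[bad],
         " assigned more than once within pair ", man$pair_id[bad],
         call. = FALSE)
  }
  if (is.null(man$rate_multiplier))
    man$rate_multiplier <- NA_real_
  man$rate_multiplier <- ifelse(
    is.na(man$rate_multiplier),
    ifelse(man$locus_type == "mtDNA", 20, 1),
    man$rate_multiplier)

  base <- dirname(normalizePath(manifest_path))
  fasta_cache <- new.env(parent = emptyenv())
  get_fasta <- function(path) {
    if (!is.null(fasta_cache[[path]])) return(fasta_cache[[path]])
    full <- if (file.exists(path)) path else file.path(base, path)
    if (!file.exists(full))
      stop("FASTA file not found: ", path, call. = FALSE)
    bin <- ape::read.FASTA(full)
    seqs <- toupper(vapply(as.character(as.list(bin)),
                           paste, "", collapse = ""))
    names(seqs) <- names(bin)
    fasta_cache[[path]] <- seqs
    seqs
  }

  pair_ids <- unique(man$pair_id)
  study <- vector("list", length(pair_ids))
  names(study) <- pair_ids
  for (pid in pair_ids) {
    rows <- man[man$pair_id == pid, ]
    seqs <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      fa <- get_fasta(rows$fasta_path[i])
      sid <- rows$sequence_id[i]
      if (!(sid %in% names(fa)))
        stop("pair ", pid, ": sequence id '", sid, "' not found in ",
             rows$fasta_path[i], call. = FALSE)
      seqs[i] <- fa[[sid]]
    }
    names(seqs) <- rows$sequence_id
    mult <- unique(rows$rate_multiplier)
    if (length(mult) > 1L)
      stop("pair ", pid, ": inconsistent rate_multiplier values",
           call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("pair ", pid, ": aligned sequence lengths differ (",
           paste(unique(lens), collapse = ", "), "); offending ids: ",
           paste(names(seqs)[lens != lens[1]], collapse = ", "),
           call. = FALSE)
    study[[pid]] <- taxon_pair_data(
      pid, rows$barrier_id[1],
      seqs[rows$population == 1L], seqs[rows$population == 2L],
      rate_multiplier = mult, locus_type = rows$locus_type[1])
  }
  report <- pair_meta(study)
  attr(study, "manifest") <- man
  attr(study, "report") <- report
  study
}

#' Write observed statistics as TSV
#'
#' One row per pair: the eight summary statistics of
#' [pair_summary_vector()] plus the Tamura-Nei distance summary
#' (`Dx`, `Dy`, `Dxy`, `Da`). A TN93 saturation failure for a pair is
#' downgraded to a warning and `NA` in the table. The header comment
#' carries the statistic-vector schema version.
#'
#' @param study list of [taxon_pair_data()] objects.
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_study_stats <- function(study, path) {
  rows <- lapply(study, function(p) {
    sv <- pair_summary_vector(p)
    ds <- tryCatch(distance_summary(p), error = function(e) {
      warning("pair ", p$pair_id, ": ", conditionMessage(e))
      c(Dx = NA_real_, Dy = NA_real_, Dxy = NA_real_, Da = NA_real_)
    })
    data.frame(pair_id = p$pair_id, barrier_id = p$barrier_id,
               n1 = p$n1, n2 = p$n2, L = p$L,
               rate_multiplier = p$rate_multiplier,
               t(sv), t(ds), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .STATS_SCHEMA), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(tab)
}

#' Write a posterior summary as JSON
#'
#' @param post a [summarize_posterior()] result.
#' @param path output file.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "posterior_summary"))
  prior <- post$provenance$prior
  x <- list(schema = "codiverge-posterior-v1",
            psi_mode = post$psi_mode, psi_mean = post$psi_mean,
            psi_posterior = as.numeric(post$psi_posterior),
            omega_mode = post$omega_mode, omega_mean = post$omega_mean,
            omega_q025 = post$omega_q025, omega_q975 = post$omega_q975,
            e_tau_mean = post$e_tau_mean, n_accept = post$n_accept,
            adjusted = post$adjusted,
            seed = post$provenance$seed,
            n_sims_total = post$provenance$n_sims_total,
            prior = if (!is.null(prior)) unclass(prior))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back a posterior summary JSON
#'
#' @param path file written by [write_posterior()].
#' @return object of class `posterior_summary`.
#' @export
read_posterior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(psi_mode = as.integer(x$psi_mode), psi_mean = x$psi_mean,
                 psi_posterior = structure(x$psi_posterior,
                   names = seq_along(x$psi_posterior)),
                 omega_mode = x$omega_mode, omega_mean = x$omega_mean,
                 omega_q025 = x$omega_q025, omega_q975 = x$omega_q975,
                 e_tau_mean = x$e_tau_mean,
                 n_accept = as.integer(x$n_accept),
                 adjusted = isTRUE(x$adjusted),
                 provenance = list(seed = x$seed,
                                   n_sims_total = x$n_sims_total,
                                   prior = x$prior)),
            class = "posterior_summary")
}

# key=value comment header shared by the checkpoint TSVs
.write_tsv_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, "=", meta[[k]]), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

.read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", lines), "=", fixed = TRUE)
  kv <- kv[lengths(kv) == 2L]
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) p[2] else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

#' Checkpoint a co-divergence fit
#'
#' Writes `sim_table.tsv`, `accepted.tsv`, `observed.tsv` and
#' `posterior.json` under `dir`. The TSV headers echo the prior so each
#' file is interpretable on its own.
#'
#' @param fit a [test_codivergence()] result.
#' @param dir output directory (created if needed).
#' @export
write_fit_checkpoint <- function(fit, dir) {
  stopifnot(inherits(fit, "codiverge_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prior <- fit$prior
  meta <- list(schema = "codiverge-simtable-v1",
               psi_max = prior$psi_max, tau_max = prior$tau_max,
               theta_max = prior$theta_max, theta_min = prior$theta_min,
               theta_ref = prior$theta_ref, mig_mean = prior$mig_mean,
               kappa = prior$kappa,
               seed = fit$seed %||% "NA")
  .write_tsv_with_meta(as.data.frame(fit$sim_table),
                       file.path(dir, "sim_table.tsv"), meta)
  .write_tsv_with_meta(as.data.frame(fit$accepted),
                       file.path(dir, "accepted.tsv"), meta)
  .write_tsv_with_meta(
    data.frame(statistic = names(fit$obs), value = unname(fit$obs)),
    file.path(dir, "observed.tsv"), meta)
  write_posterior(fit$posterior, file.path(dir, "posterior.json"))
  invisible(dir)
}

#' Read back an accepted-draws checkpoint
#'
#' Restores enough structure (`psi_max`, `tau_max` from the header) for
#' [summarize_posterior()] to reproduce the checkpointed posterior.
#'
#' @param path `accepted.tsv` written by [write_fit_checkpoint()].
#' @return data.frame of class `abc_accepted`.
#' @export
read_accepted <- function(path) {
  meta <- .read_tsv_meta(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "prior") <- list(psi_max = as.integer(meta$psi_max),
                            tau_max = meta$tau_max)
  class(df) <- c("abc_accepted", "data.frame")
  df
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that
#' parse as numbers are returned numeric. Keys carry their units where
#' relevant (e.g. `tau_max_4Nref_units`) so the scaling convention
#' travels with every result.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("config ", path, ": cannot parse line '", lines[which(bad)[1]],
         "'", call. = FALSE)
  out <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), "")
  out
}

#' Build a hyperprior from a configuration list
#'
#' Recognised keys: `tau_max_4Nref_units`, `theta_max`, `theta_min`,
#' `theta_anc_ratio`, `mig_mean`, `n_sims`, `n_accept`, `kappa`,
#' `psi_max`. Missing keys fall back to the [hyper_prior()] defaults.
#'
#' @param cfg list from [read_config()].
#' @param Y number of taxon pairs.
#' @return a [hyper_prior()].
#' @export
hyper_prior_from_config <- function(cfg, Y) {
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  hyper_prior(Y = Y,
              psi_max = pick("psi_max", Y),
              tau_max = pick("tau_max_4Nref_units", 3),
              theta_max = pick("theta_max", 0.15816),
              theta_min = pick("theta_min", 1e-4),
              theta_anc_ratio = pick("theta_anc_ratio", 0.5),
              mig_mean = pick("mig_mean", 0),
              n_sims = pick("n_sims", 1e6),
              n_accept = pick("n_accept", 2000),
              kappa = pick("kappa", 4))
}
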