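# Internal alignment handling. Sequences travel as character strings or
# character matrices; statistics work on an integer encoding
# (A=1, C=2, G=3, T=4, NA for N or gap). U is mapped to T; ambiguity
# codes other than N are rejected with their location.

.BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L, N = NA_integer_,
                 "-" = NA_integer_)
.BASE_CHARS <- c("A", "C", "G", "T")

#' Encode aligned sequences as an integer matrix
#'
#' Accepts a character vector of equal-length strings, a single-character
#' matrix (sequences in rows), or an `ape::DNAbin` object. Returns an
#' integer matrix with codes A=1, C=2, G=3, T=4 and `NA` for N or gap.
#' Lowercase input is accepted; U is read as T; IUPAC ambiguity codes
#' other than N are an error that names the sequence and site.
#'
#' @param seqs sequences (character vector, character matrix, or DNAbin).
#' @param what label used in error messages.
#' @return integer matrix, one row per sequence, with `rownames` carrying
#'   sequence ids when available.
#' @export
encode_alignment <- function(seqs, what = "alignment") {
  if (inherits(seqs, "DNAbin")) {
    seqs <- toupper(sapply(as.character(as.list(seqs)), paste, collapse = ""))
  }
  if (is.matrix(seqs)) {
    chars <- toupper(seqs)
  } else {
    if (!is.character(seqs))
      stop(what, ": sequences must be character strings", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop(what, ": sequences differ in length (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    chars <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE))),
                    nrow = length(seqs), byrow = TRUE)
    rownames(chars) <- names(seqs)
  }
  codes <- .BASE_CODES[chars]
  bad <- !(chars %in% names(.BASE_CODES))
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(chars) + 1L
    s <- (idx - 1L) %/% nrow(chars) + 1L
    id <- if (!is.null(rownames(chars))) rownames(chars)[r] else paste0("#", r)
    stop(what, ": disallowed character '", chars[idx], "' in sequence ", id,
         " at site ", s, " (only A/C/G/T/U/N/- are accepted)", call. = FALSE)
  }
  out <- matrix(codes, nrow = nrow(chars))
  rownames(out) <- rownames(chars)
  out
}

# integer codes -> character strings
.decode_alignment <- function(mat) {
  chars <- matrix(ifelse(is.na(mat), "N", .BASE_CHARS[mat]), nrow = nrow(mat))
  out <- apply(chars, 1L, paste, collapse = "")
  names(out) <- rownames(mat)
  out
}

.as_code_matrix <- function(seqs, what = "alignment") {
  if (is.matrix(seqs) && is.integer(seqs)) return(seqs)
  encode_alignment(seqs, what = what)
}
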