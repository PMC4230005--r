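# Numerical encoding of protein sequences and FASTA input.

#' Encode a protein sequence as a numerical sequence
#'
#' Replaces each residue by its total score. Input is uppercased and
#' whitespace-stripped first. By default any symbol outside the 20-letter
#' alphabet (ambiguity codes B/Z/X, U, gaps, stops) is an error reporting
#' the position; with `on_invalid = "drop"` such positions are removed with
#' a warning (note that dropping shifts positions and therefore changes the
#' geometry of any downstream diagram).
#'
#' @param residues Protein sequence, a single character string.
#' @param id Sequence identifier (free text).
#' @param scores Symbol-to-score mapping, default [aa_score_table()].
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return An object of class `"numerical_sequence"`: list with `id`,
#'   `residues` (cleaned string) and `scores` (numeric vector of the same
#'   length).
#' @export
#' @examples
#' s <- encode_sequence("MTMHTTMTTL", id = "Hu")
#' round(s$scores, 4)
encode_sequence <- function(residues, id = "seq", scores = aa_score_table(),
                            on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(res) == 0L) {
    stop("empty sequence", if (nzchar(id)) paste0(" '", id, "'"),
         call. = FALSE)
  }
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(scores))
  if (length(bad)) {
    if (on_invalid == "error") {
      stop(sprintf(
        "invalid residue '%s' at position %d in sequence '%s'",
        chars[bad[1]], bad[1], id), call. = FALSE)
    }
    warning(sprintf(
      "dropping %d invalid residue(s) from sequence '%s' (positions %s)",
      length(bad), id, paste(utils::head(bad, 10), collapse = ",")),
      call. = FALSE)
    chars <- chars[-bad]
    if (!length(chars)) stop("sequence '", id, "' empty after dropping ",
                             "invalid residues", call. = FALSE)
    res <- paste(chars, collapse = "")
  }
  structure(list(id = id, residues = res,
                 scores = unname(scores[chars])),
            class = "numerical_sequence")
}

#' @export
print.numerical_sequence <- function(x, digits = 4, ...) {
  n <- length(x$scores)
  cat(sprintf("Numerical sequence '%s' (%d residues)\n", x$id, n))
  k <- min(n, 10L)
  cat("  ", substr(x$residues, 1, k), if (n > k) "...", "\n")
  cat("  ", paste(round(x$scores[seq_len(k)], digits), collapse = " "),
      if (n > k) "...", "\n")
  invisible(x)
}

#' @export
length.numerical_sequence <- function(x) length(x$scores)

# coerce character / numerical_sequence inputs uniformly
as_numerical_sequence <- function(x, id = "seq") {
  if (inherits(x, "numerical_sequence")) return(x)
  encode_sequence(x, id = id)
}

#' Read protein sequences from a FASTA file
#'
#' Wraps line-unwrapping FASTA parsing (via Biostrings). Records keep file
#' order; duplicate identifiers are disambiguated with a numeric suffix and
#' a warning; empty records are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = record identifiers,
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) ids[!nzchar(ids)] <- "unnamed"
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids in ", path,
            "; disambiguating with numeric suffixes", call. = FALSE)
    ids <- make.unique(ids, sep = "_")
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Encode every record of a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param ... Passed on to [encode_sequence()].
#' @return Named list of `numerical_sequence` objects, in file order.
#' @export
encode_fasta <- function(path, ...) {
  seqs <- read_fasta(path)
  out <- lapply(seq_along(seqs), function(i) {
    encode_sequence(seqs[[i]], id = names(seqs)[i], ...)
  })
  names(out) <- names(seqs)
  out
}
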