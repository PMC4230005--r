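# Pairwise similarity degrees -> matching matrix -> distance matrix.

# normalize heterogeneous inputs to a named list of numerical_sequence
as_sequence_list <- function(seqs) {
  if (inherits(seqs, "numerical_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    seqs <- lapply(seq_along(seqs),
                   function(i) encode_sequence(seqs[[i]], id = ids[i]))
    names(seqs) <- ids
    return(seqs)
  }
  stopifnot(is.list(seqs), length(seqs) >= 1L)
  seqs <- lapply(seq_along(seqs), function(i) {
    id <- if (!is.null(names(seqs)) && nzchar(names(seqs)[i]))
      names(seqs)[i] else paste0("seq", i)
    as_numerical_sequence(seqs[[i]], id = id)
  })
  names(seqs) <- vapply(seqs, `[[`, "", "id")
  seqs
}

#' Matching matrix of a sequence collection
#'
#' Lower-triangular matrix (diagonal included) of pairwise similarity
#' degrees d_ij = SD(i, j); the diagonal d_ii is each sequence's similarity
#' degree against itself (including any by-path fragments arising from
#' internal repeats). The upper triangle is 0 by convention.
#'
#' @param seqs Sequences: a named character vector, a list of strings, or a
#'   list of `numerical_sequence` objects.
#' @param params [alignment_params()].
#' @return Integer n x n matrix with id dimnames.
#' @export
matching_matrix <- function(seqs, params = alignment_params()) {
  seqs <- as_sequence_list(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      d[i, j] <- similarity_degree(
        adld(seqs[[i]], seqs[[j]], params = params))
    }
  }
  d
}

#' Similarity/dissimilarity matrix from a matching matrix
#'
#' Converts similarity degrees to distances: s_ij = 1 - min(1, d_ij / d_ii)
#' for i >= j (0 above the diagonal). 0 means identical; 1 means no shared
#' fragments or free points at all. The row normalizer is the row sequence's
#' self-degree d_ii (`normalize = "row"`, the definition); `normalize =
#' "min"` divides by min(d_ii, d_jj) instead, a symmetric variant that is
#' not part of the published definition.
#'
#' @param matching Matrix from [matching_matrix()].
#' @param normalize `"row"` (default) or `"min"`.
#' @return Numeric n x n lower-triangular matrix, entries in \[0, 1\],
#'   zero diagonal.
#' @export
similarity_matrix <- function(matching, normalize = c("row", "min")) {
  normalize <- match.arg(normalize)
  d <- as.matrix(matching)
  n <- nrow(d)
  dii <- diag(d)
  if (any(dii <= 0)) {
    bad <- rownames(d)[dii <= 0]
    stop("degenerate sequence(s) with zero self similarity degree: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- matrix(0, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      norm <- if (normalize == "row") dii[i] else min(dii[i], dii[j])
      s[i, j] <- 1 - min(1, d[i, j] / norm)
    }
  }
  s
}

#' Distance analysis of a protein sequence collection
#'
#' End-to-end convenience: encodes the sequences, computes all pairwise
#' diagrams and similarity degrees, and derives the similarity/dissimilarity
#' matrix.
#'
#' @inheritParams matching_matrix
#' @param epsilon,delta,xi Tuning parameters (ignored when `params` given).
#' @param params Optional prebuilt [alignment_params()].
#' @param normalize See [similarity_matrix()].
#' @return Object of class `"adld_sm"`: list with `ids`, `matching`,
#'   `distances` and `params`.
#' @export
#' @examples
#' sm <- adld_distances(c(Hu = "MTMHTTMTTL", Gor = "MTMYATMTTL"))
#' sm$distances
adld_distances <- function(seqs, epsilon = 0, delta = 3, xi = 10,
                           params = NULL, normalize = c("row", "min")) {
  if (is.null(params)) params <- alignment_params(epsilon, delta, xi)
  seqs <- as_sequence_list(seqs)
  d <- matching_matrix(seqs, params)
  s <- similarity_matrix(d, normalize = normalize)
  structure(list(ids = names(seqs), matching = d, distances = s,
                 params = params),
            class = "adld_sm")
}

#' @export
print.adld_sm <- function(x, digits = 4, ...) {
  cat(sprintf("ADLD similarity/dissimilarity matrix (%d sequences)\n",
              length(x$ids)))
  cat(sprintf("  epsilon = %g, delta = %d, xi = %d\n",
              x$params$epsilon, x$params$delta, x$params$xi))
  print(round(x$distances, digits))
  invisible(x)
}

#' @export
as.matrix.adld_sm <- function(x, ...) x$distances

#' Symmetrized distance object
#'
#' Mirrors the lower triangle of the distance matrix into a symmetric
#' [stats::dist] object for downstream tools (clustering, tree building).
#'
#' @param m An `adld_sm` object.
#' @param ... Unused.
#' @return A `dist` object.
#' @export
as.dist.adld_sm <- function(m, ...) {
  s <- m$distances
  full <- s + t(s)
  diag(full) <- 0
  stats::as.dist(full)
}

#' Write a distance matrix as CSV
#'
#' Square layout with id header row and column; lower triangle populated,
#' values rounded for report purposes only.
#'
#' @param sm An `adld_sm` object or a square matrix with dimnames.
#' @param path Output path.
#' @param digits Report precision (default 4).
#' @export
write_sm_csv <- function(sm, path, digits = 4) {
  s <- if (inherits(sm, "adld_sm")) sm$distances else as.matrix(sm)
  df <- data.frame(id = rownames(s), round(s, digits),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance matrix in PHYLIP lower-triangular format
#'
#' Sequence count on the first line, then one row per id: the id followed by
#' the distances to all previous ids. The lower triangle is mirrored, so the
#' written matrix is symmetric by construction.
#'
#' @inheritParams write_sm_csv
#' @export
write_phylip <- function(sm, path, digits = 4) {
  s <- if (inherits(sm, "adld_sm")) sm$distances else as.matrix(sm)
  ids <- rownames(s)
  lines <- c(sprintf("%5d", nrow(s)),
             vapply(seq_len(nrow(s)), function(i) {
               vals <- if (i > 1)
                 paste(formatC(s[i, seq_len(i - 1)], digits = digits,
                               format = "f"), collapse = " ")
               else ""
               trimws(sprintf("%-10s %s", gsub("\\s+", "_", ids[i]), vals),
                      which = "right")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
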