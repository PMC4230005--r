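# Neighbor-joining tree construction and Newick export.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric
#' distance matrix, or on an `adld_sm` object (whose lower triangle is
#' mirrored first). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to 0 with a message.
#'
#' @param distances An `adld_sm` object, a `dist`, or a symmetric numeric
#'   matrix with zero diagonal and id dimnames.
#' @param ids Optional leaf labels overriding the matrix dimnames.
#' @return An unrooted tree of class `"phylo"`.
#' @export
#' @examples
#' m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(m)
neighbor_joining <- function(distances, ids = NULL) {
  if (inherits(distances, "adld_sm")) {
    d <- as.matrix(stats::as.dist(distances))
  } else if (inherits(distances, "dist")) {
    d <- as.matrix(distances)
  } else {
    d <- as.matrix(distances)
    if (!isSymmetric(unname(d), tol = 1e-12)) {
      stop("neighbor_joining() requires a symmetric distance matrix ",
           "(mirror the lower triangle first)", call. = FALSE)
    }
  }
  if (nrow(d) < 3L) {
    stop("neighbor joining needs at least 3 sequences", call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("seq", seq_len(nrow(d))),
                        paste0("seq", seq_len(nrow(d))))
  }
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    message("neighbor_joining: clamping ",
            sum(tree$edge.length < 0), " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

.newick_label <- function(lab) {
  if (grepl("[][(),:;'\"[:space:]]", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Write a tree in Newick format
#'
#' Serializes with branch lengths and a terminating semicolon. Leaf labels
#' containing Newick metacharacters or whitespace are single-quoted (quotes
#' themselves doubled), so labels like `"fin whale"` survive verbatim.
#'
#' @param tree A `"phylo"` tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(k) {
    if (is.null(tree$edge.length)) "" else
      paste0(":", sprintf("%.10g", tree$edge.length[k]))
  }
  rec <- function(k) {
    child <- tree$edge[k, 2]
    if (child <= ntip) {
      paste0(.newick_label(tree$tip.label[child]), fmt_len(k))
    } else {
      paste0("(", paste(vapply(kids[[as.character(child)]], rec, ""),
                        collapse = ","), ")", fmt_len(k))
    }
  }
  root <- ntip + 1L
  txt <- paste0("(", paste(vapply(kids[[as.character(root)]], rec, ""),
                           collapse = ","), ");")
  writeLines(txt, path)
  invisible(path)
}

#' Read a tree from a Newick file
#'
#' @param path Path to a Newick file.
#' @return A `"phylo"` tree (quoted labels unquoted).
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  tree$tip.label <- gsub("''", "'",
                         sub("^'(.*)'$", "\\1", tree$tip.label))
  tree
}
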