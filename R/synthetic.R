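# Controlled synthetic sequences and edit recipes for method experiments.

# run code under a fixed seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Random protein sequence
#'
#' Residues drawn uniformly from the 20-letter alphabet; reproducible for a
#' given seed and independent of the caller's RNG state.
#'
#' @param length Number of residues (>= 1).
#' @param seed Integer seed.
#' @return Character string of `length` residues.
#' @export
random_sequence <- function(length, seed) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  with_seed(seed, paste(sample(aa_alphabet(), length, replace = TRUE),
                        collapse = ""))
}

#' Edit recipe
#'
#' An ordered list of edits to apply to a sequence: substitutions (length
#' preserving; the replacement must differ from the original residue),
#' insertions and deletions. Positions refer to the sequence state at
#' application time (edits are applied left to right in list order).
#'
#' @param ... Edits built with [edit_sub()], [edit_ins()], [edit_del()].
#' @return List of class `"edit_recipe"`.
#' @export
#' @examples
#' r <- edit_recipe(edit_sub(3, "W"), edit_ins(5, "AGG"))
edit_recipe <- function(...) {
  edits <- list(...)
  ok <- vapply(edits, function(e)
    is.list(e) && e$kind %in% c("substitute", "insert", "delete"), TRUE)
  if (!all(ok)) stop("edits must be built with edit_sub/edit_ins/edit_del",
                     call. = FALSE)
  structure(edits, class = "edit_recipe")
}

.check_payload <- function(payload) {
  chars <- strsplit(toupper(payload), "", fixed = TRUE)[[1]]
  if (!length(chars) || !all(chars %in% aa_alphabet())) {
    stop("payload must be nonempty and use the 20-letter alphabet",
         call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' @rdname edit_recipe
#' @param position 1-based position of the edit.
#' @param payload Replacement residue (substitute) or inserted residues.
#' @export
edit_sub <- function(position, payload) {
  payload <- .check_payload(payload)
  if (nchar(payload) != 1L) stop("substitute takes a single residue",
                                 call. = FALSE)
  list(kind = "substitute", position = as.integer(position),
       payload = payload)
}

#' @rdname edit_recipe
#' @export
edit_ins <- function(position, payload) {
  list(kind = "insert", position = as.integer(position),
       payload = .check_payload(payload))
}

#' @rdname edit_recipe
#' @param n Number of residues to delete.
#' @export
edit_del <- function(position, n = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("deletion length must be >= 1", call. = FALSE)
  list(kind = "delete", position = as.integer(position), n = n)
}

#' Apply an edit recipe to a sequence
#'
#' @param residues Character string over the 20-letter alphabet.
#' @param recipe An [edit_recipe()].
#' @return Edited character string.
#' @export
#' @examples
#' apply_recipe("MTMHTTMTTL", edit_recipe(edit_sub(4, "Y")))
apply_recipe <- function(residues, recipe) {
  stopifnot(inherits(recipe, "edit_recipe"))
  s <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  for (e in recipe) {
    p <- e$position
    if (e$kind == "substitute") {
      if (p < 1L || p > length(s)) stop("substitute position ", p,
                                        " out of range", call. = FALSE)
      if (s[p] == e$payload) {
        stop("substitution at position ", p,
             " must change the residue (already '", e$payload, "')",
             call. = FALSE)
      }
      s[p] <- e$payload
    } else if (e$kind == "insert") {
      if (p < 1L || p > length(s) + 1L) stop("insert position ", p,
                                             " out of range", call. = FALSE)
      ins <- strsplit(e$payload, "", fixed = TRUE)[[1]]
      s <- append(s, ins, after = p - 1L)
    } else {
      if (p < 1L || p + e$n - 1L > length(s)) stop("delete range out of ",
                                                   "range", call. = FALSE)
      s <- s[-(p:(p + e$n - 1L))]
      if (!length(s)) stop("recipe deletes the whole sequence",
                           call. = FALSE)
    }
  }
  paste(s, collapse = "")
}

#' Random substitution payload differing from the current residue
#'
#' Convenience for building recipes: picks, reproducibly, a residue
#' different from the one currently at `position`.
#'
#' @param residues Sequence string.
#' @param position Position to substitute at.
#' @param seed Integer seed.
#' @return An edit as produced by [edit_sub()].
#' @export
random_sub <- function(residues, position, seed) {
  cur <- substr(residues, position, position)
  pool <- setdiff(aa_alphabet(), cur)
  edit_sub(position, with_seed(seed, sample(pool, 1L)))
}

#' Write a synthetic pair to FASTA
#'
#' Generates a random sequence, applies a recipe, and writes the original
#' and edited sequences as a two-record FASTA file.
#'
#' @param length Base sequence length.
#' @param seed Integer seed.
#' @param recipe An [edit_recipe()] (default: empty, identical pair).
#' @param path Output FASTA path.
#' @return Named character vector of the two sequences, invisibly.
#' @export
write_synthetic_pair <- function(length, seed, recipe = edit_recipe(),
                                 path) {
  base <- random_sequence(length, seed)
  edited <- apply_recipe(base, recipe)
  out <- c(original = base, edited = edited)
  writeLines(c(">original", base, ">edited", edited), path)
  invisible(out)
}
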