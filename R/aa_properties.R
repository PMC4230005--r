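#' @keywords internal
"_PACKAGE"

# package-level cache (property table, score table)
.adld_cache <- new.env(parent = emptyenv())

#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes of the standard amino acids, in the canonical
#' (alphabetical) order used throughout the package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.aa_property_names <- c("mW", "hI", "pK1", "pK2", "pI", "S", "cN", "F", "vR")

#' Physicochemical property table of the 20 amino acids
#'
#' Loads the packaged 20 x 9 table of amino-acid properties: molecular weight
#' (`mW`, Da), hydropathy index (`hI`), pKa of the carboxyl group (`pK1`),
#' pKa of the amino group (`pK2`), isoelectric point (`pI`), solubility
#' (`S`, g/L), number of triplet codons (`cN`), frequency in human proteins
#' (`F`, percent) and van der Waals radius of the side chain (`vR`, pm).
#' Rows are keyed strictly by one-letter symbol; the full amino-acid names
#' are informational metadata only.
#'
#' The table is validated on first load (dimensions, symbol set, finiteness,
#' codon counts) and cached for the session.
#'
#' @return A data frame with columns `symbol`, `name` and the 9 numeric
#'   property columns; 20 rows in canonical symbol order, row names = symbols.
#' @export
#' @examples
#' tab <- aa_property_table()
#' tab["W", "mW"]
aa_property_table <- function() {
  if (!is.null(.adld_cache$property_table)) {
    return(.adld_cache$property_table)
  }
  path <- system.file("extdata", "amino_acid_properties.csv",
                      package = "adld", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_property_table(tab)
  rownames(tab) <- tab$symbol
  .adld_cache$property_table <- tab
  tab
}

.validate_property_table <- function(tab) {
  expected_cols <- c("symbol", "name", .aa_property_names)
  if (!identical(names(tab), expected_cols)) {
    stop("corrupted amino-acid property data: column header mismatch",
         call. = FALSE)
  }
  if (nrow(tab) != 20L || !identical(tab$symbol, aa_alphabet())) {
    stop("corrupted amino-acid property data: expected the 20 standard ",
         "amino acids in canonical order", call. = FALSE)
  }
  vals <- as.matrix(tab[, .aa_property_names])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("corrupted amino-acid property data: non-finite entries",
         call. = FALSE)
  }
  if (!all(vals[, "cN"] %in% c(1, 2, 3, 4, 6))) {
    stop("corrupted amino-acid property data: invalid codon counts",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Property matrix of the amino acids
#'
#' The 20 x 9 numeric matrix of amino-acid properties, rows in canonical
#' symbol order and columns in the fixed property order
#' (mW, hI, pK1, pK2, pI, S, cN, F, vR). This matrix is the input of the
#' principal component scoring pipeline.
#'
#' @param table Property table as returned by [aa_property_table()].
#' @return Numeric 20 x 9 matrix with symbol row names and property column
#'   names.
#' @export
#' @examples
#' X <- property_matrix()
#' X["G", "mW"]
property_matrix <- function(table = aa_property_table()) {
  .validate_property_table(table)
  m <- as.matrix(table[, .aa_property_names])
  rownames(m) <- table$symbol
  m
}
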