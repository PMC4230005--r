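# PCA scoring pipeline: property matrix -> one total score per amino acid.

#' Column-standardize a property matrix
#'
#' Centers every column to mean 0 and scales to sample standard deviation 1
#' (divisor m - 1 over the m = 20 amino acids).
#'
#' @param X Numeric matrix (rows = samples, columns = variables).
#' @return Matrix of the same shape with standardized columns.
#' @export
standardize_properties <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("degenerate input: constant column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Correlation matrix of the property columns
#'
#' Pearson correlation matrix of the columns; scale-invariant, so the raw
#' and standardized property matrices give the same result.
#'
#' @param Xstar Numeric matrix (typically the standardized property matrix).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
property_correlation <- function(Xstar) {
  stats::cor(as.matrix(Xstar))
}

#' Eigendecomposition of a correlation matrix
#'
#' Eigenpairs sorted by descending eigenvalue, each eigenvector
#' sign-normalized so that its largest-magnitude component is positive
#' (eigenvectors are otherwise defined only up to sign).
#'
#' @param R Symmetric correlation matrix.
#' @return List with `values` (descending eigenvalues) and `vectors`
#'   (matrix whose k-th column is the k-th eigenvector).
#' @export
eigendecompose <- function(R) {
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-8)) {
    stop("eigendecompose() requires a symmetric matrix", call. = FALSE)
  }
  e <- eigen(R, symmetric = TRUE)   # eigen() already sorts descending
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- rownames(R)
  list(values = e$values, vectors = V)
}

#' Contribution rates of principal components
#'
#' The contribution rate of component i is its eigenvalue's share of the
#' total variance, CR_i = lambda_i / sum(lambda); the accumulated
#' contribution rate is the running sum.
#'
#' @param eigenvalues Nonnegative eigenvalues in descending order.
#' @return List with `cr` and `acr`, each a numeric vector.
#' @export
contribution_rates <- function(eigenvalues) {
  if (any(eigenvalues < -1e-12)) {
    stop("eigenvalues must be nonnegative", call. = FALSE)
  }
  total <- sum(eigenvalues)
  if (total <= 0) {
    stop("degenerate input: all eigenvalues are zero", call. = FALSE)
  }
  cr <- eigenvalues / total
  list(cr = cr, acr = cumsum(cr))
}

#' Number of components to retain
#'
#' Smallest t whose accumulated contribution rate reaches the threshold
#' (default 0.85, i.e. at least 85% of total variance retained).
#'
#' @param acr Nondecreasing accumulated contribution rates ending at 1.
#' @param threshold Retention threshold in (0, 1].
#' @return Integer t.
#' @export
select_components <- function(acr, threshold = 0.85) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  which(acr >= threshold)[1L]
}

#' Total scores of the samples
#'
#' Projects each standardized sample onto the t retained components and
#' collapses the component scores into a single number with the contribution
#' rates as weights: score_i = sum_k (x*_i . a_k) * CR_k, k = 1..t.
#'
#' @param Xstar Standardized sample matrix (rows = samples).
#' @param vectors Eigenvector matrix (columns = components).
#' @param cr Contribution rates aligned with `vectors`.
#' @param t Number of retained components (>= 1).
#' @return Named numeric vector, one score per row of `Xstar`.
#' @export
total_scores <- function(Xstar, vectors, cr, t) {
  t <- as.integer(t)
  if (t < 1L || t > ncol(vectors)) {
    stop("t must be between 1 and the number of components", call. = FALSE)
  }
  F <- as.matrix(Xstar) %*% vectors[, seq_len(t), drop = FALSE]
  drop(F %*% cr[seq_len(t)])
}

#' Principal component scoring of the 20 amino acids
#'
#' Runs the full pipeline on the packaged property table: standardize the
#' 20 x 9 matrix, form the 9 x 9 property correlation matrix, eigendecompose,
#' retain the leading components whose accumulated contribution rate reaches
#' `threshold`, and compute one total score per amino acid.
#'
#' @param table Property table, see [aa_property_table()].
#' @param threshold Variance retention threshold passed to
#'   [select_components()].
#' @return An object of class `"aa_pca"`: a list with `standardized`,
#'   `correlation`, `eigenvalues`, `eigenvectors`, `cr`, `acr`,
#'   `n_retained`, `component_scores` (20 x t) and `total_scores`
#'   (named vector over the 20 symbols).
#' @export
#' @examples
#' fit <- aa_pca()
#' fit$n_retained
#' round(fit$total_scores["M"], 4)
aa_pca <- function(table = aa_property_table(), threshold = 0.85) {
  X <- property_matrix(table)
  Xstar <- standardize_properties(X)
  R <- property_correlation(Xstar)
  e <- eigendecompose(R)
  rates <- contribution_rates(e$values)
  t <- select_components(rates$acr, threshold)
  scores <- total_scores(Xstar, e$vectors, rates$cr, t)
  Fmat <- Xstar %*% e$vectors[, seq_len(t), drop = FALSE]
  colnames(Fmat) <- paste0("F", seq_len(t))
  structure(
    list(standardized = Xstar, correlation = R,
         eigenvalues = e$values, eigenvectors = e$vectors,
         cr = rates$cr, acr = rates$acr, n_retained = t,
         component_scores = Fmat, total_scores = scores),
    class = "aa_pca")
}

#' @export
print.aa_pca <- function(x, digits = 4, ...) {
  cat("Principal component scoring of the 20 amino acids\n")
  cat("  retained components:", x$n_retained,
      sprintf("(ACR = %.4f)\n", x$acr[x$n_retained]))
  cat("  eigenvalues:", paste(round(x$eigenvalues, digits), collapse = " "),
      "\n")
  cat("  total scores:\n")
  print(round(x$total_scores, digits))
  invisible(x)
}

#' Per-residue score table
#'
#' The mapping from one-letter amino-acid symbol to its total score, computed
#' once from the packaged property table and cached. This is the encoding
#' alphabet used by [encode_sequence()].
#'
#' @return Named numeric vector of length 20 (names = symbols).
#' @export
#' @examples
#' round(aa_score_table()[c("M", "G", "W")], 4)
aa_score_table <- function() {
  if (is.null(.adld_cache$score_table)) {
    .adld_cache$score_table <- aa_pca()$total_scores
  }
  .adld_cache$score_table
}
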