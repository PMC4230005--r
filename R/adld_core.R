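# Banded alignment scatter diagram and its reduction to diagonal runs.

#' Alignment parameters
#'
#' Bundles and validates the three tuning parameters of the diagram:
#' `epsilon` (dissimilarity degree, in score units; 0 = residues must carry
#' identical scores), `delta` (minimum run length of a similar fragment, in
#' points) and `xi` (alignment-width threshold, in positions; the band
#' half-width is `xi` unless the length difference of the pair exceeds it).
#'
#' @param epsilon Nonnegative real, default 0.
#' @param delta Integer >= 1, default 3.
#' @param xi Integer >= 1, default 10.
#' @return List of class `"alignment_params"`.
#' @export
alignment_params <- function(epsilon = 0, delta = 3, xi = 10) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("epsilon must be a single nonnegative number", call. = FALSE)
  }
  delta <- as.integer(delta)
  xi <- as.integer(xi)
  if (is.na(delta) || delta < 1L) stop("delta must be >= 1", call. = FALSE)
  if (is.na(xi) || xi < 1L) stop("xi must be >= 1", call. = FALSE)
  structure(list(epsilon = epsilon, delta = delta, xi = xi),
            class = "alignment_params")
}

#' Effective alignment width of a sequence pair
#'
#' The band half-width w: equal to `xi` when the length difference
#' `n1 - n2` does not exceed `xi`, otherwise widened to `n1 - n2` so that a
#' pure length difference cannot push the whole diagram out of the band.
#'
#' @param n1,n2 Sequence lengths with `n1 >= n2`.
#' @param xi Alignment-width threshold.
#' @return Integer w.
#' @export
alignment_width <- function(n1, n2, xi) {
  if (n1 < n2) stop("alignment_width() requires n1 >= n2", call. = FALSE)
  if (n2 < 1L) stop("sequences must be nonempty", call. = FALSE)
  if (n1 - n2 <= xi) as.integer(xi) else as.integer(n1 - n2)
}

#' Banded alignment point set of a sequence pair
#'
#' Evaluates the match indicator over the diagonal band only: point (i, j)
#' is present iff `|i - j| <= w`, `j <= n2`, and the two residue scores agree
#' within `epsilon`. Positions beyond the shorter sequence (the conceptual
#' zero padding that equalizes lengths) never generate points. The full
#' n1 x n1 matrix is never materialized.
#'
#' @param s1,s2 `numerical_sequence` objects with `length(s1) >= length(s2)`.
#' @param params [alignment_params()].
#' @return Object of class `"alignment_points"`: list with `n1`, `n2`,
#'   `width`, and `points`, a two-column integer matrix of 1-based (i, j)
#'   coordinates ordered by track offset (0, +1, ..., -1, ...) then i.
#' @export
alignment_points <- function(s1, s2, params = alignment_params()) {
  n1 <- length(s1$scores)
  n2 <- length(s2$scores)
  if (n1 < 1L || n2 < 1L) stop("sequences must be nonempty", call. = FALSE)
  if (n1 < n2) {
    stop("alignment_points() requires length(s1) >= length(s2); ",
         "order the pair first", call. = FALSE)
  }
  w <- alignment_width(n1, n2, params$xi)
  offsets <- c(0L, seq_len(w), -seq_len(w))   # track order: 0, +1.., -1..
  pts <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    o <- offsets[k]
    i1 <- max(1L, 1L - o)
    i2 <- min(n1, n2 - o)
    if (i2 < i1) next
    i <- i1:i2
    hit <- abs(s1$scores[i] - s2$scores[i + o]) <= params$epsilon
    if (any(hit)) pts[[k]] <- cbind(i = i[hit], j = i[hit] + o)
  }
  points <- do.call(rbind, pts)
  if (is.null(points)) {
    points <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  }
  structure(list(n1 = n1, n2 = n2, width = w, points = points),
            class = "alignment_points")
}

#' Similar fragments: maximal diagonal runs of alignment points
#'
#' On every track (diagonal of offset o = j - i, |o| <= w), each maximal run
#' of consecutive points (unit diagonal steps, no gap tolerance) of length at
#' least `delta` becomes one similar fragment. Offset 0 is the artery track;
#' fragments there are the pair's aligned core, off-track fragments indicate
#' insertions/deletions.
#'
#' @param aps An `alignment_points` object.
#' @param delta Minimum run length.
#' @return Data frame with columns `track_offset`, `start_i`, `start_j`,
#'   `end_i`, `end_j`, `length`; ordered artery track first, then offsets
#'   +1, +2, ..., then -1, -2, ...; left to right within a track.
#' @export
extract_fragments <- function(aps, delta) {
  delta <- as.integer(delta)
  if (delta < 1L) stop("delta must be >= 1", call. = FALSE)
  pts <- aps$points
  empty <- data.frame(track_offset = integer(0), start_i = integer(0),
                      start_j = integer(0), end_i = integer(0),
                      end_j = integer(0), length = integer(0))
  if (nrow(pts) == 0L) return(empty)
  off <- pts[, "j"] - pts[, "i"]
  out <- list()
  offs <- unique(off)
  # track order 0, +1..+w, -1..-w
  offs <- offs[order(ifelse(offs >= 0L, offs, aps$width - offs))]
  for (o in offs) {
    i <- sort(pts[off == o, "i"])
    brk <- c(0L, which(diff(i) > 1L), length(i))
    for (b in seq_len(length(brk) - 1L)) {
      run <- i[(brk[b] + 1L):brk[b + 1L]]
      if (length(run) >= delta) {
        out[[length(out) + 1L]] <- data.frame(
          track_offset = o,
          start_i = run[1L], start_j = run[1L] + o,
          end_i = run[length(run)], end_j = run[length(run)] + o,
          length = length(run))
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Free points of a diagram
#'
#' Artery-track alignment points not covered by any artery fragment.
#' Off-track points outside fragments are discarded entirely; only the main
#' diagonal contributes free points.
#'
#' @param aps An `alignment_points` object.
#' @param fragments Fragment data frame from [extract_fragments()].
#' @return Increasing integer vector of positions i (the points are (i, i)).
#' @export
free_points <- function(aps, fragments) {
  pts <- aps$points
  artery <- sort(pts[pts[, "i"] == pts[, "j"], "i"])
  af <- fragments[fragments$track_offset == 0L, , drop = FALSE]
  if (nrow(af)) {
    covered <- unlist(mapply(seq, af$start_i, af$end_i, SIMPLIFY = FALSE))
    artery <- setdiff(artery, covered)
  }
  as.integer(artery)
}

#' Alignment diagonal line diagram of a protein sequence pair
#'
#' Builds the full diagram for a pair of sequences: orders the pair (longer
#' sequence first; equal lengths broken lexicographically by id), evaluates
#' the banded match-point set, extracts similar fragments (maximal diagonal
#' runs of length >= `delta`) and the free points left on the artery track.
#'
#' @param s1,s2 Protein sequences: either `numerical_sequence` objects or
#'   plain character strings (encoded with the default score table).
#' @param epsilon,delta,xi Tuning parameters, see [alignment_params()].
#' @param params Alternatively, a prebuilt `alignment_params` object
#'   (overrides the three scalars).
#' @return Object of class `"adld"`: list with `params`, `pair_ids`
#'   (longer sequence first), `n1`, `n2`, `width`, `fragments` (data frame,
#'   see [extract_fragments()]) and `free_points` (integer vector). All
#'   coordinates are 1-based.
#' @export
#' @examples
#' d <- adld("MTMHTTMTTL", "MTMYATMTTL")
#' d$fragments
#' similarity_degree(d)
adld <- function(s1, s2, epsilon = 0, delta = 3, xi = 10, params = NULL) {
  if (is.null(params)) params <- alignment_params(epsilon, delta, xi)
  stopifnot(inherits(params, "alignment_params"))
  s1 <- as_numerical_sequence(s1, id = "seq1")
  s2 <- as_numerical_sequence(s2, id = "seq2")
  swap <- length(s2$scores) > length(s1$scores) ||
    (length(s2$scores) == length(s1$scores) && s2$id < s1$id)
  if (swap) { tmp <- s1; s1 <- s2; s2 <- tmp }
  aps <- alignment_points(s1, s2, params)
  frags <- extract_fragments(aps, params$delta)
  fps <- free_points(aps, frags)
  structure(
    list(params = params, pair_ids = c(s1$id, s2$id),
         n1 = aps$n1, n2 = aps$n2, width = aps$width,
         fragments = frags, free_points = fps),
    class = "adld")
}

#' Similarity degree of a diagram
#'
#' Sum of the lengths (point counts) of all similar fragments — artery and
#' by-path — plus the number of free points. The raw pairwise statistic
#' underlying the distance matrix.
#'
#' @param x An `adld` object.
#' @return Integer.
#' @export
similarity_degree <- function(x) {
  stopifnot(inherits(x, "adld"))
  as.integer(sum(x$fragments$length) + length(x$free_points))
}

#' @export
print.adld <- function(x, ...) {
  cat(sprintf("ADLD of (%s, %s)  [n1 = %d, n2 = %d, band half-width %d]\n",
              x$pair_ids[1], x$pair_ids[2], x$n1, x$n2, x$width))
  cat(sprintf("  epsilon = %g, delta = %d, xi = %d\n",
              x$params$epsilon, x$params$delta, x$params$xi))
  nf <- nrow(x$fragments)
  cat(sprintf("  %d similar fragment(s), %d free point(s), SD = %d\n",
              nf, length(x$free_points), similarity_degree(x)))
  invisible(x)
}

#' @export
summary.adld <- function(object, ...) {
  f <- object$fragments
  out <- list(
    pair_ids = object$pair_ids,
    params = object$params,
    n_artery_fragments = sum(f$track_offset == 0L),
    n_bypath_fragments = sum(f$track_offset != 0L),
    total_fragment_length = sum(f$length),
    n_free_points = length(object$free_points),
    similarity_degree = similarity_degree(object))
  class(out) <- "summary.adld"
  out
}

#' @export
print.summary.adld <- function(x, ...) {
  cat(sprintf("ADLD of (%s, %s)\n", x$pair_ids[1], x$pair_ids[2]))
  cat(sprintf("  artery fragments:   %d\n", x$n_artery_fragments))
  cat(sprintf("  by-path fragments:  %d\n", x$n_bypath_fragments))
  cat(sprintf("  total fragment length: %d\n", x$total_fragment_length))
  cat(sprintf("  free points:        %d\n", x$n_free_points))
  cat(sprintf("  similarity degree:  %d\n", x$similarity_degree))
  invisible(x)
}

#' Plot a diagram
#'
#' Draws the similar fragments as blue diagonal line segments and the free
#' points as red stars, on the i-j plane of the (longer, shorter) pair.
#'
#' @param x An `adld` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.adld <- function(x, ...) {
  graphics::plot(NA, xlim = c(1, x$n1), ylim = c(1, x$n1),
                 xlab = x$pair_ids[1], ylab = x$pair_ids[2],
                 main = sprintf("ADLD (%s, %s)",
                                x$pair_ids[1], x$pair_ids[2]), ...)
  f <- x$fragments
  if (nrow(f)) {
    graphics::segments(f$start_i, f$start_j, f$end_i, f$end_j,
                       col = "blue", lwd = 2)
  }
  if (length(x$free_points)) {
    graphics::points(x$free_points, x$free_points, col = "red", pch = 8)
  }
  invisible(x)
}
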