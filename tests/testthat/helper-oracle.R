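# Independent brute-force oracle: materializes the full n1 x n1 indicator
# matrix and scans every diagonal with plain loops. Used only to check the
# banded implementation; shares no code with it.

brute_adld <- function(res1, res2, epsilon = 0, delta = 3, xi = 10,
                       id1 = "a", id2 = "b") {
  st <- aa_score_table()
  if (nchar(res2) > nchar(res1) ||
      (nchar(res1) == nchar(res2) && id2 < id1)) {
    tmp <- res1; res1 <- res2; res2 <- tmp
    tmp <- id1; id1 <- id2; id2 <- tmp
  }
  t1 <- unname(st[strsplit(res1, "")[[1]]])
  t2 <- unname(st[strsplit(res2, "")[[1]]])
  n1 <- length(t1); n2 <- length(t2)
  w <- if (n1 - n2 <= xi) xi else n1 - n2
  A <- matrix(FALSE, n1, n1)
  for (i in seq_len(n1)) {
    for (j in seq_len(n1)) {
      if (j <= n2 && abs(i - j) <= w && abs(t1[i] - t2[j]) <= epsilon) {
        A[i, j] <- TRUE
      }
    }
  }
  frags <- list()
  for (o in c(0L, seq_len(w), -seq_len(w))) {
    run <- integer(0)
    for (i in seq_len(n1)) {
      j <- i + o
      on <- j >= 1 && j <= n1 && A[i, j]
      if (on) run <- c(run, i)
      if ((!on || i == n1) && length(run) >= delta) {
        frags[[length(frags) + 1L]] <- data.frame(
          track_offset = o, start_i = run[1], start_j = run[1] + o,
          end_i = run[length(run)], end_j = run[length(run)] + o,
          length = length(run))
      }
      if (!on) run <- integer(0)
    }
  }
  frags <- if (length(frags)) do.call(rbind, frags) else
    data.frame(track_offset = integer(0), start_i = integer(0),
               start_j = integer(0), end_i = integer(0),
               end_j = integer(0), length = integer(0))
  artery <- which(diag(A))
  covered <- integer(0)
  af <- frags[frags$track_offset == 0, , drop = FALSE]
  if (nrow(af)) {
    for (r in seq_len(nrow(af))) covered <- c(covered,
                                              af$start_i[r]:af$end_i[r])
  }
  fps <- setdiff(artery, covered)
  list(fragments = frags, free_points = as.integer(sort(fps)),
       sd = sum(frags$length) + length(fps),
       pair_ids = c(id1, id2), n1 = n1, n2 = n2, width = w)
}

# canonical ordering so fragment tables can be compared set-wise
sort_frags <- function(f) {
  f <- f[order(f$track_offset, f$start_i), , drop = FALSE]
  rownames(f) <- NULL
  f
}

expect_same_adld <- function(got, oracle) {
  expect_equal(sort_frags(got$fragments), sort_frags(oracle$fragments))
  expect_identical(as.integer(got$free_points), oracle$free_points)
  expect_identical(similarity_degree(got), as.integer(oracle$sd))
}

# the published per-residue total scores (4 dp), used as frozen references
REF_TOTAL_SCORES <- c(
  A = -0.9324, C = -0.5985, D = -0.6709, E = -0.2296, F = 0.4298,
  G = -1.1780, H = 0.4476, I = 0.1435, K = 0.7868, L = -0.1205,
  M = 0.5735, N = -0.0242, P = -0.9822, Q = 0.2848, R = 1.1169,
  S = -0.7077, T = -0.4525, V = -0.2643, W = 1.4729, Y = 0.9050)

write_fasta_tmp <- function(seqs, ids = names(seqs)) {
  f <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), f)
  f
}
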