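test_that("worked pair: matching matrix and distances", {
  sm <- adld_distances(c(Hu = "MTMHTTMTTL", Gor = "MTMYATMTTL"))
  expect_identical(sm$ids, c("Hu", "Gor"))
  expect_equal(unname(diag(sm$matching)), c(10L, 10L))
  expect_identical(sm$matching[2, 1], 8L)
  expect_identical(sm$matching[1, 2], 0L)   # upper triangle by convention
  expect_equal(sm$distances[2, 1], 0.2)
  expect_equal(unname(diag(sm$distances)), c(0, 0))
})

test_that("distances lie in [0, 1]; identical sequences give 0", {
  set.seed(5)
  seqs <- vapply(1:5, function(i) random_sequence(30 + i, seed = 500 + i),
                 "")
  names(seqs) <- paste0("s", 1:5)
  seqs["s5"] <- seqs["s1"]
  sm <- adld_distances(seqs)
  low <- sm$distances[lower.tri(sm$distances, diag = TRUE)]
  expect_true(all(low >= 0 & low <= 1))
  expect_equal(unname(diag(sm$distances)), rep(0, 5))
  expect_equal(sm$distances["s5", "s1"], 0)
})

test_that("score-disjoint sequences are at distance exactly 1", {
  # the two alphabets share no residues, hence no scores within eps = 0
  a <- paste(rep("ACDEF", 6), collapse = "")
  b <- paste(rep("GHIKL", 6), collapse = "")
  sm <- adld_distances(c(a = a, b = b))
  expect_identical(sm$matching[2, 1], 0L)
  expect_equal(sm$distances[2, 1], 1)
})

test_that("distance is clamped at 0 when cross-degree exceeds self-degree", {
  # the short motif matches the repeat concatenation twice over, so the
  # cross-degree (10) exceeds the motif's own self-degree (5)
  sm <- adld_distances(c(rep2 = "ACDEFACDEF", motif = "ACDEF"))
  expect_gt(sm$matching["motif", "rep2"], sm$matching["motif", "motif"])
  expect_equal(sm$distances["motif", "rep2"], 0)
})

test_that("equal-length pairs have a symmetric similarity degree", {
  r1 <- random_sequence(35, seed = 61)
  r2 <- random_sequence(35, seed = 62)
  p <- alignment_params()
  d_ab <- similarity_degree(adld(encode_sequence(r1, "a"),
                                 encode_sequence(r2, "b"), params = p))
  d_ba <- similarity_degree(adld(encode_sequence(r2, "b"),
                                 encode_sequence(r1, "a"), params = p))
  expect_identical(d_ab, d_ba)
})

test_that("self-degree counts internal repeats via by-path fragments", {
  rep_seq <- paste(rep("WYR", 8), collapse = "")  # strong self-repeats
  d_self <- adld(rep_seq, rep_seq)
  expect_gt(similarity_degree(d_self), nchar(rep_seq))
  expect_true(any(d_self$fragments$track_offset != 0L))
})

test_that("zero self-degree is a named degenerate error", {
  m <- matrix(c(5L, 0L, 3L, 0L), 2,
              dimnames = list(c("ok", "bad"), c("ok", "bad")))
  expect_error(similarity_matrix(m), "bad")
})

test_that("the symmetric normalization variant is bounded by the row variant", {
  seqs <- c(motif = "ACDEF", rep2 = "ACDEFACDEF", other = "WYRWYRWYR")
  row <- adld_distances(seqs, normalize = "row")
  mn <- adld_distances(seqs, normalize = "min")
  low <- lower.tri(row$distances)
  expect_true(all(mn$distances[low] <= row$distances[low] + 1e-12))
})

test_that("CSV and PHYLIP round-trip through the matrix reader", {
  seqs <- c(s1 = "MTMHTTMTTL", s2 = "MTMYATMTTL", s3 = "MKVINISNTM")
  sm <- adld_distances(seqs)
  fcsv <- tempfile(fileext = ".csv")
  fphy <- tempfile(fileext = ".phy")
  write_sm_csv(sm, fcsv)
  write_phylip(sm, fphy)
  sym <- as.matrix(as.dist(sm))
  back_csv <- read_distance_matrix(fcsv)
  back_phy <- read_distance_matrix(fphy)
  expect_equal(back_csv, round(sym, 4), tolerance = 1e-12)
  expect_equal(back_phy, round(sym, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(rownames(back_phy), names(seqs))
})
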