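hu <- encode_sequence("MTMHTTMTTL", "Hu")
gor <- encode_sequence("MTMYATMTTL", "Gor")

test_that("alignment width follows the two-branch rule", {
  expect_identical(alignment_width(147, 147, 12), 12L)
  expect_identical(alignment_width(100, 75, 10), 25L)
  expect_identical(alignment_width(30, 20, 10), 10L)
  expect_error(alignment_width(5, 10, 10), "n1 >= n2")
})

test_that("parameter validation enforces the documented bounds", {
  p <- alignment_params()
  expect_equal(p$epsilon, 0)
  expect_identical(p$delta, 3L)
  expect_identical(p$xi, 10L)
  expect_error(alignment_params(epsilon = -1), "epsilon")
  expect_error(alignment_params(delta = 0), "delta")
  expect_error(alignment_params(xi = 0), "xi")
})

test_that("banded point set matches direct evaluation on the worked pair", {
  aps <- alignment_points(hu, gor, alignment_params())
  artery <- sort(aps$points[aps$points[, "i"] == aps$points[, "j"], "i"])
  expect_identical(as.integer(artery), c(1L, 2L, 3L, 6L, 7L, 8L, 9L, 10L))
  expect_true(all(abs(aps$points[, "i"] - aps$points[, "j"]) <= aps$width))
  expect_true(all(aps$points[, "j"] <= aps$n2))
  # identical sequences: full diagonal present
  self <- alignment_points(hu, hu, alignment_params())
  expect_identical(sort(self$points[self$points[, "i"] ==
                                      self$points[, "j"], "i"]), 1:10)
  # epsilon >= score spread: every in-band, non-padding point is present
  all_aps <- alignment_points(hu, gor, alignment_params(epsilon = 3))
  n_expected <- sum(vapply(-10:10, function(o) {
    max(0L, min(10L, 10L - o) - max(1L, 1L - o) + 1L)
  }, 0L))
  expect_identical(nrow(all_aps$points), as.integer(n_expected))
})

test_that("worked pair yields two artery fragments and no free points", {
  d <- adld(hu, gor)
  expect_identical(d$pair_ids, c("Gor", "Hu"))  # equal length, lexicographic
  expect_equal(d$fragments$track_offset, c(0L, 0L))
  expect_equal(d$fragments$start_i, c(1L, 6L))
  expect_equal(d$fragments$end_i, c(3L, 10L))
  expect_equal(d$fragments$length, c(3L, 5L))
  expect_length(d$free_points, 0L)
  expect_identical(similarity_degree(d), 8L)
})

test_that("delta = 1 degenerates the diagram into the scatter diagram", {
  aps <- alignment_points(hu, gor, alignment_params())
  frags <- extract_fragments(aps, delta = 1L)
  expect_identical(sum(frags$length), nrow(aps$points))
  expect_length(free_points(aps, frags), 0L)
})

test_that("a sequence against itself gives one full-length artery fragment", {
  s <- encode_sequence("ACDEFGHIKL", "s")   # repeat-free
  d <- adld(s, s)
  art <- d$fragments[d$fragments$track_offset == 0L, ]
  expect_identical(nrow(art), 1L)
  expect_identical(art$length, 10L)
  expect_identical(similarity_degree(d), 10L)
})

test_that("banded implementation agrees with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n1 <- sample(5:60, 1)
    n2 <- sample(5:n1, 1)
    r1 <- random_sequence(n1, seed = rep * 101)
    r2 <- random_sequence(n2, seed = rep * 101 + 1)
    eps <- sample(c(0, 0.3, 1), 1)
    delta <- sample(2:4, 1)
    xi <- sample(c(5L, 10L), 1)
    got <- adld(encode_sequence(r1, "a"), encode_sequence(r2, "b"),
                epsilon = eps, delta = delta, xi = xi)
    oracle <- brute_adld(r1, r2, epsilon = eps, delta = delta, xi = xi,
                         id1 = "a", id2 = "b")
    expect_same_adld(got, oracle)
  }
})

test_that("swapping an equal-length pair mirrors the diagram", {
  set.seed(7)
  for (rep in 1:10) {
    r1 <- random_sequence(40, seed = rep * 7)
    r2 <- apply_recipe(r1, edit_recipe(random_sub(r1, 5, rep),
                                       random_sub(r1, 21, rep + 50)))
    a <- adld(encode_sequence(r1, "a"), encode_sequence(r2, "b"))
    b <- adld(encode_sequence(r1, "b"), encode_sequence(r2, "a"))
    fa <- sort_frags(a$fragments)
    fb <- b$fragments
    fb2 <- data.frame(track_offset = -fb$track_offset,
                      start_i = fb$start_j, start_j = fb$start_i,
                      end_i = fb$end_j, end_j = fb$end_i,
                      length = fb$length)
    expect_equal(fa, sort_frags(fb2))
    expect_identical(length(a$free_points), length(b$free_points))
    expect_identical(similarity_degree(a), similarity_degree(b))
  }
})

test_that("a block insertion shifts the suffix onto a by-path track", {
  s <- random_sequence(60, seed = 99)
  for (k in c(2L, 5L)) {
    p <- 25L
    payload <- substr(random_sequence(k + 40, seed = 100 + k), 1, k)
    s2 <- apply_recipe(s, edit_recipe(edit_ins(p, payload)))
    d <- adld(encode_sequence(s2, "ins"), encode_sequence(s, "base"))
    f <- d$fragments
    pre <- f[f$track_offset == 0L & f$start_i == 1L, ]
    expect_identical(nrow(pre), 1L)
    expect_gte(pre$end_i, p - 1L)
    suf <- f[f$track_offset == -k, ]
    expect_identical(nrow(suf), 1L)
    expect_identical(suf$end_i, 60L + k)
    expect_identical(suf$end_j, 60L)
  }
})

test_that("one interior substitution splits the artery fragment", {
  s <- random_sequence(30, seed = 3)
  q <- 14L
  s2 <- apply_recipe(s, edit_recipe(random_sub(s, q, seed = 4)))
  d <- adld(encode_sequence(s, "a"), encode_sequence(s2, "b"))
  art <- d$fragments[d$fragments$track_offset == 0L, ]
  expect_true(all(art$start_i != q & art$end_i != q))
  expect_true(any(art$end_i == q - 1L) && any(art$start_i == q + 1L))
  aps <- alignment_points(encode_sequence(s, "a"), encode_sequence(s2, "b"),
                          alignment_params())
  expect_false(any(aps$points[, "i"] == q & aps$points[, "j"] == q))
})

test_that("point set grows with epsilon; fragments shrink with delta", {
  r1 <- random_sequence(50, seed = 21)
  r2 <- random_sequence(45, seed = 22)
  s1 <- encode_sequence(r1, "a"); s2 <- encode_sequence(r2, "b")
  prev <- NULL
  for (eps in c(0, 0.2, 0.5, 1, 2)) {
    aps <- alignment_points(s1, s2, alignment_params(epsilon = eps))
    keys <- paste(aps$points[, 1], aps$points[, 2])
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
  prev_frags <- Inf; prev_fps <- -1L
  for (delta in 1:6) {
    d <- adld(s1, s2, epsilon = 0.5, delta = delta)
    expect_lte(nrow(d$fragments), prev_frags)
    expect_gte(length(d$free_points), prev_fps)
    prev_frags <- nrow(d$fragments)
    prev_fps <- length(d$free_points)
  }
})
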