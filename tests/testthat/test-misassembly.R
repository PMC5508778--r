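test_that("physical coverage spans both reads and the gap between them", {
  p <- make_pairs("c", 0, "c", 90, read_len = 10)
  prof <- physical_coverage(p, "c", 100)
  expect_equal(prof$coverage, rep(1L, 100))

  expect_equal(physical_coverage(empty_pairs_fixture(), "c", 50)$coverage,
               rep(0L, 50))

  two <- make_pairs(c("c", "c"), c(10, 10), c("c", "c"), c(15, 15),
                    read_len = 5)
  prof2 <- physical_coverage(two, "c", 30)
  expect_equal(prof2$coverage,
               c(rep(0L, 10), rep(2L, 10), rep(0L, 10)))

  expect_error(physical_coverage(make_pairs("c", 0, "d", 0), "c", 100),
               "other than")
})

test_that("physical coverage matches a brute-force base-painting oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(1000, 1)
    L <- 500
    pos1 <- sample(0:(L - 20), n, replace = TRUE)
    pos2 <- sample(0:(L - 20), n, replace = TRUE)
    p <- make_pairs(rep("c", n), pos1, rep("c", n), pos2, read_len = 20)
    prof <- physical_coverage(p, "c", L)
    oracle <- integer(L)
    for (i in seq_len(n)) {
      span <- (min(pos1[i], pos2[i]) + 1):(max(pos1[i], pos2[i]) + 20)
      oracle[span] <- oracle[span] + 1L
    }
    expect_identical(prof$coverage, oracle)
  }
})

test_that("deepest low-coverage interval matches hand-derived cases", {
  call <- find_low_coverage_interval(c(5, 5, 0, 0, 5, 5), delta = 3, "c")
  expect_equal(call$start, 2)
  expect_equal(call$end, 4)
  expect_equal(call$score, -6)

  expect_null(find_low_coverage_interval(c(4, 5, 6), delta = 3, "c"))

  call2 <- find_low_coverage_interval(c(0, 0, 0), delta = 2, "c")
  expect_equal(c(call2$start, call2$end, call2$score), c(0, 3, -6))

  expect_error(find_low_coverage_interval(numeric(0), delta = 1), "empty")
})

test_that("break calls split contigs at interval midpoints, recursively", {
  cs <- contig_set("ctg", 1e5)
  one <- data.frame(contig = "ctg", start = 49000, end = 51000,
                    score = -5000)
  res <- break_contigs(cs, one, min_score_magnitude = 100)
  expect_equal(unname(contig_lengths(res$contigs)), c(50000, 50000))
  expect_equal(names(res$contigs), c("ctg_1", "ctg_2"))

  weak <- data.frame(contig = "ctg", start = 49000, end = 51000,
                     score = -50)
  res2 <- break_contigs(cs, weak, min_score_magnitude = 100)
  expect_equal(names(res2$contigs), "ctg")

  two <- data.frame(contig = c("ctg", "ctg"),
                    start = c(24000, 74000), end = c(26000, 76000),
                    score = c(-9000, -5000))
  res3 <- break_contigs(cs, two, min_score_magnitude = 100)
  expect_equal(unname(contig_lengths(res3$contigs)),
               c(25000, 50000, 25000))
})

test_that("breaking conserves total bases and remaps pair coordinates", {
  set.seed(3)
  cs <- contig_set(c("a", "b"), c(80000, 60000))
  calls <- data.frame(contig = "a", start = 39000, end = 41000,
                      score = -1e4)
  res <- break_contigs(cs, calls)
  expect_equal(sum(contig_lengths(res$contigs)), sum(contig_lengths(cs)))

  pairs <- make_pairs(c("a", "a", "b"), c(100, 45000, 10),
                      c("a", "b", "b"), c(39999, 500, 59000),
                      read_len = 100)
  rp <- remap_pairs(pairs, res$remap)
  expect_equal(rp$contig1, c("a_1", "a_2", "b"))
  expect_equal(rp$pos2, c(39999, 500, 59000))  # a_1 keeps coords; b untouched
  expect_equal(rp$pos1[2], 45000 - 40000)
  # mate straddling the break point is clipped to its piece
  straddle <- make_pairs("a", 39950, "a", 100, read_len = 100)
  rs <- remap_pairs(straddle, res$remap)
  expect_equal(rs$contig1, "a_1")
  expect_equal(rs$end1, 40000 - 0)
})

test_that("an induced coverage gap is detected near its true position", {
  # two unrelated halves: a pair whose mate would cross the junction maps
  # to a different contig, so it is absent from the intra-contig stream
  L <- 200000
  junction <- 120000
  mk <- function(lo, hi, n, seed) {
    set.seed(seed)
    p1 <- sample(lo:(hi - 100), n, replace = TRUE)
    d <- sample(500:20000, n, TRUE) * sample(c(-1, 1), n, TRUE)
    p2 <- p1 + d
    keep <- p2 >= lo & p2 <= hi - 100
    make_pairs(rep("chim", sum(keep)), p1[keep],
               rep("chim", sum(keep)), p2[keep], read_len = 100)
  }
  pairs <- rbind(mk(0, junction, 7000, 19), mk(junction, L, 5000, 20))
  cs <- contig_set("chim", L)
  calls <- detect_breaks(pairs, cs, min_equiv_span = 3000)
  expect_equal(nrow(calls), 1)
  expect_lt(abs(calls$midpoint - junction), 5000)
  # clean contigs of the same density yield no call: terminal coverage
  # ramps are excluded by the edge margin
  for (s in 21:23) {
    clean <- mk(0, L, 12000, s)
    expect_equal(nrow(detect_breaks(clean, cs, min_equiv_span = 3000)), 0)
  }
})

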