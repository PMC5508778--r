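test_that("path traversal yields order and orientation from B/E crossings", {
  cs <- contig_set(c("1", "2"), c(1e5, 1e5))
  fwd <- build_graph(make_candidates("1", "E", "2", "B", 50, 5), cs, 5)
  lay <- extract_paths(fwd, cs, n_th = 1)
  expect_equal(lay[[1]]$placements$contig, c("1", "2"))
  expect_equal(lay[[1]]$placements$orientation, c("forward", "forward"))
  expect_true(lay[[1]]$is_seed)   # 2 contigs > n_th = 1

  rev <- build_graph(make_candidates("1", "E", "2", "E", 50, 5), cs, 5)
  lay2 <- extract_paths(rev, cs, n_th = 2)
  expect_equal(lay2[[1]]$placements$orientation, c("forward", "reverse"))
  expect_false(lay2[[1]]$is_seed)  # 2 contigs, n_th = 2

  # isolated contig becomes a singleton non-seed layout
  cs3 <- contig_set(c("1", "2", "zzz"), c(1e5, 1e5, 5e4))
  lay3 <- extract_paths(fwd, cs3, n_th = 2)
  single <- Filter(function(l) nrow(l$placements) == 1, lay3)
  expect_equal(length(single), 1)
  expect_equal(single[[1]]$placements$contig, "zzz")
  expect_false(single[[1]]$is_seed)
})

test_that("every component node is visited exactly once and paths are canonical", {
  set.seed(23)
  for (i in 1:20) {
    cand <- random_candidate_set(sample(5:30, 1), sample(5:80, 1))
    cs <- contig_set(sprintf("c%03d", 1:30), rep(1e5, 30))
    g <- build_graph(cand, cs, min_links = 1)
    lays <- extract_paths(g, cs, n_th = 3)
    placed <- unlist(lapply(lays, function(l) l$placements$contig))
    expect_setequal(placed, names(cs))          # complete
    expect_false(any(duplicated(placed)))       # exactly once
    for (l in lays) {
      p <- l$placements
      if (nrow(p) > 1) {
        # canonical form: lexicographically smaller terminal first
        expect_true(p$contig[1] <= p$contig[nrow(p)])
      }
    }
  }
})

test_that("seed assignment maximizes total original-graph weight with stable ties", {
  seed_a <- scaffold_layout("A", c("a1", "a2"), rep("forward", 2), TRUE)
  seed_b <- scaffold_layout("B", c("b1", "b2"), rep("forward", 2), TRUE)
  links <- make_candidates(c("x", "x", "x"), c("B", "E", "B"),
                           c("a1", "a2", "b1"), c("E", "B", "B"),
                           raw = c(1, 1, 1), weight = c(2.5, 1.5, 1.5))
  got <- assign_to_seed("x", links, list(seed_a, seed_b))
  expect_equal(got$seed, 1)
  expect_equal(got$weight, 4.0)

  none <- assign_to_seed("orphan", links, list(seed_a, seed_b))
  expect_true(is.na(none$seed))

  tie <- make_candidates(c("x", "x"), c("B", "E"), c("a1", "b1"),
                         c("E", "B"), raw = c(1, 1), weight = c(2, 2))
  expect_equal(assign_to_seed("x", tie, list(seed_a, seed_b))$seed, 1)
})

test_that("insertion scoring matches an exhaustive independent scorer", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    ctgs <- sprintf("s%02d", seq_len(n))
    extra <- "ins"
    all_ctg <- c(ctgs, extra)
    # random link weights over all end pairs
    ends <- expand.grid(a = all_ctg, b = all_ctg,
                        ta = c("B", "E"), tb = c("B", "E"),
                        stringsAsFactors = FALSE)
    ends <- ends[ends$a < ends$b, ]
    keep <- sample(nrow(ends), min(nrow(ends), 25))
    links <- make_candidates(ends$a[keep], ends$ta[keep],
                             ends$b[keep], ends$tb[keep],
                             raw = 10, weight = round(stats::runif(
                               length(keep), 0, 5), 3))
    seed <- scaffold_layout("s", ctgs,
                            sample(c("forward", "reverse"), n, TRUE), TRUE)
    # package's argmax
    best <- NULL
    for (pos in 0:n) {
      for (ori in c("forward", "reverse")) {
        s <- score_insertion(seed, extra, pos, ori, links)
        if (is.null(best) || s > best$s) best <- list(pos = pos, ori = ori,
                                                      s = s)
      }
    }
    # brute-force oracle over the same slots
    obest <- NULL
    for (pos in 0:n) {
      for (ori in c("forward", "reverse")) {
        ct <- append(seed$placements$contig, extra, after = pos)
        oo <- append(seed$placements$orientation, ori, after = pos)
        s <- brute_layout_weight(ct, oo, links)
        if (is.null(obest) || s > obest$s) obest <- list(pos = pos,
                                                         ori = ori, s = s)
      }
    }
    expect_equal(best$s, obest$s)
    # a zero-link contig adds nothing: terminal slots keep the seed's
    # total, interior slots lose exactly the adjacency they split
    total <- brute_layout_weight(seed$placements$contig,
                                 seed$placements$orientation, links)
    expect_equal(score_insertion(seed, "nolinks", 0, "forward", links),
                 total)
    expect_equal(score_insertion(seed, "nolinks", n, "forward", links),
                 total)
    for (pos in seq_len(n - 1)) {
      expect_lte(score_insertion(seed, "nolinks", pos, "forward", links),
                 total + 1e-12)
    }
  }
})

test_that("small-contig insertion conserves the contig multiset", {
  seeds <- list(scaffold_layout("A", c("a1", "a2", "a3", "a4"),
                                rep("forward", 4), TRUE),
                scaffold_layout("B", c("b1", "b2", "b3", "b4"),
                                rep("forward", 4), TRUE))
  smalls <- lapply(sprintf("x%d", 1:5), function(ctg) {
    scaffold_layout(ctg, ctg, "forward", FALSE)
  })
  links <- make_candidates(
    c("x1", "x2", "x3", "x4"), c("E", "E", "B", "E"),
    c("a1", "a2", "b1", "b4"), c("B", "E", "B", "E"),
    raw = 10, weight = c(4, 3, 5, 2))
  out <- insert_small_contigs(seeds, smalls, links)
  placed <- unlist(lapply(out, function(l) l$placements$contig))
  expect_setequal(placed, c(sprintf("a%d", 1:4), sprintf("b%d", 1:4),
                            sprintf("x%d", 1:5)))
  expect_false(any(duplicated(placed)))
  # x5 has no links anywhere: it must come through as its own layout
  x5 <- Filter(function(l) identical(l$placements$contig, "x5"), out)
  expect_equal(length(x5), 1)

  # with no seeds the input passes through
  expect_identical(insert_small_contigs(list(), smalls, links), smalls)
})

test_that("a strongly linked contig lands between its two partners", {
  seed <- scaffold_layout("s", c("a", "b", "c"), rep("forward", 3), TRUE)
  links <- make_candidates(c("a", "ins"), c("E", "E"),
                           c("ins", "b"), c("B", "B"),
                           raw = 10, weight = c(6, 6))
  small <- list(scaffold_layout("i", "ins", "forward", FALSE))
  out <- insert_small_contigs(list(seed), small, links)
  expect_equal(out[[1]]$placements$contig, c("a", "ins", "b", "c"))
  expect_equal(out[[1]]$placements$orientation[2], "forward")
})
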