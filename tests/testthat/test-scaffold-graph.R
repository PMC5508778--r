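test_that("reads assign to B/E windows with short-contig clamping", {
  expect_equal(assign_read_to_end(100, 200, 1e6, 5e5), "B")
  expect_equal(assign_read_to_end(6e5, 6e5 + 100, 1e6, 5e5), "E")
  expect_true(is.na(assign_read_to_end(4e5, 4e5 + 100, 1e6, 2e5)))
  # window clamps to half the contig so B and E never overlap
  expect_equal(assign_read_to_end(10, 20, 1000, 5000), "B")
  expect_true(is.na(assign_read_to_end(490, 510, 1000, 5000)))
})

test_that("link counting aggregates per end-pair and drops mid-contig mates", {
  cs <- contig_set(c("C1", "C2"), c(1e6, 1e6))
  seven <- make_pairs(rep("C1", 7), 9e5 + (1:7), rep("C2", 7), 1:7,
                      read_len = 100)
  lk <- count_links(seven, cs, l = 5e5)
  expect_equal(nrow(lk), 1)
  expect_equal(lk$raw_links, 7L)
  expect_equal(paste(lk$u_contig, lk$u_tag), "C1 E")
  expect_equal(paste(lk$v_contig, lk$v_tag), "C2 B")

  mid <- make_pairs("C1", 4.99e5, "C2", 10, read_len = 100, end1 = 5.01e5)
  expect_equal(nrow(count_links(mid, cs, l = 5e5)), 0)

  mixed <- rbind(
    make_pairs(rep("C1", 3), 9e5 + (1:3), rep("C2", 3), 1:3, read_len = 50),
    make_pairs(rep("C1", 2), 9e5 + (1:2), rep("C2", 2), 9e5 + (1:2),
               read_len = 50))
  lk2 <- count_links(mixed, cs, l = 5e5)
  expect_equal(nrow(lk2), 2)   # EB and EE counted on separate edges
  expect_setequal(paste0(lk2$u_tag, lk2$v_tag), c("EB", "EE"))
  expect_setequal(lk2$raw_links, c(3L, 2L))
})

test_that("restriction sites are counted in the window with a +1 pseudocount", {
  # window of width 10 covering "GATCAAGATC": two sites + pseudocount
  expect_equal(count_restriction_sites("GATCAAGATCAAAAAAAAAA", tag = "B",
                                       l = 10, motifs = "GATC"), 3)
  expect_equal(count_restriction_sites("AAAAAAAAAA", tag = "B", l = 10,
                                       motifs = "GATC"), 1)
  expect_equal(count_restriction_sites("GAATC", tag = "B", l = 5,
                                       motifs = "GANTC"), 2)
  # non-palindromic motif: reverse complement is scanned too
  expect_equal(count_restriction_sites("AAGAAGGAAA", tag = "B", l = 10,
                                       motifs = "CCTTC"), 2)
  expect_equal(count_restriction_sites("AACTGCAGTT", tag = "B", l = 10,
                                       motifs = "GGTACC"), 1)
  # E-window of a longer sequence
  s <- paste0(strrep("A", 90), "GATCABGATC")
  expect_equal(count_restriction_sites(gsub("B", "T", s), tag = "E", l = 10,
                                       motifs = "GATC"), 3)
  cs <- contig_set("c", 10)
  expect_error(count_restriction_sites(cs, "c", "B", 10, "GATC"),
               "raw-count")
})

test_that("edge weights normalize raw links by restriction-site counts", {
  expect_equal(normalize_weight(10, 3, 2), 2.0)
  expect_equal(normalize_weight(0, 5, 9), 0.0)
  expect_equal(normalize_weight(7, 1, 1), 3.5)
  # scale equivariance
  expect_equal(normalize_weight(24, 4, 8), 2 * normalize_weight(12, 4, 8))
})

test_that("greedy construction adds an edge only when both ends are new", {
  cs <- contig_set(as.character(1:4), rep(1e5, 4))
  cand <- make_candidates(c("1", "1", "3"), c("E", "E", "B"),
                          c("2", "3", "4"), c("B", "B", "B"),
                          raw = c(50, 30, 20), weight = c(5, 3, 2))
  g <- build_graph(cand, cs, min_links = 5)
  hic <- g$edges[g$edges$kind != "CONTIG", ]
  expect_equal(nrow(hic), 2)
  expect_setequal(paste(hic$u_contig, hic$u_tag, hic$v_contig, hic$v_tag),
                  c("1 E 2 B", "3 B 4 B"))

  low <- make_candidates("1", "E", "2", "B", raw = 3, weight = 10)
  g2 <- build_graph(low, cs, min_links = 5)
  expect_equal(sum(g2$edges$kind != "CONTIG"), 0)
})

test_that("cycles are opened by deleting the lightest Hi-C edge", {
  cs <- contig_set(c("A", "B", "X", "Y", "Z"), rep(1e5, 5))
  four <- make_candidates(c("A", "A"), c("B", "E"), c("B", "B"),
                          c("B", "E"), raw = c(50, 30), weight = c(5, 3))
  g <- build_graph(four, cs, min_links = 5)
  hic <- g$edges[g$edges$kind != "CONTIG", ]
  expect_equal(nrow(hic), 1)
  expect_equal(paste0(hic$u_tag, hic$v_tag), "BB")  # the w=5 BB edge stays
  expect_true(isTRUE(graph_is_valid(g)))

  # 6-cycle over three contigs: weights 4, 2, 5 -> the 2 goes
  six <- make_candidates(c("X", "Y", "Z"), c("E", "E", "E"),
                         c("Y", "Z", "X"), c("B", "B", "B"),
                         raw = c(40, 20, 50), weight = c(4, 2, 5))
  g6 <- build_graph(six, cs, min_links = 5)
  hic6 <- g6$edges[g6$edges$kind != "CONTIG", ]
  expect_equal(nrow(hic6), 2)
  expect_false(any(hic6$weight == 2))
  expect_true(isTRUE(graph_is_valid(g6)))

  # acyclic graph passes through unchanged
  acyc <- build_graph(make_candidates("A", "E", "B", "B", 50, 5), cs, 5)
  expect_identical(remove_cycles(acyc)$edges, acyc$edges)
})

test_that("graph laws hold on random candidate sets and selection is a matching", {
  set.seed(11)
  for (i in 1:25) {
    cand <- random_candidate_set(sample(5:40, 1), sample(5:120, 1))
    cs <- contig_set(sprintf("c%03d", 1:40), rep(1e5, 40))
    g <- build_graph(cand, cs, min_links = 1)
    expect_true(isTRUE(graph_is_valid(g)))
    hic <- g$edges[g$edges$kind != "CONTIG", ]
    ends <- c(paste(hic$u_contig, hic$u_tag), paste(hic$v_contig, hic$v_tag))
    expect_false(any(duplicated(ends)))  # Hi-C edges form a matching
  }
})

test_that("dominant true adjacencies are recovered exactly", {
  # chain c1-c2-c3-c4 with strong true weights and weak noise
  cs <- contig_set(paste0("c", 1:4), rep(1e5, 4))
  truth <- make_candidates(c("c1", "c2", "c3"), c("E", "E", "E"),
                           c("c2", "c3", "c4"), c("B", "B", "B"),
                           raw = c(90, 80, 85), weight = c(9, 8, 8.5))
  noise <- make_candidates(c("c1", "c2"), c("B", "B"),
                           c("c3", "c4"), c("E", "E"),
                           raw = c(10, 12), weight = c(1, 1.2))
  g <- build_graph(rbind(truth, noise), cs, min_links = 5)
  hic <- g$edges[g$edges$kind != "CONTIG", ]
  expect_setequal(paste(hic$u_contig, hic$v_contig),
                  c("c1 c2", "c2 c3", "c3 c4"))
})
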