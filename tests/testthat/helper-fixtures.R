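# shared fixture builders; everything is generated in code

# minimal pair-table constructor with sensible defaults
make_pairs <- function(contig1, pos1, contig2, pos2,
                       read_len = 10, mapq1 = 60, mapq2 = 60,
                       end1 = pos1 + read_len, end2 = pos2 + read_len,
                       strand1 = "+", strand2 = "-",
                       read_id = NULL) {
  n <- length(contig1)
  if (is.null(read_id)) read_id <- sprintf("p%03d", seq_len(n))
  data.frame(read_id = read_id,
             contig1 = contig1, pos1 = pos1, end1 = end1,
             strand1 = rep_len(strand1, n), mapq1 = rep_len(mapq1, n),
             contig2 = contig2, pos2 = pos2, end2 = end2,
             strand2 = rep_len(strand2, n), mapq2 = rep_len(mapq2, n),
             stringsAsFactors = FALSE)
}

empty_pairs_fixture <- function() {
  make_pairs(character(0), numeric(0), character(0), numeric(0))
}

pair_cols <- function() c("read_id", "contig1", "pos1", "end1",
                          "contig2", "pos2", "end2", "mapq1", "mapq2")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a tiny SAM file; each record is c(qname, flag, rname, pos1based,
# mapq, cigar)
write_sam <- function(path, sq, records) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  body <- vapply(records, function(r) {
    paste(r[1], r[2], r[3], r[4], r[5], r[6], "*", 0, 0, "*", "*",
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# a small deterministic scaffold-graph candidate table
make_candidates <- function(u_contig, u_tag, v_contig, v_tag, raw, weight) {
  data.frame(u_contig = u_contig, u_tag = u_tag,
             v_contig = v_contig, v_tag = v_tag,
             raw_links = raw, weight = weight, stringsAsFactors = FALSE)
}

# random candidate-edge sets used for the graph-law properties
random_candidate_set <- function(n_contigs, n_edges) {
  ctg <- sprintf("c%03d", seq_len(n_contigs))
  u <- sample(ctg, n_edges, replace = TRUE)
  v <- sample(ctg, n_edges, replace = TRUE)
  keep <- u != v
  u <- u[keep]; v <- v[keep]
  raw <- sample(1:50, length(u), replace = TRUE)
  make_candidates(u, sample(c("B", "E"), length(u), TRUE),
                  v, sample(c("B", "E"), length(u), TRUE),
                  raw, raw / runif(length(u), 1, 20))
}

# independent O(n^2) oracle: deepest-deficit subarray by exhaustive search
brute_min_subarray <- function(x, delta) {
  best <- 0
  n <- length(x)
  for (i in seq_len(n)) {
    s <- cumsum(x[i:n] - delta)
    m <- min(s)
    if (m < best) best <- m
  }
  best
}

# independent insertion scorer: total adjacent-pair weight of a layout,
# looked up directly from the candidate table
brute_layout_weight <- function(contigs, orientations, links) {
  total <- 0
  for (i in seq_len(length(contigs) - 1)) {
    ta <- if (orientations[i] == "forward") "E" else "B"
    tb <- if (orientations[i + 1] == "forward") "B" else "E"
    a <- paste(contigs[i], ta, sep = ":")
    b <- paste(contigs[i + 1], tb, sep = ":")
    hit <- (paste(links$u_contig, links$u_tag, sep = ":") == a &
              paste(links$v_contig, links$v_tag, sep = ":") == b) |
           (paste(links$u_contig, links$u_tag, sep = ":") == b &
              paste(links$v_contig, links$v_tag, sep = ":") == a)
    total <- total + sum(links$weight[hit])
  }
  total
}

graph_is_valid <- function(g) {
  e <- g$edges
  ids <- c(paste(e$u_contig, e$u_tag), paste(e$v_contig, e$v_tag))
  deg <- table(ids)
  if (any(deg > 2)) return("degree > 2")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = paste(e$u_contig, e$u_tag),
               to = paste(e$v_contig, e$v_tag)), directed = FALSE)
  if (!igraph::is_forest(ig)) return("cyclic")
  comp <- igraph::components(ig)
  for (k in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == k]
    if (sum(deg[nodes] == 1) != 2) return("component without 2 leaves")
  }
  TRUE
}

# shared full-size simulation runs (built once per test session)
clean_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_hic_dataset(sim_config(seed = 101))
    val
  }
})

chimeric_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_hic_dataset(sim_config(chimera_rate = 0.1,
                                              seed = 202))
    }
    val
  }
})
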