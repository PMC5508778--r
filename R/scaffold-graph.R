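#' Assign a read to a contig end window
#'
#' Each contig contributes two nodes to the scaffold graph, `B` (beginning)
#' and `E` (end). Only read pairs mapped within a window of length `l` at a
#' contig end count as linkage between contigs; the effective window is
#' `min(l, floor(length/2))` so the two windows of a short contig never
#' overlap. A read is assigned when its whole mapped interval lies inside a
#' window.
#'
#' @param pos 0-based leftmost mapped base (vectorized).
#' @param read_end 0-based exclusive rightmost mapped base.
#' @param contig_length contig length in bases.
#' @param l end-window length in bases.
#' @return character vector in `{"B", "E", NA}`.
#' @export
assign_read_to_end <- function(pos, read_end, contig_length, l) {
  stopifnot(l > 0)
  w <- pmin(l, contig_length %/% 2)
  ifelse(read_end <= w, "B",
         ifelse(pos >= contig_length - w, "E", NA_character_))
}

#' Count Hi-C links between contig-end pairs
#'
#' For each inter-contig read pair whose mates both fall in an end window,
#' increments the raw link count of the unordered end-node pair. The four
#' possible tag combinations (BB, BE, EB, EE) are counted separately: they
#' encode the relative orientation of the joined contigs.
#'
#' @param pairs MAPQ-filtered pair table; intra-contig rows are ignored.
#' @param contigs a `ContigSet`.
#' @param l end-window length in bases.
#' @return data.frame of raw link counts with columns `u_contig`, `u_tag`,
#'   `v_contig`, `v_tag`, `raw_links`; endpoints ordered canonically
#'   (`u < v` by contig name, then tag).
#' @export
count_links <- function(pairs, contigs, l) {
  validate_pairs(pairs, contigs)
  len <- contig_lengths(contigs)
  inter <- pairs[pairs$contig1 != pairs$contig2, , drop = FALSE]
  if (!nrow(inter)) return(empty_link_table())
  t1 <- assign_read_to_end(inter$pos1, inter$end1, len[inter$contig1], l)
  t2 <- assign_read_to_end(inter$pos2, inter$end2, len[inter$contig2], l)
  ok <- !is.na(t1) & !is.na(t2)
  if (!any(ok)) return(empty_link_table())
  dt <- data.table::data.table(c1 = inter$contig1[ok], t1 = t1[ok],
                               c2 = inter$contig2[ok], t2 = t2[ok])
  swap <- dt$c1 > dt$c2 | (dt$c1 == dt$c2 & dt$t1 > dt$t2)
  dt[swap, c("c1", "t1", "c2", "t2") := .(c2, t2, c1, t1)]
  agg <- dt[, list(raw_links = .N), by = c("c1", "t1", "c2", "t2")]
  out <- data.frame(u_contig = agg$c1, u_tag = agg$t1,
                    v_contig = agg$c2, v_tag = agg$t2,
                    raw_links = agg$raw_links, stringsAsFactors = FALSE)
  out <- out[order(out$u_contig, out$u_tag, out$v_contig, out$v_tag), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_link_table <- function() {
  data.frame(u_contig = character(), u_tag = character(),
             v_contig = character(), v_tag = character(),
             raw_links = integer(), stringsAsFactors = FALSE)
}

#' Count restriction sites in a contig end window
#'
#' Returns the number of occurrences of the restriction enzyme recognition
#' motif(s) whose start lies within the end window of width
#' `min(l, floor(length/2))`, plus a pseudocount of 1 (so the normalized
#' weight denominator can never be zero). IUPAC ambiguity codes in the motif
#' are honoured; for non-palindromic motifs the reverse complement is
#' scanned as well.
#'
#' @param contigs a `ContigSet` with sequences, or a single
#'   [Biostrings::DNAString].
#' @param contig contig name (ignored when a bare sequence is given).
#' @param tag `"B"` or `"E"`.
#' @param l end-window length in bases.
#' @param motifs character vector of IUPAC motifs, e.g. `"GATC"` or
#'   `c("GATC", "GANTC")`.
#' @return integer site count (>= 1).
#' @export
count_restriction_sites <- function(contigs, contig = NULL, tag, l, motifs) {
  stopifnot(tag %in% c("B", "E"), l > 0, length(motifs) >= 1)
  if (inherits(contigs, "ContigSet")) {
    if (!has_sequences(contigs)) {
      stop("restriction-site counting needs sequences; supply a FASTA or ",
           "use raw-count mode (no enzyme)")
    }
    seq <- contig_sequence(contigs, contig)
  } else {
    seq <- Biostrings::DNAString(contigs)
  }
  len <- length(seq)
  w <- min(l, len %/% 2)
  if (w < 1) return(1L)
  max_ml <- max(nchar(motifs))
  if (tag == "B") {
    win_start <- 1L
    win_end <- min(len, w + max_ml - 1L)
  } else {
    win_start <- len - w + 1L
    win_end <- len
  }
  window <- Biostrings::subseq(seq, win_start, win_end)
  n <- 0L
  for (motif in motifs) {
    pats <- Biostrings::DNAString(motif)
    rc <- Biostrings::reverseComplement(pats)
    scan <- list(pats)
    if (as.character(rc) != as.character(pats)) scan <- c(scan, list(rc))
    for (p in scan) {
      hits <- Biostrings::matchPattern(p, window, fixed = FALSE)
      # motif may overhang the window end; only starts inside the window count
      n <- n + sum(BiocGenerics::start(hits) <= w)
    }
  }
  n + 1L
}

#' Restriction-normalized edge weight
#'
#' Raw link counts are length-biased: long contig ends accumulate more Hi-C
#' pairs regardless of adjacency. The weight divides the raw count by the
#' number of restriction sites in the two end windows,
#' `W = links / (RE_u + RE_v)`, since expected pair yield scales with cut
#' sites rather than bases.
#'
#' @param raw_links raw link count (vectorized).
#' @param re_u,re_v pseudocounted restriction-site counts (>= 1).
#' @return numeric weight(s).
#' @export
normalize_weight <- function(raw_links, re_u, re_v) {
  stopifnot(all(re_u >= 1), all(re_v >= 1))
  raw_links / (re_u + re_v)
}

#' Candidate scaffold-graph edges with normalized weights
#'
#' Combines [count_links()] with per-end restriction-site counts into the
#' candidate edge table consumed by [build_graph()] (and retained, unpruned,
#' for small-contig insertion). With `motifs = NULL` (raw-count mode) the
#' weight equals the raw link count.
#'
#' @param pairs MAPQ-filtered pair table.
#' @param contigs a `ContigSet`.
#' @param l end-window length in bases (default 500000).
#' @param motifs restriction enzyme motif(s), or `NULL` for raw-count mode.
#' @return data.frame with `u_contig`, `u_tag`, `v_contig`, `v_tag`,
#'   `raw_links`, `weight`.
#' @export
candidate_edges <- function(pairs, contigs, l = 5e5, motifs = NULL) {
  links <- count_links(pairs, contigs, l)
  if (is.null(motifs)) {
    links$weight <- as.numeric(links$raw_links)
    return(links)
  }
  ends <- unique(rbind(
    data.frame(contig = links$u_contig, tag = links$u_tag,
               stringsAsFactors = FALSE),
    data.frame(contig = links$v_contig, tag = links$v_tag,
               stringsAsFactors = FALSE)))
  if (nrow(ends)) {
    re <- mapply(function(ctg, tg) {
      count_restriction_sites(contigs, ctg, tg, l, motifs)
    }, ends$contig, ends$tag)
    names(re) <- paste(ends$contig, ends$tag, sep = ":")
    links$weight <- normalize_weight(
      links$raw_links,
      re[paste(links$u_contig, links$u_tag, sep = ":")],
      re[paste(links$v_contig, links$v_tag, sep = ":")])
  } else {
    links$weight <- numeric(0)
  }
  links
}

edge_kind <- function(u_tag, v_tag) paste0(u_tag, v_tag)

node_ids <- function(contig, tag) paste(contig, tag, sep = ":")

#' Build the scaffold graph
#'
#' Nodes are contig ends (`B`/`E`); Hi-C edges join ends of different
#' contigs. Construction: (i) candidates with fewer than `min_links` raw
#' pairs are discarded as likely noise; (ii) survivors are sorted by weight,
#' descending; (iii) scanning in order, an edge is added only when *neither*
#' endpoint is already in the graph — a greedy maximum-weight matching on
#' end nodes; (iv) a CONTIG edge joins the B and E nodes of every contig
#' that received a Hi-C edge; (v) any cycle created in (iv) is broken by
#' [remove_cycles()]. The result has maximum degree 2, is acyclic, and
#' every connected component has exactly two degree-1 nodes, so each
#' component is a unique contig path.
#'
#' @param candidates candidate edge table from [candidate_edges()].
#' @param contigs a `ContigSet`.
#' @param min_links minimum raw link count for a candidate (default 5).
#' @param l end-window length recorded in the graph parameters.
#' @param motifs enzyme motifs recorded in the graph parameters.
#' @return an object of class `ScaffoldGraph`: list with `edges` (data.frame
#'   `u_contig`, `u_tag`, `v_contig`, `v_tag`, `kind`, `raw_links`,
#'   `weight`) and `params`.
#' @export
build_graph <- function(candidates, contigs, min_links = 5, l = NA,
                        motifs = NULL) {
  cand <- candidates[candidates$raw_links >= min_links, , drop = FALSE]
  ord <- order(-cand$weight, -cand$raw_links,
               node_ids(cand$u_contig, cand$u_tag),
               node_ids(cand$v_contig, cand$v_tag))
  cand <- cand[ord, , drop = FALSE]
  used <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    u <- node_ids(cand$u_contig[i], cand$u_tag[i])
    v <- node_ids(cand$v_contig[i], cand$v_tag[i])
    if (!(u %in% used) && !(v %in% used)) {
      keep[i] <- TRUE
      used <- c(used, u, v)
    }
  }
  hic <- cand[keep, , drop = FALSE]
  hic$kind <- edge_kind(hic$u_tag, hic$v_tag)
  linked <- sort(unique(c(hic$u_contig, hic$v_contig)))
  contig_edges <- data.frame(
    u_contig = linked, u_tag = rep("B", length(linked)),
    v_contig = linked, v_tag = rep("E", length(linked)),
    raw_links = rep(NA_integer_, length(linked)),
    weight = rep(NA_real_, length(linked)),
    kind = rep("CONTIG", length(linked)), stringsAsFactors = FALSE)
  edges <- rbind(hic[, colnames(contig_edges)], contig_edges)
  rownames(edges) <- NULL
  g <- structure(list(edges = edges,
                      params = list(l = l, min_links = min_links,
                                    motifs = motifs)),
                 class = "ScaffoldGraph")
  remove_cycles(g)
}

#' @export
print.ScaffoldGraph <- function(x, ...) {
  cat(sprintf("ScaffoldGraph: %d contigs, %d Hi-C edges\n",
              sum(x$edges$kind == "CONTIG"),
              sum(x$edges$kind != "CONTIG")))
  invisible(x)
}

#' Break cycles in a scaffold graph
#'
#' After the matching step every node has at most one Hi-C edge and one
#' CONTIG edge, so each connected component is a simple path or a simple
#' cycle (e.g. the 4-cycle arising when both `X:B–Y:B` and `X:E–Y:E` are
#' selected). Each cyclic component is opened by deleting its
#' minimum-weight Hi-C edge; CONTIG edges are never deleted.
#'
#' @param g a `ScaffoldGraph`.
#' @return the acyclic `ScaffoldGraph`.
#' @export
remove_cycles <- function(g) {
  repeat {
    comp <- graph_components(g$edges)
    deg <- node_degrees(g$edges)
    cyclic <- NULL
    for (cid in unique(comp$comp)) {
      nodes <- comp$node[comp$comp == cid]
      if (all(deg[nodes] == 2)) {  # degree-2-everywhere component is a cycle
        cyclic <- nodes
        break
      }
    }
    if (is.null(cyclic)) return(g)
    e <- g$edges
    u <- node_ids(e$u_contig, e$u_tag)
    on_cycle <- which(e$kind != "CONTIG" & u %in% cyclic)
    sub <- e[on_cycle, , drop = FALSE]
    pick <- on_cycle[order(sub$weight, sub$raw_links,
                           node_ids(sub$u_contig, sub$u_tag))[1]]
    g$edges <- e[-pick, , drop = FALSE]
    rownames(g$edges) <- NULL
  }
}

# connected components of the edge list by BFS: data.frame(node, comp)
graph_components <- function(edges) {
  u <- node_ids(edges$u_contig, edges$u_tag)
  v <- node_ids(edges$v_contig, edges$v_tag)
  nodes <- unique(c(u, v))
  nbr <- split(c(v, u), c(u, v))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    cid <- cid + 1L
    queue <- start
    comp[[start]] <- cid
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nx in nbr[[cur]]) {
        if (is.na(comp[[nx]])) {
          comp[[nx]] <- cid
          queue <- c(queue, nx)
        }
      }
    }
  }
  data.frame(node = nodes, comp = unname(comp[nodes]),
             stringsAsFactors = FALSE)
}

node_degrees <- function(edges) {
  ids <- c(node_ids(edges$u_contig, edges$u_tag),
           node_ids(edges$v_contig, edges$v_tag))
  table(ids)
}

#' Export graph edges as TSV
#' @param g a `ScaffoldGraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  utils::write.table(
    g$edges[, c("u_contig", "u_tag", "v_contig", "v_tag", "kind",
                "raw_links", "weight")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export graph as GraphViz DOT
#' @param g a `ScaffoldGraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(g, path) {
  e <- g$edges
  lines <- c("graph scaffold {",
             sprintf("  \"%s:%s\" -- \"%s:%s\" [label=\"%s\"];",
                     e$u_contig, e$u_tag, e$v_contig, e$v_tag,
                     ifelse(e$kind == "CONTIG", "contig",
                            sprintf("%s w=%.3g", e$kind, e$weight))),
             "}")
  writeLines(lines, path)
  invisible(path)
}
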