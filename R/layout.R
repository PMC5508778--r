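#' Scaffold layout constructor
#'
#' @param id layout identifier.
#' @param contig character vector of placed contig names (unique).
#' @param orientation character vector, `"forward"` or `"reverse"`.
#' @param is_seed logical: does this layout qualify as a seed scaffold?
#' @return an object of class `ScaffoldLayout`.
#' @export
scaffold_layout <- function(id, contig, orientation, is_seed = FALSE) {
  stopifnot(length(contig) == length(orientation),
            all(orientation %in% c("forward", "reverse")))
  if (anyDuplicated(contig)) stop("contig repeated within a layout")
  structure(list(id = id,
                 placements = data.frame(contig = as.character(contig),
                                         orientation = orientation,
                                         stringsAsFactors = FALSE),
                 is_seed = is_seed),
            class = "ScaffoldLayout")
}

#' @export
print.ScaffoldLayout <- function(x, ...) {
  cat(sprintf("ScaffoldLayout %s (%s): %s\n", x$id,
              if (x$is_seed) "seed" else "small",
              paste0(x$placements$contig,
                     ifelse(x$placements$orientation == "forward", "+", "-"),
                     collapse = " ")))
  invisible(x)
}

#' Extract scaffold paths from the graph
#'
#' Each connected component of a valid scaffold graph is a simple path
#' between its two degree-1 nodes; traversing it yields the contig order,
#' and the direction in which each CONTIG edge is crossed yields the
#' orientation (B to E is forward, E to B reverse). Components with more
#' than `n_th` contigs are marked as seed scaffolds; smaller ones, and
#' contigs with no Hi-C edge at all, become non-seed layouts. Paths are
#' canonicalized so the lexicographically smaller terminal contig comes
#' first, making output deterministic.
#'
#' @param g a `ScaffoldGraph` satisfying the degree and acyclicity
#'   invariants.
#' @param contigs a `ContigSet`; contigs absent from the graph are emitted
#'   as singleton layouts.
#' @param n_th seed threshold: a layout is a seed iff it has more than
#'   `n_th` contigs (default 3).
#' @return list of `ScaffoldLayout` objects.
#' @export
extract_paths <- function(g, contigs, n_th = 3) {
  e <- g$edges
  layouts <- list()
  if (nrow(e)) {
    u <- node_ids(e$u_contig, e$u_tag)
    v <- node_ids(e$v_contig, e$v_tag)
    comp <- graph_components(e)
    deg <- node_degrees(e)
    incid <- split(rep(seq_len(nrow(e)), 2), c(u, v))
    other <- function(edge_i, node) {
      if (u[edge_i] == node) v[edge_i] else u[edge_i]
    }
    k <- 0
    for (cid in sort(unique(comp$comp))) {
      nodes <- comp$node[comp$comp == cid]
      terms <- nodes[deg[nodes] == 1]
      if (length(terms) != 2 || any(deg[nodes] > 2)) {
        stop("scaffold graph component violates the path property; ",
             "graph was not built by build_graph()")
      }
      term_ctg <- sub(":[BE]$", "", terms)
      term_tag <- sub("^.*:", "", terms)
      start <- terms[order(term_ctg, term_tag)][1]
      # walk the unique path from the chosen terminal
      path <- start
      seen_edges <- integer()
      cur <- start
      repeat {
        nxt_e <- setdiff(incid[[cur]], seen_edges)
        if (!length(nxt_e)) break
        nxt_e <- nxt_e[1]
        seen_edges <- c(seen_edges, nxt_e)
        cur <- other(nxt_e, cur)
        path <- c(path, cur)
      }
      if (length(path) != length(nodes)) {
        stop("path traversal did not visit the whole component")
      }
      ctg <- sub(":[BE]$", "", path)
      tag <- sub("^.*:", "", path)
      first <- seq(1, length(path), by = 2)
      if (any(ctg[first] != ctg[first + 1])) {
        stop("path does not alternate CONTIG and Hi-C edges")
      }
      k <- k + 1
      layouts[[length(layouts) + 1]] <- scaffold_layout(
        id = sprintf("component_%d", k),
        contig = ctg[first],
        orientation = ifelse(tag[first] == "B", "forward", "reverse"),
        is_seed = length(first) > n_th)
    }
  }
  in_graph <- unique(c(e$u_contig, e$v_contig))
  lone <- setdiff(names(contigs), in_graph)
  for (ctg in lone) {
    layouts[[length(layouts) + 1]] <- scaffold_layout(
      id = sprintf("singleton_%s", ctg), contig = ctg,
      orientation = "forward", is_seed = FALSE)
  }
  layouts
}

# fast lookup of candidate-edge weights by canonical end-pair key
link_index <- function(links) {
  key <- paste(node_ids(links$u_contig, links$u_tag),
               node_ids(links$v_contig, links$v_tag), sep = "|")
  stats::setNames(links$weight, key)
}

lookup_weight <- function(idx, c1, t1, c2, t2) {
  a <- node_ids(c1, t1)
  b <- node_ids(c2, t2)
  key <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  w <- unname(idx[key])
  w[is.na(w)] <- 0
  w
}

# weight of the junction between consecutive oriented placements: the edge
# joining the facing ends (right end of A, left end of B)
adjacency_weight <- function(idx, contig_a, orient_a, contig_b, orient_b) {
  ta <- ifelse(orient_a == "forward", "E", "B")
  tb <- ifelse(orient_b == "forward", "B", "E")
  lookup_weight(idx, contig_a, ta, contig_b, tb)
}

# total internal weight of an oriented layout
layout_weight <- function(placements, idx) {
  n <- nrow(placements)
  if (n < 2) return(0)
  sum(adjacency_weight(idx,
                       placements$contig[-n], placements$orientation[-n],
                       placements$contig[-1], placements$orientation[-1]))
}

#' Assign a small-scaffold contig to a seed scaffold
#'
#' The assigned seed is the one maximizing the total weight of all edges in
#' the original (pre-pruning) candidate edge set connecting either end of
#' the contig to any end of any contig in the seed. Ties break by seed
#' order; a contig with zero weight to every seed is unassigned.
#'
#' @param contig contig name.
#' @param original_links the full candidate edge table (before the
#'   `min_links` filter and the greedy matching).
#' @param seeds list of seed `ScaffoldLayout`s.
#' @return list with `seed` (index into `seeds`, or `NA`) and `weight`.
#' @export
assign_to_seed <- function(contig, original_links, seeds) {
  if (!length(seeds)) return(list(seed = NA_integer_, weight = 0))
  touches <- original_links$u_contig == contig |
    original_links$v_contig == contig
  sub <- original_links[touches, , drop = FALSE]
  other <- ifelse(sub$u_contig == contig, sub$v_contig, sub$u_contig)
  totals <- vapply(seeds, function(s) {
    sum(sub$weight[other %in% s$placements$contig])
  }, numeric(1))
  if (max(totals) <= 0) return(list(seed = NA_integer_, weight = 0))
  list(seed = which.max(totals), weight = max(totals))
}

#' Score a hypothetical contig insertion
#'
#' Total internal weight of the seed layout after inserting `contig` with
#' the given orientation at gap index `position` (0 = before the first
#' placement, `nrow(placements)` = after the last): the seed's existing
#' adjacent-pair weights, minus the adjacency split by an interior
#' insertion, plus the new adjacencies created on either side of the
#' inserted contig.
#'
#' @param seed a seed `ScaffoldLayout`.
#' @param contig contig name to insert.
#' @param position gap index, 0..number of placements.
#' @param orientation `"forward"` or `"reverse"`.
#' @param original_links full candidate edge table (or a prebuilt index
#'   from `link_index`).
#' @return numeric score.
#' @export
score_insertion <- function(seed, contig, position, orientation,
                            original_links) {
  idx <- if (is.numeric(original_links)) original_links
         else link_index(original_links)
  p <- seed$placements
  n <- nrow(p)
  stopifnot(position >= 0, position <= n)
  new_p <- rbind(p[seq_len(position), , drop = FALSE],
                 data.frame(contig = contig, orientation = orientation,
                            stringsAsFactors = FALSE),
                 p[setdiff(seq_len(n), seq_len(position)), , drop = FALSE])
  layout_weight(new_p, idx)
}

# argmax over all (position, orientation) slots; ties resolve to the
# smallest position, then forward orientation
best_insertion <- function(seed, contig, idx) {
  n <- nrow(seed$placements)
  best <- NULL
  for (pos in 0:n) {
    for (ori in c("forward", "reverse")) {
      s <- score_insertion(seed, contig, pos, ori, idx)
      if (is.null(best) || s > best$score) {
        best <- list(position = pos, orientation = ori, score = s)
      }
    }
  }
  best
}

#' Insert small-scaffold contigs into seed scaffolds
#'
#' Even after weight normalization, residual length biases can keep small
#' contigs out of the main paths. Each contig of each non-seed layout is
#' assigned to at most one seed by [assign_to_seed()], then placed at the
#' (position, orientation) maximizing the seed's total weight, evaluated
#' exhaustively over every gap in both orientations. Contigs are inserted
#' in descending order of their assignment weight, against the growing
#' seed. A small layout none of whose contigs can be assigned is kept
#' intact; individually unassignable contigs from partially assigned
#' layouts become singletons. The contig multiset is conserved.
#'
#' @param seeds list of seed `ScaffoldLayout`s.
#' @param smalls list of non-seed `ScaffoldLayout`s.
#' @param original_links full candidate edge table.
#' @return list of `ScaffoldLayout`s: the grown seeds followed by the
#'   unassigned leftovers.
#' @export
insert_small_contigs <- function(seeds, smalls, original_links) {
  if (!length(seeds) || !length(smalls)) return(c(seeds, smalls))
  queue <- do.call(rbind, lapply(seq_along(smalls), function(i) {
    p <- smalls[[i]]$placements
    data.frame(layout = i, contig = p$contig, stringsAsFactors = FALSE)
  }))
  assign <- lapply(queue$contig, assign_to_seed,
                   original_links = original_links, seeds = seeds)
  queue$seed <- vapply(assign, function(a) a$seed, numeric(1))
  queue$weight <- vapply(assign, function(a) a$weight, numeric(1))
  idx <- link_index(original_links)
  # layouts with no assignable contig at all are passed through intact
  assignable_layout <- tapply(!is.na(queue$seed), queue$layout, any)
  keep_intact <- as.integer(names(assignable_layout)[!assignable_layout])
  todo <- queue[!queue$layout %in% keep_intact, , drop = FALSE]
  todo <- todo[order(-todo$weight, todo$contig), , drop = FALSE]
  leftovers <- smalls[keep_intact]
  for (i in seq_len(nrow(todo))) {
    ctg <- todo$contig[i]
    s <- todo$seed[i]
    if (is.na(s)) {
      leftovers[[length(leftovers) + 1]] <- scaffold_layout(
        sprintf("singleton_%s", ctg), ctg, "forward", is_seed = FALSE)
      next
    }
    b <- best_insertion(seeds[[s]], ctg, idx)
    p <- seeds[[s]]$placements
    seeds[[s]]$placements <- rbind(
      p[seq_len(b$position), , drop = FALSE],
      data.frame(contig = ctg, orientation = b$orientation,
                 stringsAsFactors = FALSE),
      p[setdiff(seq_len(nrow(p)), seq_len(b$position)), , drop = FALSE])
  }
  c(seeds, leftovers)
}

#' Export layouts as a TSV table
#' @param layouts list of `ScaffoldLayout`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layouts, path) {
  rows <- do.call(rbind, lapply(layouts, function(l) {
    data.frame(scaffold = l$id, rank = seq_len(nrow(l$placements)),
               contig = l$placements$contig,
               orientation = l$placements$orientation,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
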