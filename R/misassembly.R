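#' Per-base physical coverage of Hi-C pairs on one contig
#'
#' The physical coverage of a read pair is the whole interval spanned by its
#' two reads *and* the gap between them; per-base physical coverage counts
#' how many pairs span each base. A chimeric join shows up as a sharp dip:
#' no genuine pair straddles the junction of two unrelated sequences.
#'
#' @param pairs pair table restricted to intra-contig pairs on `contig`.
#' @param contig contig name.
#' @param contig_length contig length in bases.
#' @return an object of class `PhysicalCoverageProfile`: a list with
#'   `contig` and an integer `coverage` vector, one value per base.
#' @export
physical_coverage <- function(pairs, contig, contig_length) {
  validate_pairs(pairs)
  if (nrow(pairs)) {
    if (any(pairs$contig1 != contig | pairs$contig2 != contig)) {
      stop("physical_coverage: pair references a contig other than ", contig)
    }
  }
  start0 <- pmin(pairs$pos1, pairs$pos2)
  end0 <- pmax(pairs$end1, pairs$end2)
  if (length(start0) && any(end0 > contig_length)) {
    stop("pair extends past the end of contig ", contig)
  }
  cov <- IRanges::coverage(IRanges::IRanges(start = start0 + 1, end = end0),
                           width = contig_length)
  structure(list(contig = contig, coverage = as.integer(cov)),
            class = "PhysicalCoverageProfile")
}

#' @export
print.PhysicalCoverageProfile <- function(x, ...) {
  cat(sprintf("PhysicalCoverageProfile for %s: %d bases, median %g\n",
              x$contig, length(x$coverage),
              stats::median(x$coverage)))
  invisible(x)
}

#' Deepest low-coverage interval of a profile
#'
#' Finds the contiguous interval minimizing the sum of
#' `coverage - delta`, i.e. the region most consistently below the expected
#' coverage level — a minimum-sum-subarray variant of Kadane's algorithm,
#' computed here from prefix sums in one vectorized pass. Returns `NULL`
#' when no interval falls below the expectation (minimum sum >= 0).
#'
#' @param profile a `PhysicalCoverageProfile` (or a bare numeric coverage
#'   vector, in which case `contig` names the output).
#' @param delta expected per-base coverage level (> 0).
#' @param contig contig name used when `profile` is a bare vector.
#' @return a `BreakCall` — list with `contig`, 0-based half-open
#'   `start`/`end` and negative `score` (the deficit) — or `NULL`.
#' @export
find_low_coverage_interval <- function(profile, delta, contig = NA_character_) {
  if (inherits(profile, "PhysicalCoverageProfile")) {
    contig <- profile$contig
    cov <- profile$coverage
  } else {
    cov <- profile
  }
  if (!length(cov)) stop("empty coverage profile")
  stopifnot(delta > 0)
  # P[i+1] = sum of the first i shifted values; the deepest interval ending
  # at i has sum P[i+1] - max(P[1..i]); ties resolve to the earliest end and
  # the earliest compatible start, so output is deterministic.
  p <- c(0, cumsum(cov - delta))
  n <- length(cov)
  cm <- cummax(p[seq_len(n)])
  ending <- p[seq_len(n) + 1L] - cm
  j <- which.min(ending)
  score <- ending[j]
  if (score >= 0) return(NULL)
  start <- which(p[seq_len(j)] == cm[j])[1] - 1L
  structure(list(contig = contig, start = start, end = j, score = score),
            class = "BreakCall")
}

#' Detect misassembly break points from physical coverage
#'
#' Runs the low-coverage scan on every contig and returns accepted break
#' calls. Because the subarray scan yields one interval at a time, detection
#' iterates: the deepest accepted deficit splits the profile at the interval
#' midpoint and both halves are re-scanned (with `delta` re-estimated on the
#' half) until no further call passes. An accepted call must carry a deficit
#' at least `delta * min_equiv_span` (the equivalent of `min_equiv_span`
#' bases of entirely missing coverage) and its midpoint must lie at least
#' `edge_margin` bases from both ends of the segment under scan — physical
#' coverage necessarily ramps to zero at sequence ends, so terminal dips are
#' not evidence of misassembly.
#'
#' @param pairs MAPQ-filtered pair table (intra-contig pairs are used).
#' @param contigs a `ContigSet`.
#' @param delta expected-coverage level; `NULL` (default) estimates it per
#'   contig as half the median of the nonzero per-base physical coverage.
#' @param min_equiv_span minimum deficit expressed as a span of fully absent
#'   coverage, in bases (default 5000).
#' @param edge_margin exclusion zone at segment ends, bases (default 10000).
#' @return a data.frame of break calls: `contig`, `start`, `end`, `score`,
#'   `midpoint` (coordinates on the original contig, 0-based).
#' @export
detect_breaks <- function(pairs, contigs, delta = NULL,
                          min_equiv_span = 5000, edge_margin = 10000) {
  validate_pairs(pairs, contigs)
  intra <- pairs[pairs$contig1 == pairs$contig2, , drop = FALSE]
  len <- contig_lengths(contigs)
  by_contig <- split(intra, intra$contig1)
  calls <- list()
  for (ctg in names(contigs)) {
    sub <- by_contig[[ctg]]
    if (is.null(sub) || !nrow(sub)) next
    prof <- physical_coverage(sub, ctg, len[[ctg]])
    calls[[ctg]] <- scan_segment(prof$coverage, 0L, ctg, delta,
                                 min_equiv_span, edge_margin)
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls)) {
    calls <- data.frame(contig = character(), start = numeric(),
                        end = numeric(), score = numeric(),
                        midpoint = numeric(), stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  calls[order(calls$contig, calls$start), , drop = FALSE]
}

# recursive scan of one coverage segment; offset converts back to original
# contig coordinates
scan_segment <- function(cov, offset, ctg, delta, min_equiv_span,
                         edge_margin) {
  if (length(cov) < 2 * edge_margin) return(NULL)
  d <- delta
  if (is.null(d)) {
    nz <- cov[cov > 0]
    if (!length(nz)) return(NULL)
    d <- stats::median(nz) / 2
    if (d <= 0) return(NULL)
  }
  call <- find_low_coverage_interval(cov, d, ctg)
  if (is.null(call)) return(NULL)
  mid <- floor((call$start + call$end) / 2)
  if (-call$score < d * min_equiv_span) return(NULL)
  if (mid < edge_margin || mid > length(cov) - edge_margin) return(NULL)
  here <- data.frame(contig = ctg, start = offset + call$start,
                     end = offset + call$end, score = call$score,
                     midpoint = offset + mid, stringsAsFactors = FALSE)
  rbind(
    scan_segment(cov[seq_len(mid)], offset, ctg, delta, min_equiv_span,
                 edge_margin),
    here,
    scan_segment(cov[(mid + 1):length(cov)], offset + mid, ctg, delta,
                 min_equiv_span, edge_margin)
  )
}

#' Split contigs at accepted break calls
#'
#' Each accepted call (deficit magnitude at least `min_score_magnitude`,
#' midpoint at least `edge_margin` from both ends of the piece it falls in)
#' splits its contig at the interval midpoint into `<name>_1` and
#' `<name>_2`; further calls on the same contig split the pieces recursively.
#' Calls on one contig are applied deepest-deficit first; a call whose
#' midpoint no longer clears the margin inside its (already split) piece is
#' dropped. Total bases are conserved.
#'
#' @param contigs a `ContigSet`.
#' @param calls break-call data.frame from [detect_breaks()] (columns
#'   `contig`, `start`, `end`, `score`; `midpoint` optional).
#' @param min_score_magnitude minimum `|score|` for a call to be applied
#'   (default 0: calls are assumed pre-vetted).
#' @param edge_margin minimum distance of a split point from the ends of the
#'   piece being split (default 10000 bases).
#' @return a list with `contigs` (the post-break `ContigSet`) and `remap`, a
#'   data.frame mapping original coordinate intervals to new contigs:
#'   `orig_contig`, `orig_start`, `orig_end`, `new_contig` (new coordinates
#'   are original minus `orig_start`).
#' @export
break_contigs <- function(contigs, calls, min_score_magnitude = 0,
                          edge_margin = 10000) {
  stopifnot(inherits(contigs, "ContigSet"))
  len <- contig_lengths(contigs)
  if (nrow(calls) && length(bad <- setdiff(calls$contig, names(contigs)))) {
    stop("break call references unknown contig(s): ",
         paste(bad, collapse = ", "))
  }
  calls <- calls[abs(calls$score) >= min_score_magnitude, , drop = FALSE]
  pieces_by_contig <- lapply(names(contigs), function(ctg) {
    pieces <- data.frame(start = 0, end = len[[ctg]], name = ctg,
                         stringsAsFactors = FALSE)
    sub <- calls[calls$contig == ctg, , drop = FALSE]
    if (!nrow(sub)) return(pieces)
    sub <- sub[order(sub$score), , drop = FALSE]  # deepest deficit first
    mids <- if ("midpoint" %in% colnames(sub)) sub$midpoint
            else floor((sub$start + sub$end) / 2)
    for (m in mids) {
      i <- which(pieces$start < m & m < pieces$end)
      if (!length(i)) next
      i <- i[1]
      if (m - pieces$start[i] < edge_margin ||
          pieces$end[i] - m < edge_margin) next
      parent <- pieces[i, ]
      left <- data.frame(start = parent$start, end = m,
                         name = paste0(parent$name, "_1"))
      right <- data.frame(start = m, end = parent$end,
                          name = paste0(parent$name, "_2"))
      pieces <- rbind(pieces[seq_len(i - 1), , drop = FALSE], left, right,
                      pieces[-seq_len(i), , drop = FALSE])
    }
    pieces
  })
  names(pieces_by_contig) <- names(contigs)
  remap <- do.call(rbind, lapply(names(contigs), function(ctg) {
    p <- pieces_by_contig[[ctg]]
    data.frame(orig_contig = ctg, orig_start = p$start, orig_end = p$end,
               new_contig = p$name, stringsAsFactors = FALSE)
  }))
  rownames(remap) <- NULL
  new_names <- remap$new_contig
  new_lengths <- remap$orig_end - remap$orig_start
  new_seqs <- NULL
  if (has_sequences(contigs)) {
    new_seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(remap)),
      function(i) {
        Biostrings::subseq(contigs$seq[[remap$orig_contig[i]]],
                           start = remap$orig_start[i] + 1,
                           end = remap$orig_end[i])
      }))
  }
  list(contigs = contig_set(new_names, new_lengths, new_seqs),
       remap = remap)
}

#' Remap a pair table through a contig-break remapping
#'
#' Mates are assigned to pieces by their leftmost mapped base; a mate
#' interval straddling a break point is clipped to the piece containing its
#' start.
#'
#' @param pairs a pair table in pre-break contig coordinates.
#' @param remap remapping table from [break_contigs()].
#' @return the pair table in post-break contig coordinates.
#' @export
remap_pairs <- function(pairs, remap) {
  validate_pairs(pairs)
  map_mate <- function(ctg, pos, end) {
    new_ctg <- ctg
    new_pos <- pos
    new_end <- end
    for (oc in unique(remap$orig_contig)) {
      sub <- remap[remap$orig_contig == oc, , drop = FALSE]
      if (nrow(sub) == 1 && sub$new_contig[1] == oc) next
      sel <- which(ctg == oc)
      if (!length(sel)) next
      idx <- findInterval(pos[sel], sub$orig_start)
      new_ctg[sel] <- sub$new_contig[idx]
      new_pos[sel] <- pos[sel] - sub$orig_start[idx]
      new_end[sel] <- pmin(end[sel], sub$orig_end[idx]) - sub$orig_start[idx]
    }
    list(ctg = new_ctg, pos = new_pos, end = new_end)
  }
  m1 <- map_mate(pairs$contig1, pairs$pos1, pairs$end1)
  m2 <- map_mate(pairs$contig2, pairs$pos2, pairs$end2)
  pairs$contig1 <- m1$ctg; pairs$pos1 <- m1$pos; pairs$end1 <- m1$end
  pairs$contig2 <- m2$ctg; pairs$pos2 <- m2$pos; pairs$end2 <- m2$end
  pairs
}

#' Write break calls as BED
#' @param calls break-call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breaks_bed <- function(calls, path) {
  if (!nrow(calls)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- data.frame(calls$contig, format_coord(calls$start),
                    format_coord(calls$end), ".", calls$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
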