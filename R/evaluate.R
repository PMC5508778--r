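#' True contig adjacencies of a simulated fragmentation
#'
#' Derives, from the fragmentation truth, the ordered pairs of
#' single-fragment contigs that are directly adjacent on a chromosome,
#' with the orientation each contig must take to reproduce the genome.
#' Chimeric contigs are excluded: they have no single true position.
#'
#' @param parts truth table from [fragment_into_contigs()].
#' @return data.frame with `ctg_a`, `ctg_b`, `strand_a`, `strand_b`
#'   (`+` means the contig in forward orientation reads the genome strand).
#' @export
truth_adjacencies <- function(parts) {
  n_parts <- table(parts$contig)
  single <- names(n_parts)[n_parts == 1]
  p <- parts[parts$contig %in% single, , drop = FALSE]
  rows <- list()
  for (ch in unique(p$chrom)) {
    sub <- p[p$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$gstart), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      if (sub$gend[i] != sub$gstart[i + 1]) next  # a chimera ate the gap
      rows[[length(rows) + 1]] <- data.frame(
        ctg_a = sub$contig[i], ctg_b = sub$contig[i + 1],
        strand_a = sub$strand[i], strand_b = sub$strand[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(ctg_a = character(), ctg_b = character(),
                      strand_a = character(), strand_b = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Order and orientation accuracy of layouts against simulation truth
#'
#' An adjacency is *recovered* when its two contigs are placed next to
#' each other in some layout (in either direction). Among recovered
#' adjacencies, the orientation is *correct* when the relative
#' configuration matches the genome: contig A then B with both in their
#' true strands, or B then A with both flipped.
#'
#' @param layouts list of `ScaffoldLayout`s.
#' @param parts truth table from [fragment_into_contigs()].
#' @return list with `n_truth`, `n_recovered`, `adjacency_recall`,
#'   `n_orient_correct`, `orientation_accuracy`.
#' @export
evaluate_layouts <- function(layouts, parts) {
  truth <- truth_adjacencies(parts)
  placed <- do.call(rbind, lapply(layouts, function(l) l$placements))
  adj <- list()
  for (l in layouts) {
    p <- l$placements
    if (nrow(p) < 2) next
    adj[[length(adj) + 1]] <- data.frame(
      a = p$contig[-nrow(p)], oa = p$orientation[-nrow(p)],
      b = p$contig[-1], ob = p$orientation[-1], stringsAsFactors = FALSE)
  }
  adj <- if (length(adj)) do.call(rbind, adj) else
    data.frame(a = character(), oa = character(), b = character(),
               ob = character(), stringsAsFactors = FALSE)
  to_orient <- function(strand) ifelse(strand == "+", "forward", "reverse")
  flip <- function(o) ifelse(o == "forward", "reverse", "forward")
  n_rec <- 0L
  n_ori <- 0L
  for (i in seq_len(nrow(truth))) {
    fwd <- which(adj$a == truth$ctg_a[i] & adj$b == truth$ctg_b[i])
    rev <- which(adj$a == truth$ctg_b[i] & adj$b == truth$ctg_a[i])
    if (!length(fwd) && !length(rev)) next
    n_rec <- n_rec + 1L
    oa <- to_orient(truth$strand_a[i])
    ob <- to_orient(truth$strand_b[i])
    ok <- FALSE
    if (length(fwd)) {
      ok <- any(adj$oa[fwd] == oa & adj$ob[fwd] == ob)
    }
    if (!ok && length(rev)) {
      ok <- any(adj$oa[rev] == flip(ob) & adj$ob[rev] == flip(oa))
    }
    if (ok) n_ori <- n_ori + 1L
  }
  list(n_truth = nrow(truth), n_recovered = n_rec,
       adjacency_recall = if (nrow(truth)) n_rec / nrow(truth) else NA_real_,
       n_orient_correct = n_ori,
       orientation_accuracy = if (n_rec) n_ori / n_rec else NA_real_)
}

#' Break-call accuracy against chimera truth
#'
#' A true junction counts as detected when an accepted break midpoint on
#' its contig lies within `tol` bases of it; a break counts as false when
#' it is farther than `tol` from every junction of its contig. The
#' false-break rate is scaled per 10 clean (non-chimeric) contigs.
#'
#' @param calls break-call data.frame from [detect_breaks()].
#' @param chimeras chimera truth table (`contig`, `junction`).
#' @param contigs the pre-break `ContigSet` (for the clean-contig count).
#' @param tol matching tolerance in bases (default 5000).
#' @return list with `n_junctions`, `n_detected`, `recall`, `n_false`,
#'   `n_clean_contigs`, `false_per_10_clean`.
#' @export
evaluate_breaks <- function(calls, chimeras, contigs, tol = 5000) {
  mids <- if (nrow(calls)) {
    if ("midpoint" %in% colnames(calls)) calls$midpoint
    else floor((calls$start + calls$end) / 2)
  } else numeric(0)
  detected <- vapply(seq_len(nrow(chimeras)), function(i) {
    on_ctg <- calls$contig == chimeras$contig[i]
    any(on_ctg & abs(mids - chimeras$junction[i]) <= tol)
  }, logical(1))
  false_call <- vapply(seq_len(nrow(calls)), function(j) {
    junc <- chimeras$junction[chimeras$contig == calls$contig[j]]
    !length(junc) || all(abs(mids[j] - junc) > tol)
  }, logical(1))
  n_clean <- length(setdiff(names(contigs), chimeras$contig))
  list(n_junctions = nrow(chimeras), n_detected = sum(detected),
       recall = if (nrow(chimeras)) sum(detected) / nrow(chimeras)
                else NA_real_,
       n_false = sum(false_call), n_clean_contigs = n_clean,
       false_per_10_clean = if (n_clean) 10 * sum(false_call) / n_clean
                            else NA_real_)
}
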