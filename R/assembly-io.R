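#' Read a contig FASTA into a ContigSet
#'
#' Sequences are uppercased; contig names are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA path.
#' @return a `ContigSet` with sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) return(contig_set(character(), numeric()))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- nm
  contig_set(nm, Biostrings::width(seqs), seqs)
}

#' AGP table for a set of layouts
#'
#' Builds the AGP v2.1 description of the scaffolds: one `W` line per
#' placed contig and one `N` gap line (gap type `scaffold`, linkage `yes`,
#' evidence `proximity_ligation`) between consecutive contigs. Scaffolds
#' are named `scaffold_<k>` in order of decreasing scaffold length
#' (contig bases plus gaps).
#'
#' @param layouts list of `ScaffoldLayout`s.
#' @param contigs a `ContigSet` (lengths are sufficient).
#' @param gap_size length of the N gap between consecutive contigs
#'   (default 500).
#' @return data.frame with the nine AGP columns.
#' @export
agp_table <- function(layouts, contigs, gap_size = 500) {
  len <- contig_lengths(contigs)
  missing <- setdiff(unlist(lapply(layouts, function(l) l$placements$contig)),
                     names(contigs))
  if (length(missing)) {
    stop("layout places unknown contig(s): ", paste(missing, collapse = ", "))
  }
  scaff_len <- vapply(layouts, function(l) {
    sum(len[l$placements$contig]) +
      gap_size * max(0, nrow(l$placements) - 1)
  }, numeric(1))
  ord <- order(-scaff_len, vapply(layouts, function(l)
    l$placements$contig[1], character(1)))
  rows <- list()
  for (k in seq_along(ord)) {
    l <- layouts[[ord[k]]]
    obj <- sprintf("scaffold_%d", k)
    at <- 1
    part <- 0
    for (i in seq_len(nrow(l$placements))) {
      if (i > 1) {
        part <- part + 1
        rows[[length(rows) + 1]] <- data.frame(
          object = obj, object_beg = at, object_end = at + gap_size - 1,
          part_number = part, component_type = "N",
          c6 = as.character(gap_size), c7 = "scaffold", c8 = "yes",
          c9 = "proximity_ligation", stringsAsFactors = FALSE)
        at <- at + gap_size
      }
      ctg <- l$placements$contig[i]
      w <- len[[ctg]]
      part <- part + 1
      rows[[length(rows) + 1]] <- data.frame(
        object = obj, object_beg = at, object_end = at + w - 1,
        part_number = part, component_type = "W",
        c6 = ctg, c7 = "1", c8 = as.character(w),
        c9 = if (l$placements$orientation[i] == "forward") "+" else "-",
        stringsAsFactors = FALSE)
      at <- at + w
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("object", "object_beg", "object_end", "part_number",
                     "component_type", "component_id_or_gap_length",
                     "component_beg_or_gap_type",
                     "component_end_or_linkage",
                     "orientation_or_evidence")
  out
}

#' Write scaffold FASTA and AGP
#'
#' Each layout becomes one FASTA record: its contig sequences in order,
#' reverse placements reverse-complemented, separated by `gap_size` Ns.
#' The AGP file describes the identical structure, so the two outputs are
#' mutually reconstructible.
#'
#' @param layouts list of `ScaffoldLayout`s.
#' @param contigs a `ContigSet` with sequences.
#' @param fasta_path,agp_path output paths (`NULL` to skip one of them).
#' @param gap_size gap length in Ns (default 500).
#' @return the AGP data.frame, invisibly.
#' @export
write_scaffolds <- function(layouts, contigs, fasta_path, agp_path = NULL,
                            gap_size = 500) {
  if (!has_sequences(contigs)) {
    stop("scaffold FASTA output needs contig sequences")
  }
  agp <- agp_table(layouts, contigs, gap_size)
  if (!is.null(fasta_path)) {
    seqs <- scaffolds_from_agp(agp, contigs)
    Biostrings::writeXStringSet(seqs, fasta_path, width = 60)
  }
  if (!is.null(agp_path)) {
    con <- file(agp_path, "w")
    writeLines("##agp-version\t2.1", con)
    utils::write.table(agp, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(agp)
}

#' Reconstruct scaffold sequences from an AGP table
#'
#' Independent reconstruction used for output validation: builds every
#' scaffold from its AGP component lines and the contig sequences.
#'
#' @param agp AGP data.frame (as from [agp_table()]) or path to an AGP
#'   file.
#' @param contigs a `ContigSet` with sequences.
#' @return a [Biostrings::DNAStringSet] of scaffold sequences.
#' @export
scaffolds_from_agp <- function(agp, contigs) {
  if (is.character(agp)) agp <- read_agp(agp)
  out <- list()
  for (obj in unique(agp$object)) {
    sub <- agp[agp$object == obj, , drop = FALSE]
    sub <- sub[order(sub$part_number), , drop = FALSE]
    parts <- lapply(seq_len(nrow(sub)), function(i) {
      if (sub$component_type[i] == "N") {
        strrep("N", as.integer(sub$component_id_or_gap_length[i]))
      } else {
        ctg <- sub$component_id_or_gap_length[i]
        s <- contig_sequence(contigs, ctg)
        s <- Biostrings::subseq(
          s, as.integer(sub$component_beg_or_gap_type[i]),
          as.integer(sub$component_end_or_linkage[i]))
        if (sub$orientation_or_evidence[i] == "-") {
          s <- Biostrings::reverseComplement(s)
        }
        as.character(s)
      }
    })
    out[[obj]] <- paste(unlist(parts), collapse = "")
  }
  Biostrings::DNAStringSet(unlist(out))
}

#' Read an AGP file
#' @param path AGP path.
#' @return AGP data.frame in the column layout of [agp_table()].
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    stop("malformed AGP line: expected 9 columns")
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  data.frame(object = m[, 1], object_beg = as.numeric(m[, 2]),
             object_end = as.numeric(m[, 3]),
             part_number = as.integer(m[, 4]), component_type = m[, 5],
             component_id_or_gap_length = m[, 6],
             component_beg_or_gap_type = m[, 7],
             component_end_or_linkage = m[, 8],
             orientation_or_evidence = m[, 9], stringsAsFactors = FALSE)
}

#' NG50 of a set of scaffold lengths
#'
#' Length of the scaffold at which scaffolds that long or longer cover half
#' of the (estimated) genome size.
#'
#' @param lengths numeric scaffold lengths.
#' @param genome_size assumed genome size in bases.
#' @return NG50 in bases (`NA` if the scaffolds cover less than half the
#'   genome).
#' @export
ng50 <- function(lengths, genome_size) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= genome_size / 2)
  if (!length(i)) return(NA_real_)
  s[i[1]]
}
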