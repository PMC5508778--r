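#' Contig set container
#'
#' A `ContigSet` holds an ordered collection of uniquely named contigs with
#' their lengths and, optionally, their DNA sequences. Sequences are required
#' only for operations that inspect the bases themselves (restriction-site
#' counting, scaffold FASTA output); everything else runs on names and
#' lengths alone.
#'
#' @param names character vector of unique contig names.
#' @param lengths integer vector of contig lengths in bases (> 0).
#' @param seqs optional [Biostrings::DNAStringSet] (or named character
#'   vector) of sequences, one per contig, same order as `names`.
#' @return An object of class `ContigSet`.
#' @export
contig_set <- function(names, lengths, seqs = NULL) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) {
    stop("'names' and 'lengths' must have equal length")
  }
  if (anyDuplicated(names)) {
    stop("duplicate contig names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (length(lengths) && any(lengths <= 0)) {
    stop("contig lengths must be > 0")
  }
  if (!is.null(seqs)) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    if (length(seqs) != length(names)) {
      stop("'seqs' must contain one sequence per contig")
    }
    names(seqs) <- names
    if (any(Biostrings::width(seqs) != lengths)) {
      stop("sequence widths disagree with declared contig lengths")
    }
  }
  structure(
    list(info = data.frame(name = names, length = lengths,
                           stringsAsFactors = FALSE),
         seq = seqs),
    class = "ContigSet"
  )
}

#' @export
length.ContigSet <- function(x) nrow(x$info)

#' @export
names.ContigSet <- function(x) x$info$name

#' @export
print.ContigSet <- function(x, ...) {
  cat(sprintf("ContigSet with %d contigs, %.0f bases total (%s sequence)\n",
              length(x), sum(x$info$length),
              if (is.null(x$seq)) "without" else "with"))
  invisible(x)
}

#' Contig lengths as a named vector
#' @param x a `ContigSet`.
#' @return named numeric vector of lengths.
#' @export
contig_lengths <- function(x) {
  stopifnot(inherits(x, "ContigSet"))
  stats::setNames(x$info$length, x$info$name)
}

#' Does a contig set carry sequences?
#' @param x a `ContigSet`.
#' @return logical scalar.
#' @export
has_sequences <- function(x) !is.null(x$seq)

#' Extract one contig's sequence
#' @param x a `ContigSet` with sequences.
#' @param name contig name.
#' @return a [Biostrings::DNAString].
#' @export
contig_sequence <- function(x, name) {
  if (!has_sequences(x)) {
    stop("ContigSet has no sequences; supply a FASTA")
  }
  if (!name %in% names(x)) stop("unknown contig: ", name)
  x$seq[[name]]
}

# internal: check that a pairs data.frame has the canonical columns and that
# every referenced contig exists in the set
pair_columns <- c("read_id",
                  "contig1", "pos1", "end1", "strand1", "mapq1",
                  "contig2", "pos2", "end2", "strand2", "mapq2")

validate_pairs <- function(pairs, contigs = NULL) {
  missing <- setdiff(pair_columns, colnames(pairs))
  if (length(missing)) {
    stop("pair table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!is.null(contigs)) {
    known <- names(contigs)
    bad <- setdiff(unique(c(pairs$contig1, pairs$contig2)), known)
    if (length(bad)) {
      stop("alignment references unknown contig(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(pairs)
}

empty_pairs <- function() {
  data.frame(read_id = character(),
             contig1 = character(), pos1 = numeric(), end1 = numeric(),
             strand1 = character(), mapq1 = integer(),
             contig2 = character(), pos2 = numeric(), end2 = numeric(),
             strand2 = character(), mapq2 = integer(),
             stringsAsFactors = FALSE)
}
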