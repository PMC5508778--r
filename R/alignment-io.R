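#' Read paired Hi-C alignments
#'
#' Parses Hi-C read-pair alignments into the internal pair table, one row per
#' read pair with both mates mapped. Two dialects are supported:
#'
#' * `"sam"` — SAM/BAM via Rsamtools. Only primary records are considered
#'   (secondary and supplementary alignments are ignored); a pair is emitted
#'   only when both of its primary mates are mapped. SAM's 1-based positions
#'   are converted to 0-based half-open.
#' * `"bed_pairs"` — a plain tab-separated table with ten columns
#'   `contig1 start1 end1 contig2 start2 end2 read_id mapq1 mapq2 strands`,
#'   0-based half-open coordinates, `strands` a two-character string such as
#'   `"+-"`. Lines starting with `#` are comments.
#'
#' @param path path to a SAM, BAM or bed_pairs file. `.sam`/`.bam` extensions
#'   select the SAM dialect automatically.
#' @param dialect `"sam"`, `"bed_pairs"`, or `"auto"` (default: guess from
#'   the file extension, falling back to bed_pairs).
#' @param contigs optional `ContigSet`; when given, every referenced contig
#'   name is checked against it.
#' @return a data.frame with columns `read_id`, and `contig`, `pos`, `end`,
#'   `strand`, `mapq` for each mate (suffixes `1`/`2`); coordinates 0-based
#'   half-open.
#' @export
read_alignments <- function(path, dialect = c("auto", "sam", "bed_pairs"),
                            contigs = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE))
      "sam" else "bed_pairs"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  pairs <- switch(dialect,
                  sam = read_pairs_sam(path),
                  bed_pairs = read_pairs_bed(path))
  if (!is.null(contigs)) {
    validate_pairs(pairs, contigs)
    len <- contig_lengths(contigs)
    bad <- pairs$end1 > len[pairs$contig1] | pairs$end2 > len[pairs$contig2]
    if (any(bad)) {
      stop("alignment coordinates exceed contig length for pair(s): ",
           paste(utils::head(pairs$read_id[bad], 5), collapse = ", "))
    }
  }
  pairs
}

read_pairs_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0) return(empty_pairs())
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  rec_df <- data.frame(
    read_id = rec$qname,
    contig = as.character(rec$rname),
    pos = rec$pos - 1,
    end = rec$pos - 1 + rw,
    strand = as.character(rec$strand),
    mapq = as.integer(rec$mapq),
    mate = ifelse(bitwAnd(rec$flag, 0x40L) > 0L, 1L, 2L),
    stringsAsFactors = FALSE)
  dt <- data.table::as.data.table(rec_df)
  m1 <- dt[dt$mate == 1L][, utils::head(.SD, 1L), by = "read_id"]
  m2 <- dt[dt$mate == 2L][, utils::head(.SD, 1L), by = "read_id"]
  both <- merge(m1, m2, by = "read_id", suffixes = c("1", "2"))
  out <- as.data.frame(both)[, pair_columns]
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_pairs_bed <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_pairs())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    stop("malformed bed_pairs record (expected 10 tab-separated columns) ",
         "at line ", lineno[which(nf != 10L)[1]])
  }
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop("malformed bed_pairs ", what, " at line ",
           lineno[which(is.na(v))[1]])
    }
    v
  }
  strands <- m[, 10]
  if (any(!grepl("^[+-][+-]$", strands))) {
    stop("malformed strands column at line ",
         lineno[which(!grepl("^[+-][+-]$", strands))[1]])
  }
  data.frame(
    read_id = m[, 7],
    contig1 = m[, 1], pos1 = num(1 + 1, "start1"), end1 = num(3, "end1"),
    strand1 = substr(strands, 1, 1), mapq1 = as.integer(num(8, "mapq1")),
    contig2 = m[, 4], pos2 = num(5, "start2"), end2 = num(6, "end2"),
    strand2 = substr(strands, 2, 2), mapq2 = as.integer(num(9, "mapq2")),
    stringsAsFactors = FALSE)[, pair_columns]
}

#' Write a pair table in the bed_pairs dialect
#'
#' @param pairs a pair table as returned by [read_alignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_pairs <- function(pairs, path) {
  validate_pairs(pairs)
  out <- data.frame(pairs$contig1, format_coord(pairs$pos1),
                    format_coord(pairs$end1),
                    pairs$contig2, format_coord(pairs$pos2),
                    format_coord(pairs$end2),
                    pairs$read_id, pairs$mapq1, pairs$mapq2,
                    paste0(pairs$strand1, pairs$strand2))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Filter read pairs on mapping quality
#'
#' Keeps exactly the pairs in which both mates exceed the threshold; a pair
#' with one confidently mapped and one ambiguous mate is dropped whole, since
#' its linkage evidence is only as good as its worse mate. Multi-mapping
#' reads carry low mapping quality and are removed by the same filter.
#'
#' @param pairs a pair table.
#' @param threshold minimum exclusive mapping quality (default 30: a pair is
#'   kept iff both mates have MAPQ > 30).
#' @return the filtered pair table.
#' @export
filter_by_mapq <- function(pairs, threshold = 30) {
  stopifnot(threshold >= 0)
  validate_pairs(pairs)
  keep <- pairs$mapq1 > threshold & pairs$mapq2 > threshold
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove coordinate-duplicate read pairs
#'
#' Optional PCR-duplicate style deduplication: pairs with identical mate
#' coordinates (contig, start, end, both mates) are collapsed to one,
#' keeping the first occurrence. Duplicates are retained by default
#' throughout the pipeline; this is opt-in.
#'
#' @param pairs a pair table.
#' @return the deduplicated pair table.
#' @export
dedup_pairs <- function(pairs) {
  validate_pairs(pairs)
  key <- paste(pairs$contig1, pairs$pos1, pairs$end1,
               pairs$contig2, pairs$pos2, pairs$end2, sep = "\r")
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
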