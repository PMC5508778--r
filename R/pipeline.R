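#' Run the scaffolding pipeline end to end
#'
#' Stages, in order: read contigs and alignments; drop pairs failing the
#' mapping-quality filter; optionally detect and apply misassembly breaks
#' (remapping the pairs onto the broken contigs); count end-window links
#' and normalize them by restriction-site counts; build the scaffold graph
#' greedily and break cycles; extract paths; insert small-scaffold contigs
#' into seeds; write all artifacts. The pipeline itself uses no random
#' numbers, so identical inputs and parameters give byte-identical output.
#'
#' @param contigs a `ContigSet` (with sequences for normalization/FASTA
#'   output) or path to a contig FASTA.
#' @param alignments a pair table or path to a SAM/BAM/bed_pairs file.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and returns results in memory only.
#' @param motifs restriction enzyme motif(s), e.g. `"GATC"`; `NULL`
#'   selects raw-count mode (weights are raw link counts). `raw_counts`
#'   must then be `TRUE`, as a guard against silently unnormalized runs.
#' @param raw_counts set `TRUE` to score edges by raw link counts without
#'   restriction-site normalization.
#' @param l end-window length in bases (default 500000).
#' @param mapq_threshold exclusive MAPQ cutoff (default 30).
#' @param min_links minimum raw links per candidate edge (default 5).
#' @param n_th seed threshold: seeds have more than `n_th` contigs
#'   (default 3).
#' @param gap_size N-gap length between scaffolded contigs (default 500).
#' @param break_detection run misassembly detection (default `TRUE`).
#' @param break_min_equiv_span,break_edge_margin detection thresholds, see
#'   [detect_breaks()].
#' @param dedup drop coordinate-duplicate pairs first (default `FALSE`).
#' @return list with `layouts`, `contigs` (post-break), `breaks`, `remap`,
#'   `graph`, `candidates`, `agp`, `stats` (per-stage counters), and
#'   `out_dir`.
#' @export
run_scaffold <- function(contigs, alignments, out_dir = NULL,
                         motifs = NULL, raw_counts = is.null(motifs),
                         l = 5e5, mapq_threshold = 30, min_links = 5,
                         n_th = 3, gap_size = 500,
                         break_detection = TRUE,
                         break_min_equiv_span = 5000,
                         break_edge_margin = 10000,
                         dedup = FALSE) {
  if (is.character(contigs)) contigs <- read_fasta(contigs)
  if (is.character(alignments)) {
    alignments <- read_alignments(alignments, contigs = contigs)
  }
  validate_pairs(alignments, contigs)
  if (is.null(motifs) && !raw_counts) {
    stop("no restriction enzyme motif given; pass motifs= or opt in to ",
         "raw_counts = TRUE")
  }
  stats <- list(pairs_read = nrow(alignments))
  pairs <- filter_by_mapq(alignments, mapq_threshold)
  if (dedup) pairs <- dedup_pairs(pairs)
  stats$pairs_passing_mapq <- nrow(pairs)

  breaks <- data.frame(contig = character(), start = numeric(),
                       end = numeric(), score = numeric(),
                       midpoint = numeric(), stringsAsFactors = FALSE)
  remap <- NULL
  if (break_detection) {
    breaks <- detect_breaks(pairs, contigs,
                            min_equiv_span = break_min_equiv_span,
                            edge_margin = break_edge_margin)
    if (nrow(breaks)) {
      bk <- break_contigs(contigs, breaks,
                          edge_margin = break_edge_margin)
      contigs <- bk$contigs
      remap <- bk$remap
      pairs <- remap_pairs(pairs, remap)
    }
  }
  stats$breaks_applied <- nrow(breaks)

  cand <- candidate_edges(pairs, contigs, l = l,
                          motifs = if (raw_counts) NULL else motifs)
  stats$candidate_edges <- nrow(cand)
  graph <- build_graph(cand, contigs, min_links = min_links, l = l,
                       motifs = motifs)
  stats$hic_edges_kept <- sum(graph$edges$kind != "CONTIG")

  layouts <- extract_paths(graph, contigs, n_th = n_th)
  seeds <- Filter(function(x) x$is_seed, layouts)
  smalls <- Filter(function(x) !x$is_seed, layouts)
  stats$seed_scaffolds <- length(seeds)
  stats$small_scaffolds <- length(smalls)
  layouts <- insert_small_contigs(seeds, smalls, cand)
  stats$final_scaffolds <- length(layouts)

  agp <- agp_table(layouts, contigs, gap_size)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (has_sequences(contigs)) {
      write_scaffolds(layouts, contigs,
                      fasta_path = file.path(out_dir, "scaffolds.fasta"),
                      agp_path = file.path(out_dir, "scaffolds.agp"),
                      gap_size = gap_size)
    } else {
      con <- file(file.path(out_dir, "scaffolds.agp"), "w")
      writeLines("##agp-version\t2.1", con)
      utils::write.table(agp, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      close(con)
    }
    write_breaks_bed(breaks, file.path(out_dir, "breaks.bed"))
    if (!is.null(remap)) {
      utils::write.table(remap, file.path(out_dir, "break_remap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_graph_tsv(graph, file.path(out_dir, "graph_edges.tsv"))
    write_layout_tsv(layouts, file.path(out_dir, "layout.tsv"))
    cfg_echo <- list(motifs = motifs, raw_counts = raw_counts, l = l,
                     mapq_threshold = mapq_threshold,
                     min_links = min_links, n_th = n_th,
                     gap_size = gap_size, break_detection = break_detection,
                     break_min_equiv_span = break_min_equiv_span,
                     break_edge_margin = break_edge_margin, dedup = dedup)
    jsonlite::write_json(c(cfg_echo, stats),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  list(layouts = layouts, contigs = contigs, breaks = breaks,
       remap = remap, graph = graph, candidates = cand, agp = agp,
       stats = stats, out_dir = out_dir)
}

#' Generate and write a simulated Hi-C fixture
#'
#' Runs the simulator and writes genome FASTA, contig FASTA, bed_pairs
#' alignments, truth tables (fragmentation parts and chimera junctions)
#' and the config echo into a directory. Seeded and deterministic.
#'
#' @param cfg a `SimConfig`.
#' @param out_dir output directory.
#' @return the simulation list from [simulate_hic_dataset()], invisibly,
#'   with `out_dir` attached.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  sim <- simulate_hic_dataset(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome,
                              file.path(out_dir, "genome.fasta"),
                              width = 60)
  Biostrings::writeXStringSet(sim$contigs$seq,
                              file.path(out_dir, "contigs.fasta"),
                              width = 60)
  write_bed_pairs(sim$pairs, file.path(out_dir, "pairs.bed_pairs"))
  utils::write.table(sim$parts, file.path(out_dir, "truth_parts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$chimeras,
                     file.path(out_dir, "truth_chimeras.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$cfg),
                       file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  sim$out_dir <- out_dir
  invisible(sim)
}
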