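#' Simulation configuration
#'
#' Parameters of the synthetic Hi-C dataset generator. The defaults
#' describe a compact but structurally realistic study system: a
#' 4-chromosome, 8 Mb genome fragmented into ~60 contigs of 50–200 kb,
#' probed by 200,000 Hi-C pairs of which 5% are inter-chromosomal, with
#' intra-chromosomal contact distance decaying exponentially on a 15 kb
#' scale — capturing the two properties the scaffolder relies on: contact
#' probability is much higher within than between chromosomes, and decays
#' rapidly with genomic distance.
#'
#' @param n_chromosomes number of chromosomes (> 0).
#' @param chromosome_length chromosome length in bases.
#' @param contig_min,contig_max uniform bounds on fragment length, bases.
#' @param intra_decay_scale exponential decay length of intra-chromosomal
#'   contact distance, bases.
#' @param p_inter probability that a pair is inter-chromosomal.
#' @param n_pairs number of Hi-C read pairs.
#' @param read_length read length in bases.
#' @param chimera_rate fraction of fragments fused into chimeric contigs
#'   (each chimera consumes two fragments from different chromosomes).
#' @param seed RNG seed; every downstream stage derives its stream from it.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(n_chromosomes = 4, chromosome_length = 2e6,
                       contig_min = 5e4, contig_max = 2e5,
                       intra_decay_scale = 1.5e4, p_inter = 0.05,
                       n_pairs = 2e5, read_length = 100,
                       chimera_rate = 0, seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              contig_min = contig_min, contig_max = contig_max,
              intra_decay_scale = intra_decay_scale, p_inter = p_inter,
              n_pairs = n_pairs, read_length = read_length,
              chimera_rate = chimera_rate, seed = seed)
  if (n_chromosomes < 1) stop("invalid config: n_chromosomes must be >= 1")
  if (chromosome_length <= 0) stop("invalid config: chromosome_length")
  if (contig_min <= 0 || contig_max < contig_min) {
    stop("invalid config: contig length bounds")
  }
  if (p_inter < 0 || p_inter > 1) stop("invalid config: p_inter not in [0,1]")
  if (chimera_rate < 0 || chimera_rate > 1) {
    stop("invalid config: chimera_rate not in [0,1]")
  }
  if (intra_decay_scale <= 0) stop("invalid config: intra_decay_scale")
  if (n_pairs < 0) stop("invalid config: n_pairs")
  if (read_length <= 0) stop("invalid config: read_length")
  structure(cfg, class = "SimConfig")
}

#' Simulate a multi-chromosome genome
#'
#' Uniform-random DNA; restriction sites for common 4-cutters arise
#' naturally (GATC about every 256 bp), so no site planting is needed.
#'
#' @param cfg a `SimConfig`.
#' @return a [Biostrings::DNAStringSet] named `chr1..chrN`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chromosome_length,
                 replace = TRUE), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(cfg$n_chromosomes))
  out
}

#' Fragment a simulated genome into contigs
#'
#' Chromosomes are cut at random points into fragments with lengths
#' uniform on `[contig_min, contig_max]` (a trailing remainder shorter
#' than `contig_min` is merged into the previous fragment). A
#' `chimera_rate` fraction of fragments is fused pairwise across
#' chromosomes into chimeric contigs with the junction recorded. Every
#' contig is reverse-complemented with probability 1/2 and names are
#' assigned in shuffled order, so neither input order nor orientation
#' leaks the truth.
#'
#' @param genome a [Biostrings::DNAStringSet] from [simulate_genome()].
#' @param cfg the same `SimConfig`.
#' @return list with `contigs` (a `ContigSet` with sequences), `parts`
#'   (truth table: `contig`, `part`, `chrom`, `gstart`, `gend`, `cstart`,
#'   `cend`, `strand` — genome interval `[gstart, gend)` maps to contig
#'   interval `[cstart, cend)`, reversed when `strand == "-"`), and
#'   `chimeras` (`contig`, `junction` in contig coordinates).
#' @export
fragment_into_contigs <- function(genome, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  frags <- list()
  for (chrom in names(genome)) {
    L <- length(genome[[chrom]])
    at <- 0
    while (at < L) {
      size <- round(stats::runif(1, cfg$contig_min, cfg$contig_max))
      end <- min(at + size, L)
      if (L - end < cfg$contig_min) end <- L
      frags[[length(frags) + 1]] <- data.frame(
        chrom = chrom, gstart = at, gend = end, stringsAsFactors = FALSE)
      at <- end
    }
  }
  frags <- do.call(rbind, frags)
  n_frag <- nrow(frags)
  n_chim <- round(cfg$chimera_rate * n_frag)
  # pick chimera partners from different chromosomes
  pool <- sample(n_frag)
  chim_pairs <- list()
  while (length(chim_pairs) < n_chim && length(pool) >= 2) {
    a <- pool[1]
    partner <- which(frags$chrom[pool[-1]] != frags$chrom[a])
    if (!length(partner)) break
    b <- pool[-1][partner[1]]
    chim_pairs[[length(chim_pairs) + 1]] <- c(a, b)
    pool <- setdiff(pool, c(a, b))
  }
  chim_members <- unlist(chim_pairs)
  singles <- setdiff(seq_len(n_frag), chim_members)
  part_sets <- c(lapply(singles, function(i) frags[i, , drop = FALSE]),
                 lapply(chim_pairs, function(p) frags[p, , drop = FALSE]))
  n_ctg <- length(part_sets)
  flip <- sample(c(TRUE, FALSE), n_ctg, replace = TRUE)
  name_order <- sample(n_ctg)
  ctg_names <- sprintf("contig_%04d", name_order)
  parts <- list()
  chimeras <- list()
  seqs <- character(n_ctg)
  for (i in seq_len(n_ctg)) {
    ps <- part_sets[[i]]
    ps$strand <- "+"
    if (flip[i]) {
      ps <- ps[rev(seq_len(nrow(ps))), , drop = FALSE]
      ps$strand <- "-"
    }
    widths <- ps$gend - ps$gstart
    ps$cstart <- cumsum(c(0, widths[-length(widths)]))
    ps$cend <- ps$cstart + widths
    ps$contig <- ctg_names[i]
    ps$part <- seq_len(nrow(ps))
    parts[[i]] <- ps
    if (nrow(ps) > 1) {
      chimeras[[length(chimeras) + 1]] <- data.frame(
        contig = ctg_names[i], junction = ps$cend[1],
        stringsAsFactors = FALSE)
    }
    pieces <- vapply(seq_len(nrow(ps)), function(j) {
      s <- Biostrings::subseq(genome[[ps$chrom[j]]],
                              ps$gstart[j] + 1, ps$gend[j])
      if (ps$strand[j] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    seqs[i] <- paste(pieces, collapse = "")
  }
  parts <- do.call(rbind, parts)[, c("contig", "part", "chrom", "gstart",
                                     "gend", "cstart", "cend", "strand")]
  rownames(parts) <- NULL
  chimeras <- if (length(chimeras)) do.call(rbind, chimeras) else
    data.frame(contig = character(), junction = numeric(),
               stringsAsFactors = FALSE)
  ord <- order(ctg_names)
  contigs <- contig_set(ctg_names[ord], nchar(seqs)[ord], seqs[ord])
  list(contigs = contigs, parts = parts, chimeras = chimeras)
}

#' Simulate Hi-C read pairs over a fragmented genome
#'
#' Each pair is inter-chromosomal with probability `p_inter` (two uniform
#' loci on distinct chromosomes); otherwise one locus is uniform and its
#' mate lies at a signed distance drawn from an exponential with scale
#' `intra_decay_scale`, reflected at chromosome ends. Reads of
#' `read_length` bases are placed at each locus and mapped through the
#' fragmentation truth into contig coordinates (clipped at part
#' boundaries), yielding perfect MAPQ-60 alignments. Pairs landing in one
#' contig are kept — they are the input of misassembly detection.
#'
#' @param genome genome from [simulate_genome()] (only lengths are used).
#' @param parts truth table from [fragment_into_contigs()].
#' @param cfg the same `SimConfig`.
#' @return list with `pairs` (pair table in contig coordinates) and
#'   `truth` (data.frame `chrom1`, `g1`, `chrom2`, `g2`, `inter` in genome
#'   coordinates).
#' @export
simulate_hic_pairs <- function(genome, parts, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 2L)
  L <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- cfg$n_pairs
  rl <- cfg$read_length
  inter <- stats::runif(n) < cfg$p_inter
  chrom1 <- sample(names(L), n, replace = TRUE, prob = L)
  g1 <- floor(stats::runif(n) * (L[chrom1] - rl))
  chrom2 <- chrom1
  g2 <- numeric(n)
  if (any(!inter)) {
    d <- round(stats::rexp(sum(!inter), rate = 1 / cfg$intra_decay_scale)) *
      sample(c(-1, 1), sum(!inter), replace = TRUE)
    gg <- g1[!inter] + d
    lim <- L[chrom1[!inter]] - rl
    for (k in 1:50) {
      out <- gg < 0 | gg > lim
      if (!any(out)) break
      gg <- ifelse(gg < 0, -gg, gg)
      gg <- ifelse(gg > lim, 2 * lim - gg, gg)
    }
    g2[!inter] <- pmin(pmax(gg, 0), lim)
  }
  if (any(inter)) {
    ni <- sum(inter)
    c2 <- sample(names(L), ni, replace = TRUE, prob = L)
    clash <- c2 == chrom1[inter]
    while (any(clash)) {
      c2[clash] <- sample(names(L), sum(clash), replace = TRUE, prob = L)
      clash <- c2 == chrom1[inter]
    }
    chrom2[inter] <- c2
    g2[inter] <- floor(stats::runif(ni) * (L[c2] - rl))
  }
  m1 <- map_reads_to_contigs(chrom1, g1, rl, parts)
  m2 <- map_reads_to_contigs(chrom2, g2, rl, parts)
  pairs <- data.frame(
    read_id = sprintf("pair_%06d", seq_len(n)),
    contig1 = m1$contig, pos1 = m1$pos, end1 = m1$end, strand1 = m1$strand,
    mapq1 = 60L,
    contig2 = m2$contig, pos2 = m2$pos, end2 = m2$end, strand2 = m2$strand,
    mapq2 = 60L, stringsAsFactors = FALSE)
  truth <- data.frame(chrom1 = chrom1, g1 = unname(g1),
                      chrom2 = chrom2, g2 = unname(g2),
                      inter = chrom1 != chrom2, stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

# map genome-space read intervals [g, g+rl) to contig coordinates through
# the fragmentation truth; reads are clipped at fragment boundaries
map_reads_to_contigs <- function(chrom, g, rl, parts) {
  contig <- character(length(g))
  pos <- numeric(length(g))
  end <- numeric(length(g))
  strand <- character(length(g))
  for (ch in unique(chrom)) {
    p <- parts[parts$chrom == ch, , drop = FALSE]
    p <- p[order(p$gstart), , drop = FALSE]
    sel <- which(chrom == ch)
    idx <- findInterval(g[sel], p$gstart)
    ge <- pmin(g[sel] + rl, p$gend[idx])
    fwd <- p$strand[idx] == "+"
    contig[sel] <- p$contig[idx]
    pos[sel] <- ifelse(fwd,
                       p$cstart[idx] + (g[sel] - p$gstart[idx]),
                       p$cstart[idx] + (p$gend[idx] - ge))
    end[sel] <- ifelse(fwd,
                       p$cstart[idx] + (ge - p$gstart[idx]),
                       p$cstart[idx] + (p$gend[idx] - g[sel]))
    strand[sel] <- ifelse(fwd, "+", "-")
  }
  list(contig = contig, pos = pos, end = end, strand = strand)
}

#' Per-chromosome intra/inter contact probability
#'
#' For each chromosome, among all simulated pairs touching it, the
#' fraction that is intra-chromosomal versus inter-chromosomal — the
#' summary statistic that motivates proximity-ligation scaffolding: intra
#' should dominate inter on every chromosome.
#'
#' @param truth truth data.frame from [simulate_hic_pairs()].
#' @return data.frame with `chrom`, `n_touching`, `intra_prob`,
#'   `inter_prob`.
#' @export
contact_probability_summary <- function(truth) {
  chroms <- sort(unique(c(truth$chrom1, truth$chrom2)))
  rows <- lapply(chroms, function(ch) {
    touch <- truth$chrom1 == ch | truth$chrom2 == ch
    intra <- truth$chrom1 == ch & truth$chrom2 == ch
    data.frame(chrom = ch, n_touching = sum(touch),
               intra_prob = sum(intra) / sum(touch),
               inter_prob = 1 - sum(intra) / sum(touch),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the whole simulator
#'
#' Convenience wrapper: genome, fragmentation and Hi-C pairs in one call,
#' fully determined by `cfg$seed`.
#'
#' @param cfg a `SimConfig`.
#' @return list with `genome`, `contigs`, `parts`, `chimeras`, `pairs`,
#'   `truth`, `cfg`.
#' @export
simulate_hic_dataset <- function(cfg = sim_config()) {
  genome <- simulate_genome(cfg)
  frag <- fragment_into_contigs(genome, cfg)
  hic <- simulate_hic_pairs(genome, frag$parts, cfg)
  list(genome = genome, contigs = frag$contigs, parts = frag$parts,
       chimeras = frag$chimeras, pairs = hic$pairs, truth = hic$truth,
       cfg = cfg)
}
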