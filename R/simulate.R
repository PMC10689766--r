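# Synthetic lysogen genomes and virion read pools with machine-readable
# truth. Virion fragments are drawn on the CIRCULAR excised prophage, so a
# predictable fraction of pairs straddle the att junction and appear on the
# linear reference as outward-facing discordant pairs and soft-clipped split
# reads — exactly the evidence the detection module consumes. Reads are
# emitted pre-aligned (truth SAM) so detection is testable without an
# aligner; FASTQ is also written for end-to-end runs through a real mapper.

#' Build a simulation configuration
#'
#' The defaults describe a realistic overnight-culture virion library from
#' a lysogen: a 1 Mb chromosome at 55% GC carrying a 20 kb and a 40 kb
#' prophage (active prophage genomes span roughly 16-57 kbp) at titres of a
#' few 1e7 virions/mL, sequenced as 150 bp paired-end reads with ~500 bp
#' inserts and 2% residual host-DNA background.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param genome_len_bp Host chromosome length.
#' @param genome_gc Host GC fraction.
#' @param prophages Tibble with `length_bp`, `gc`, `titre`, `insertion_pos`
#'   (0-based position in the host backbone, pre-insertion coordinates).
#' @param background_read_fraction Fraction of read pairs from residual
#'   host DNA, in `[0, 1)`.
#' @param read_len_bp,insert_mean_bp,insert_sd_bp Read/fragment geometry.
#' @param total_read_pairs Total pairs simulated.
#' @param supernatant_volume_ml Volume the titres refer to (metadata only).
#' @param lateral_transduction Optional list
#'   `(prophage, side, extent_bp, headful_bp, edge_enrichment)` consumed by
#'   [apply_lateral_transduction()].
#' @return A `vip_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_len_bp = 1000000L,
                       genome_gc = 0.55,
                       prophages = tibble(
                         length_bp = c(20000L, 40000L),
                         gc = c(0.45, 0.40),
                         titre = c(2e7, 5e7),
                         insertion_pos = c(250000L, 600000L)),
                       background_read_fraction = 0.02,
                       read_len_bp = 150L,
                       insert_mean_bp = 500L,
                       insert_sd_bp = 60L,
                       total_read_pairs = 200000L,
                       supernatant_volume_ml = 30,
                       lateral_transduction = NULL) {
  stopifnot(is.data.frame(prophages) || nrow(prophages) == 0L)
  if (background_read_fraction < 0 || background_read_fraction >= 1) {
    abort("background_read_fraction must be in [0, 1)")
  }
  if (genome_gc < 0 || genome_gc > 1) abort("genome_gc must be in [0, 1]")
  if (nrow(prophages)) {
    if (any(prophages$length_bp <= 0) || any(prophages$titre < 0)) {
      abort("prophage lengths must be positive and titres non-negative")
    }
    if (any(prophages$gc < 0 | prophages$gc > 1)) {
      abort("prophage gc must be in [0, 1]")
    }
    pos <- prophages$insertion_pos
    if (any(pos <= 0 | pos >= genome_len_bp)) {
      abort("insertion_pos must lie strictly inside the host backbone")
    }
    if (anyDuplicated(pos)) abort("insertion positions overlap")
    if (any(prophages$length_bp < insert_mean_bp)) {
      abort("prophage shorter than the mean insert size")
    }
  }
  structure(
    list(seed = as.integer(seed), genome_len_bp = as.integer(genome_len_bp),
         genome_gc = genome_gc, prophages = as_tibble(prophages),
         background_read_fraction = background_read_fraction,
         read_len_bp = as.integer(read_len_bp),
         insert_mean_bp = insert_mean_bp, insert_sd_bp = insert_sd_bp,
         total_read_pairs = as.integer(total_read_pairs),
         supernatant_volume_ml = supernatant_volume_ml,
         lateral_transduction = lateral_transduction),
    class = "vip_sim_config")
}

.random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic lysogen genome with embedded prophages
#'
#' The host backbone is drawn at `genome_gc`; each prophage is drawn at its
#' own GC and inserted at its backbone position. Truth intervals are
#' recorded in final (post-insertion) coordinates.
#'
#' @param cfg A `vip_sim_config`.
#' @return A `vip_truth` list: `genome` (one-row genome tibble),
#'   `prophages` (truth intervals with `titre`, `gc`), `config`.
#' @export
make_lysogen <- function(cfg) {
  stopifnot(inherits(cfg, "vip_sim_config"))
  set.seed(cfg$seed)
  host <- .random_seq(cfg$genome_len_bp, cfg$genome_gc)
  pp <- cfg$prophages
  if (nrow(pp)) {
    pp <- dplyr::arrange(pp, .data$insertion_pos)
    pp$label <- sprintf("pp_sim%02d", seq_len(nrow(pp)))
    pp$sequence <- map_chr(seq_len(nrow(pp)),
                           function(i) .random_seq(pp$length_bp[i], pp$gc[i]))
    offsets <- c(0, cumsum(pp$length_bp))[seq_len(nrow(pp))]
    pp$start <- pp$insertion_pos + as.integer(offsets)
    pp$end <- pp$start + pp$length_bp
    pieces <- character(2L * nrow(pp) + 1L)
    prev <- 0L
    for (i in seq_len(nrow(pp))) {
      pieces[2L * i - 1L] <- substr(host, prev + 1L, pp$insertion_pos[i])
      pieces[2L * i] <- pp$sequence[i]
      prev <- pp$insertion_pos[i]
    }
    pieces[2L * nrow(pp) + 1L] <- substr(host, prev + 1L, cfg$genome_len_bp)
    genome_seq <- paste(pieces, collapse = "")
  } else {
    genome_seq <- host
    pp$label <- character(0)
    pp$sequence <- character(0)
    pp$start <- integer(0)
    pp$end <- integer(0)
  }
  genome <- tibble(genome_id = "sim_chr", sequence = genome_seq,
                   length = nchar(genome_seq))
  truth <- pp[, c("label", "start", "end", "length_bp", "gc", "titre",
                  "insertion_pos")]
  truth$genome_id <- genome$genome_id
  structure(list(genome = genome, prophages = truth, config = cfg),
            class = "vip_truth")
}

# map a read covering circular interval [s, s+len) of a prophage at host
# offset A, circle length L, onto the linear reference; returns pos,
# aligned_len, clips and whether it wraps the junction
.map_circular <- function(s, len, A, L) {
  s <- s %% L
  wraps <- s + len > L
  len1 <- ifelse(wraps, L - s, len)       # right-edge portion
  len2 <- ifelse(wraps, len - len1, 0L)   # left-edge portion
  primary_right <- !wraps | len1 >= len2
  tibble(
    pos = ifelse(primary_right, A + s, A),
    aligned_len = ifelse(wraps, ifelse(primary_right, len1, len2), len),
    clip_left = ifelse(wraps & primary_right, 0L,
                       ifelse(wraps, len1, 0L)),
    clip_right = ifelse(wraps & primary_right, len2, 0L),
    wrapped = wraps)
}

.circ_substr <- function(seqs, s, len, L) {
  # circular substring of a single string `seqs` (the prophage sequence)
  s <- s %% L
  wraps <- s + len > L
  out <- character(length(s))
  out[!wraps] <- substring(seqs, s[!wraps] + 1L, s[!wraps] + len[!wraps])
  if (any(wraps)) {
    out[wraps] <- paste0(substring(seqs, s[wraps] + 1L, L),
                         substring(seqs, 1L, len[wraps] - (L - s[wraps])))
  }
  out
}

.truncated_frags <- function(n, cfg, L) {
  frag <- as.integer(round(rnorm(n, cfg$insert_mean_bp, cfg$insert_sd_bp)))
  pmin(pmax(frag, cfg$read_len_bp), L)
}

#' Simulate the virion read pool for a synthetic lysogen
#'
#' Read pairs are apportioned multinomially: the background fraction comes
#' uniformly from the whole lysogen chromosome (residual undigested host
#' DNA), and the rest is split across prophages proportional to
#' `titre * length` (their DNA mass share). Prophage fragments start
#' uniformly on the circular excised genome; fragment lengths are
#' Normal(insert_mean, insert_sd) truncated below at the read length.
#' Reads are error-free: the method depends on mapping positions, not base
#' accuracy. The true eluted DNA mass per mL is derived from genome-copy
#' masses (prophage mass share inflated by the background fraction so read
#' fractions and mass fractions agree).
#'
#' @param truth A `vip_truth` from [make_lysogen()].
#' @return A `vip_sim` list: `truth`, `alignments` (truth alignment records
#'   in the [read_alignments()] schema plus `origin`, `read_of_pair`,
#'   `wrapped`), `metadata` (one-row tibble incl. `m_dna_ng_per_ml`),
#'   `expected` (per-origin expected read fractions), `counts`.
#' @export
simulate_virion_reads <- function(truth) {
  stopifnot(inherits(truth, "vip_truth"))
  cfg <- truth$config
  set.seed(cfg$seed + 1L)
  pp <- truth$prophages
  rl <- cfg$read_len_bp
  G <- truth$genome$length
  b <- cfg$background_read_fraction
  mass_w <- if (nrow(pp)) pp$titre * pp$length_bp else numeric(0)
  if (sum(mass_w) == 0 && b == 0) abort("no read source: all titres zero and no background")
  probs <- if (sum(mass_w) > 0) c((1 - b) * mass_w / sum(mass_w), b) else
    c(rep(0, nrow(pp)), 1)
  counts <- as.integer(rmultinom(1, cfg$total_read_pairs, probs))
  names(counts) <- c(pp$label, "background")

  gseq <- truth$genome$sequence
  recs <- list()
  for (i in seq_len(nrow(pp))) {
    n <- counts[i]
    if (n == 0L) next
    L <- pp$length_bp[i]
    A <- pp$start[i]
    pseq <- substr(gseq, A + 1L, A + L)
    frag <- .truncated_frags(n, cfg, L)
    s <- as.integer(floor(runif(n, 0, L)))
    r1s <- s
    r2s <- (s + frag - rl)
    m1 <- .map_circular(r1s, rep(rl, n), A, L)
    m2 <- .map_circular(r2s, rep(rl, n), A, L)
    junction_pair <- (s + frag) > L
    ids <- sprintf("%s_%06d", pp$label[i], seq_len(n))
    mk <- function(m, strand, mate, ro) {
      mstrand <- if (strand == "+") "-" else "+"
      tibble(read_id = ids, genome_id = truth$genome$genome_id,
             pos = as.integer(m$pos), strand = strand,
             mate_pos = as.integer(mate$pos),
             mate_strand = mstrand,
             mapq = 60L, aligned_len = as.integer(m$aligned_len),
             clip_left = as.integer(m$clip_left),
             clip_right = as.integer(m$clip_right),
             is_primary = TRUE,
             is_proper_pair = !junction_pair,
             seq = .circ_substr(pseq, if (ro == 1L) r1s else r2s,
                                rep(rl, n), L),
             origin = pp$label[i], read_of_pair = ro,
             wrapped = m$wrapped)
    }
    recs[[length(recs) + 1L]] <- mk(m1, "+", m2, 1L)
    recs[[length(recs) + 1L]] <- mk(m2, "-", m1, 2L)
  }
  nb <- counts[["background"]]
  if (nb > 0L) {
    frag <- .truncated_frags(nb, cfg, G)
    s <- as.integer(floor(runif(nb, 0, G - frag + 1)))
    ids <- sprintf("bg_%06d", seq_len(nb))
    p1 <- s
    p2 <- s + frag - rl
    bg <- function(pos, strand, mate_pos, ro) {
      mstrand <- if (strand == "+") "-" else "+"
      tibble(read_id = ids, genome_id = truth$genome$genome_id,
             pos = pos, strand = strand, mate_pos = mate_pos,
             mate_strand = mstrand,
             mapq = 60L, aligned_len = rl, clip_left = 0L, clip_right = 0L,
             is_primary = TRUE, is_proper_pair = TRUE,
             seq = substring(gseq, pos + 1L, pos + rl),
             origin = "background", read_of_pair = ro, wrapped = FALSE)
    }
    recs[[length(recs) + 1L]] <- bg(p1, "+", p2, 1L)
    recs[[length(recs) + 1L]] <- bg(p2, "-", p1, 2L)
  }
  aln <- list_rbind(recs)

  total_mass_g_per_ml <- if (sum(mass_w) > 0) {
    sum(pp$titre * pp$length_bp) * M_NT / AVOGADRO / (1 - b)
  } else 0
  expected <- tibble(
    origin = c(pp$label, "background"),
    expected_read_fraction = probs,
    true_titre = c(pp$titre, NA_real_))
  metadata <- tibble(
    sample_id = "sim_sample",
    m_dna_ng_per_ml = total_mass_g_per_ml * 1e9,
    supernatant_volume_ml = cfg$supernatant_volume_ml,
    total_read_pairs = cfg$total_read_pairs,
    background_read_fraction = b)
  structure(list(truth = truth, alignments = aln, metadata = metadata,
                 expected = expected, counts = counts, config = cfg),
            class = "vip_sim")
}

#' @export
print.vip_sim <- function(x, ...) {
  cat("<vip_sim> ", x$truth$genome$length, " bp lysogen, ",
      nrow(x$truth$prophages), " prophage(s), ",
      nrow(x$alignments), " simulated reads\n", sep = "")
  invisible(x)
}

#' Add a lateral-transduction coverage gradient to a simulated read pool
#'
#' Lateral transduction packages host DNA adjacent to an induced prophage in
#' successive capsid headfuls, so coverage steps down once per headful
#' moving away from the prophage. Extra host-derived pairs are added on the
#' configured flank with per-step expected depth decaying geometrically
#' from `edge_enrichment x background` at the prophage edge to background
#' after `extent_bp` (multiplicative loss per packaging step). An extent
#' reaching past the genome end is truncated with a warning.
#'
#' @param sim A `vip_sim`; its config must carry `lateral_transduction`
#'   with `side` (`"left"`/`"right"`), `extent_bp`, `headful_bp`,
#'   `edge_enrichment`, and optionally `prophage` (truth label; default the
#'   first).
#' @return The modified `vip_sim`; `sim$lateral` records the step truth
#'   (`step`, `start`, `end`, `enrichment`, `n_pairs`).
#' @export
apply_lateral_transduction <- function(sim) {
  stopifnot(inherits(sim, "vip_sim"))
  cfg <- sim$config
  lt <- cfg$lateral_transduction
  if (is.null(lt)) abort("config has no lateral_transduction section")
  set.seed(cfg$seed + 2L)
  pp <- sim$truth$prophages
  lab <- lt$prophage %||% pp$label[1]
  row <- pp[pp$label == lab, ]
  if (nrow(row) != 1L) abort(paste0("unknown prophage label: ", lab))
  G <- sim$truth$genome$length
  rl <- cfg$read_len_bp
  n_steps <- as.integer(ceiling(lt$extent_bp / lt$headful_bp))
  decay <- lt$edge_enrichment^(-1 / n_steps)
  bg_depth <- 2 * rl * cfg$background_read_fraction *
    cfg$total_read_pairs / G
  gseq <- sim$truth$genome$sequence
  recs <- list()
  steps <- list()
  for (k in seq_len(n_steps)) {
    if (lt$side == "right") {
      lo <- row$end + (k - 1L) * lt$headful_bp
      hi <- min(G, row$end + k * lt$headful_bp)
    } else if (lt$side == "left") {
      hi <- row$start - (k - 1L) * lt$headful_bp
      lo <- max(0L, row$start - k * lt$headful_bp)
    } else abort("lateral_transduction side must be 'left' or 'right'")
    if (hi <= lo) {
      warn("lateral-transduction extent truncated at genome end")
      break
    }
    if (hi - lo < lt$headful_bp && k < n_steps) {
      warn("lateral-transduction extent truncated at genome end")
    }
    enr <- lt$edge_enrichment * decay^(k - 1L)
    lambda <- (enr - 1) * bg_depth * (hi - lo) / (2 * rl)
    nk <- if (lambda > 0) rpois(1, lambda) else 0L
    steps[[k]] <- tibble(step = k, start = lo, end = hi, enrichment = enr,
                         n_pairs = nk)
    if (nk == 0L) next
    frag <- .truncated_frags(nk, cfg, hi - lo)
    s <- as.integer(floor(runif(nk, lo, hi - frag + 1)))
    ids <- sprintf("lt_s%02d_%06d", k, seq_len(nk))
    p1 <- s
    p2 <- s + frag - rl
    lt_rec <- function(pos, strand, mate_pos, ro) {
      mstrand <- if (strand == "+") "-" else "+"
      tibble(read_id = ids, genome_id = sim$truth$genome$genome_id,
             pos = pos, strand = strand, mate_pos = mate_pos,
             mate_strand = mstrand,
             mapq = 60L, aligned_len = rl, clip_left = 0L, clip_right = 0L,
             is_primary = TRUE, is_proper_pair = TRUE,
             seq = substring(gseq, pos + 1L, pos + rl),
             origin = "lateral", read_of_pair = ro, wrapped = FALSE)
    }
    recs[[length(recs) + 1L]] <- lt_rec(p1, "+", p2, 1L)
    recs[[length(recs) + 1L]] <- lt_rec(p2, "-", p1, 2L)
  }
  added <- if (length(recs)) list_rbind(recs) else NULL
  if (!is.null(added)) {
    old_n <- nrow(sim$alignments)
    sim$alignments <- bind_rows(sim$alignments, added)
    # extra encapsidated host DNA adds to the eluted mass
    sim$metadata$m_dna_ng_per_ml <- sim$metadata$m_dna_ng_per_ml *
      nrow(sim$alignments) / old_n
  }
  sim$lateral <- list_rbind(steps)
  sim
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a simulated read pool to disk
#'
#' Emits gzipped FASTQ (R1/R2, reads in sequencing orientation), the truth
#' SAM (reads pre-aligned with correct positions, orientations and clip
#' structure), the truth BED of prophage intervals, a sample-metadata TSV,
#' and the genome FASTA.
#'
#' @param sim A `vip_sim`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "vip_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln <- dplyr::arrange(sim$alignments, .data$read_id, .data$read_of_pair)
  paths <- list(
    fastq_r1 = file.path(dir, "reads_R1.fastq.gz"),
    fastq_r2 = file.path(dir, "reads_R2.fastq.gz"),
    sam = file.path(dir, "truth.sam"),
    bed = file.path(dir, "truth_prophages.bed"),
    metadata = file.path(dir, "sample_metadata.tsv"),
    fasta = file.path(dir, "genome.fasta"))
  for (ro in c(1L, 2L)) {
    r <- aln[aln$read_of_pair == ro, ]
    seqs <- ifelse(r$strand == "-", .revcomp(r$seq), r$seq)
    con <- gzfile(paths[[ro]], "w")
    writeLines(paste0("@", r$read_id, "/", ro, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
    close(con)
  }
  write_truth_sam(aln, sim$truth$genome, paths$sam)
  write_bed(sim$truth$prophages, paths$bed)
  readr::write_tsv(sim$metadata, paths$metadata, progress = FALSE)
  write_genome_fasta(sim$truth$genome, paths$fasta)
  invisible(paths)
}

#' Write truth alignment records as SAM
#'
#' @param alignments Simulator alignment tibble (needs `read_of_pair`,
#'   `seq`, clip columns).
#' @param genome One-row genome tibble for the header.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(alignments, genome, path) {
  a <- alignments
  flag <- 0x1L + 0x40L * (a$read_of_pair == 1L) + 0x80L * (a$read_of_pair == 2L) +
    0x2L * a$is_proper_pair + 0x10L * (a$strand == "-") +
    0x20L * (a$mate_strand == "-")
  cigar <- paste0(
    ifelse(a$clip_left > 0L, paste0(a$clip_left, "S"), ""),
    a$aligned_len, "M",
    ifelse(a$clip_right > 0L, paste0(a$clip_right, "S"), ""))
  lines <- paste(a$read_id, flag, a$genome_id, a$pos + 1L, a$mapq, cigar,
                 "=", a$mate_pos + 1L, 0L, a$seq, strrep("I", nchar(a$seq)),
                 sep = "\t")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", genome$genome_id, "\tLN:", genome$length))
  writeLines(c(header, lines), path)
  invisible(path)
}
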