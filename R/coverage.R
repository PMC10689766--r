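# Per-base virion-read coverage and coverage-island segmentation. Virion
# libraries have very little chromosomal background, so active prophages
# stand out as contiguous high-coverage islands over a low background that
# is re-estimated after masking the islands themselves.

#' Compute a per-base coverage profile from retained alignments
#'
#' Depth counts alignments (not fragments) per base, so overlapping mates of
#' one pair contribute twice; the simulator's oracles use the same
#' convention. The initial background is the genome-wide median depth and is
#' refined by [segment_islands()].
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @param genome One-row genome tibble (or a row of one) for the reference
#'   the alignments map to.
#' @return A `vip_coverage` object: list with `genome_id`, integer vector
#'   `depth` of genome length, and `background`.
#' @export
compute_coverage <- function(alignments, genome) {
  stopifnot(is.data.frame(genome), nrow(genome) == 1L)
  glen <- genome$length
  aln <- dplyr::filter(alignments, .data$genome_id == genome$genome_id)
  if (nrow(aln) == 0L) {
    warn(paste0("no retained alignments on ", genome$genome_id,
                "; empty coverage profile"))
    depth <- integer(glen)
  } else {
    ir <- IRanges::IRanges(start = aln$pos + 1L, width = aln$aligned_len)
    ir <- IRanges::restrict(ir, start = 1L, end = glen)
    depth <- as.integer(IRanges::coverage(ir, width = glen))
  }
  structure(
    list(genome_id = genome$genome_id, depth = depth,
         background = stats::median(depth)),
    class = "vip_coverage")
}

#' @export
print.vip_coverage <- function(x, ...) {
  cat("<vip_coverage> ", x$genome_id, ": ", length(x$depth), " bp, ",
      "mean depth ", signif(mean(x$depth), 3),
      ", background ", signif(x$background, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.vip_coverage <- function(x, ...) {
  r <- rle(x$depth)
  end <- cumsum(r$lengths)
  tibble(genome_id = x$genome_id,
         start = c(0L, head(end, -1L)),
         end = end,
         depth = r$values)
}

#' @export
glance.vip_coverage <- function(x, ...) {
  tibble(genome_id = x$genome_id, genome_len = length(x$depth),
         total_aligned_bases = sum(as.numeric(x$depth)),
         mean_depth = mean(x$depth), background = x$background)
}

.runs_at_least <- function(depth, thr, merge_gap_bp, min_len_bp) {
  ir <- IRanges::IRanges(S4Vectors::Rle(depth >= thr))
  if (length(ir) == 0L) return(ir)
  ir <- IRanges::reduce(ir, min.gapwidth = merge_gap_bp + 1L)
  ir <- ir[IRanges::width(ir) >= min_len_bp]
  if (length(ir) == 0L) return(ir)
  # merging can dilute a run of threshold-passing blips below the fold
  # threshold; islands must keep mean depth >= thr after merging
  cs <- cumsum(as.numeric(depth))
  means <- (cs[IRanges::end(ir)] -
              c(0, cs)[IRanges::start(ir)]) / IRanges::width(ir)
  ir[means >= thr]
}

#' Segment high-coverage islands (candidate active prophages)
#'
#' Maximal runs with depth at least `min_fold` times background, merged
#' across gaps of at most `merge_gap_bp`, kept if at least `min_len_bp`
#' long. The background (median depth outside islands) is then re-estimated
#' and segmentation repeated until the island set is stable, up to
#' `max_rounds` rounds. If the background is zero while coverage exists (a
#' pure virion library with no residual host DNA), every covered run of
#' sufficient length becomes a candidate and the profile is flagged.
#'
#' @param profile A `vip_coverage` object.
#' @param min_fold Island threshold as a multiple of background (default 5).
#' @param min_len_bp Minimum merged island length (default 5000; the
#'   smallest active prophages seen in practice are ~16 kbp).
#' @param merge_gap_bp Merge islands separated by at most this gap
#'   (default 2000).
#' @param max_rounds Cap on background re-estimation rounds (default 5).
#' @return Tibble of islands (`genome_id`, `start`, `end`, `label`,
#'   `mean_depth`) with attributes `background` (final estimate),
#'   `rounds`, `converged`, and `virion_only`.
#' @export
segment_islands <- function(profile, min_fold = 5, min_len_bp = 5000L,
                            merge_gap_bp = 2000L, max_rounds = 5L) {
  stopifnot(inherits(profile, "vip_coverage"))
  depth <- profile$depth
  glen <- length(depth)
  bg <- stats::median(depth)
  virion_only <- FALSE
  if (bg == 0 && any(depth > 0)) {
    # background-free library: any covered run is a candidate
    ir <- .runs_at_least(depth, 1L, merge_gap_bp, min_len_bp)
    virion_only <- TRUE
    warn("background coverage is zero; treating all covered runs as candidates")
    rounds <- 1L
    converged <- TRUE
  } else {
    ir <- IRanges::IRanges()
    converged <- FALSE
    rounds <- 0L
    while (rounds < max_rounds) {
      rounds <- rounds + 1L
      thr <- min_fold * bg
      new_ir <- .runs_at_least(depth, thr, merge_gap_bp, min_len_bp)
      outside <- rep(TRUE, glen)
      if (length(new_ir)) {
        cov <- as.logical(IRanges::coverage(new_ir, width = glen) > 0L)
        outside <- !cov
      }
      bg_new <- if (any(outside)) stats::median(depth[outside]) else 0
      same <- length(new_ir) == length(ir) &&
        all(IRanges::start(new_ir) == IRanges::start(ir)) &&
        all(IRanges::end(new_ir) == IRanges::end(ir))
      ir <- new_ir
      if (same && isTRUE(all.equal(bg_new, bg))) {
        converged <- TRUE
        bg <- bg_new
        break
      }
      if (bg_new == 0) {
        # residual background so sparse its median is zero outside islands;
        # a further round would threshold at zero, so keep this island set
        bg <- 0
        converged <- TRUE
        break
      }
      bg <- bg_new
    }
    if (!converged && rounds >= max_rounds) {
      warn("island segmentation did not converge; keeping last island set")
    }
  }
  out <- tibble(
    genome_id = profile$genome_id,
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir),
    label = if (length(ir)) sprintf("island_%02d", seq_along(ir)) else character(0))
  out$mean_depth <- map_dbl(seq_len(nrow(out)), function(i) {
    mean(depth[(out$start[i] + 1L):out$end[i]])
  })
  attr(out, "background") <- bg
  attr(out, "rounds") <- rounds
  attr(out, "converged") <- converged
  attr(out, "virion_only") <- virion_only
  out
}

#' GC fraction of a sequence over {A,C,G,T} only
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Numeric vector of GC fractions; `NaN` when no A/C/G/T present.
#' @export
gc_fraction <- function(sequence) {
  vapply(sequence, function(s) {
    counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
    acgt <- counts[c("A", "C", "G", "T")]
    if (sum(acgt) == 0) return(NaN)
    unname((acgt["G"] + acgt["C"]) / sum(acgt))
  }, numeric(1), USE.NAMES = FALSE)
}
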