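# Junction-spanning read evidence and exact boundary refinement.
#
# An induced prophage excises as a circle, so virion fragments that straddle
# the att junction produce, on the linear lysogen reference, (i) outward-
# facing discordant mate pairs anchored near attL and attR and (ii) reads
# split across the junction, soft-clipped at one boundary with the clipped
# bases matching the sequence just inside the other boundary.

#' Collect junction-spanning evidence for a candidate prophage region
#'
#' Mate pairs count as support when one mate lies within `search_window_bp`
#' of the candidate's left edge on the minus strand and the other within the
#' window of the right edge on the plus strand (outward-facing, the
#' signature of a circular excised template). Pairs near both edges in any
#' other orientation are recorded with `orientation_ok = FALSE` and excluded
#' from the support count. Alignments soft-clipped by at least `min_clip`
#' bases at one edge count as split support; when `genome` is supplied the
#' clipped bases must anchor (exact match) near the other edge, which also
#' pins the partner boundary coordinate.
#'
#' @param alignments Alignment tibble ([read_alignments()]).
#' @param candidate One-row interval tibble (a row of [segment_islands()]).
#' @param search_window_bp Window around each candidate edge (default 2000).
#' @param max_insert_bp Maximum implied circular insert retained as support
#'   (default 1500).
#' @param min_clip Minimum soft-clip length for split evidence (default 20).
#' @param genome Optional one-row genome tibble with `sequence`, used to
#'   anchor clipped bases at the opposite edge.
#' @return A `vip_junctions` object with tibbles `pair_support`
#'   (`left_anchor_pos`, `left_end`, `right_start`, `right_anchor_pos`,
#'   `orientation_ok`) and `split_support` (`side`, `clip_pos`,
#'   `partner_pos`), and the integer `support_count`.
#' @export
collect_junction_evidence <- function(alignments, candidate,
                                      search_window_bp = 2000L,
                                      max_insert_bp = 1500L,
                                      min_clip = 20L,
                                      genome = NULL) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1L)
  w <- search_window_bp
  cs <- candidate$start
  ce <- candidate$end
  aln <- dplyr::filter(alignments, .data$genome_id == candidate$genome_id)
  aln$end_pos <- aln$pos + aln$aligned_len
  aln$near_left <- abs(aln$pos - cs) <= w
  aln$near_right <- abs(aln$end_pos - ce) <= w

  # mate pairs with one read at each edge
  cand <- dplyr::filter(aln, .data$near_left | .data$near_right)
  pair_support <- tibble(left_anchor_pos = integer(0), left_end = integer(0),
                         right_start = integer(0), right_anchor_pos = integer(0),
                         orientation_ok = logical(0))
  if (nrow(cand) > 1L) {
    dup <- cand$read_id[duplicated(cand$read_id)]
    if (length(dup)) {
      prs <- dplyr::filter(cand, .data$read_id %in% dup) |>
        dplyr::arrange(.data$read_id, .data$pos)
      prs <- dplyr::group_by(prs, .data$read_id) |>
        dplyr::filter(dplyr::n() == 2L) |>
        dplyr::summarise(
          left_anchor_pos = .data$pos[1],
          left_end = .data$end_pos[1],
          left_strand = .data$strand[1],
          left_near = .data$near_left[1],
          right_start = .data$pos[2],
          right_anchor_pos = .data$end_pos[2],
          right_strand = .data$strand[2],
          right_near = .data$near_right[2],
          .groups = "drop") |>
        dplyr::filter(.data$left_near, .data$right_near,
                      .data$left_anchor_pos != .data$right_start)
      if (nrow(prs)) {
        pair_support <- tibble(
          left_anchor_pos = prs$left_anchor_pos,
          left_end = prs$left_end,
          right_start = prs$right_start,
          right_anchor_pos = prs$right_anchor_pos,
          orientation_ok = prs$left_strand == "-" & prs$right_strand == "+")
      }
    }
  }

  # split (soft-clipped) reads at an edge, anchored at the other edge
  split_support <- tibble(side = character(0), clip_pos = integer(0),
                          partner_pos = integer(0))
  right_clips <- dplyr::filter(aln, .data$clip_right >= min_clip,
                               abs(.data$end_pos - ce) <= w)
  left_clips <- dplyr::filter(aln, .data$clip_left >= min_clip,
                              abs(.data$pos - cs) <= w)
  anchor <- function(clipped_seq, region_start, region_end) {
    # exact-match the clipped bases within a window at the opposite edge;
    # returns 0-based match start or NA
    if (is.null(genome) || is.na(clipped_seq) || nchar(clipped_seq) == 0L) {
      return(NA_integer_)
    }
    glen <- nchar(genome$sequence)
    region_start <- max(0L, region_start)
    region_end <- min(glen, region_end)
    if (region_end - region_start < nchar(clipped_seq)) return(NA_integer_)
    region <- substr(genome$sequence, region_start + 1L, region_end)
    hit <- regexpr(clipped_seq, region, fixed = TRUE)
    if (hit == -1L) return(NA_integer_)
    region_start + as.integer(hit) - 1L
  }
  if (nrow(right_clips)) {
    rows <- pmap(list(right_clips$seq %||% rep(NA_character_, nrow(right_clips)),
                      right_clips$clip_right, right_clips$end_pos),
                 function(s, clip, cpos) {
      clipped <- if (is.na(s)) NA_character_ else
        substr(s, nchar(s) - clip + 1L, nchar(s))
      p <- anchor(clipped, cs - w, cs + w + if (is.na(clipped)) 0L else nchar(clipped))
      if (!is.null(genome) && is.na(p)) return(NULL)  # failed anchoring
      tibble(side = "right", clip_pos = cpos, partner_pos = p)
    })
    split_support <- bind_rows(split_support, list_rbind(purrr::compact(rows)))
  }
  if (nrow(left_clips)) {
    rows <- pmap(list(left_clips$seq %||% rep(NA_character_, nrow(left_clips)),
                      left_clips$clip_left, left_clips$pos),
                 function(s, clip, cpos) {
      clipped <- if (is.na(s)) NA_character_ else substr(s, 1L, clip)
      p <- anchor(clipped, ce - w - clip, ce + w)
      if (!is.null(genome) && is.na(p)) return(NULL)
      # partner coordinate is the attR implied by the match end (exclusive)
      tibble(side = "left", clip_pos = cpos,
             partner_pos = if (is.na(p)) NA_integer_ else p + clip)
    })
    split_support <- bind_rows(split_support, list_rbind(purrr::compact(rows)))
  }

  structure(
    list(candidate = candidate,
         pair_support = pair_support,
         split_support = split_support,
         support_count = sum(pair_support$orientation_ok) + nrow(split_support),
         search_window_bp = search_window_bp,
         max_insert_bp = max_insert_bp),
    class = "vip_junctions")
}

#' @export
print.vip_junctions <- function(x, ...) {
  cat("<vip_junctions> candidate ", x$candidate$label, " [",
      x$candidate$start, ",", x$candidate$end, "): ",
      sum(x$pair_support$orientation_ok), " oriented pairs, ",
      nrow(x$split_support), " splits (support ", x$support_count, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.vip_junctions <- function(x, ...) {
  bind_rows(
    mutate(x$pair_support, kind = "pair"),
    mutate(x$split_support, kind = "split"))
}

# score one (attL, attR) hypothesis against the evidence
.boundary_score <- function(aL, aR, pairs, splits, max_insert_bp) {
  np <- 0L
  if (nrow(pairs)) {
    ok <- pairs$orientation_ok &
      aL <= pairs$left_anchor_pos &
      aR >= pairs$right_anchor_pos &
      (aR - pairs$right_start) + (pairs$left_end - aL) <= max_insert_bp
    np <- sum(ok)
  }
  ns <- 0L
  if (nrow(splits)) {
    ok <- ifelse(splits$side == "right",
                 splits$clip_pos == aR &
                   (is.na(splits$partner_pos) | splits$partner_pos == aL),
                 splits$clip_pos == aL &
                   (is.na(splits$partner_pos) | splits$partner_pos == aR))
    ns <- sum(ok)
  }
  c(pairs = np, splits = ns)
}

#' Refine prophage boundaries from junction evidence
#'
#' Chooses the (attL, attR) pair maximising the number of supporting
#' oriented mate pairs and anchored split reads whose implied circular
#' insert size is at most `max_insert_bp`. Ties are broken by (1) more
#' split-read support, (2) shorter interval, (3) leftmost start. With fewer
#' than `min_support` total junction observations the call falls back to the
#' coverage-island edges and is tiered `coverage_only`. Candidate boundary
#' coordinates are taken from the evidence itself (anchor positions and clip
#' points) plus the island edges, restricted to the search windows; on small
#' instances this search provably agrees with exhaustive enumeration of
#' every base-pair position pair because the score only changes at
#' evidence-derived coordinates.
#'
#' @param candidate One-row island interval tibble.
#' @param evidence `vip_junctions` for that candidate.
#' @param min_support Minimum junction observations for a `junction`-tier
#'   call (default 2, guarding against chimeric artefacts).
#' @return One-row call tibble: `genome_id`, `start`, `end`, `label`,
#'   `length_bp`, `support_count`, `confidence`.
#' @export
refine_boundaries <- function(candidate, evidence, min_support = 2L) {
  stopifnot(inherits(evidence, "vip_junctions"))
  w <- evidence$search_window_bp
  cs <- candidate$start
  ce <- candidate$end
  pairs <- evidence$pair_support
  splits <- evidence$split_support
  if (evidence$support_count < min_support) {
    return(tibble(genome_id = candidate$genome_id, start = cs, end = ce,
                  label = candidate$label, length_bp = ce - cs,
                  support_count = evidence$support_count,
                  confidence = "coverage_only"))
  }
  op <- pairs[pairs$orientation_ok, , drop = FALSE]
  aL_cand <- c(cs, op$left_anchor_pos,
               splits$clip_pos[splits$side == "left"],
               splits$partner_pos[splits$side == "right"])
  aR_cand <- c(ce, op$right_anchor_pos,
               splits$clip_pos[splits$side == "right"],
               splits$partner_pos[splits$side == "left"])
  aL_cand <- sort(unique(aL_cand[!is.na(aL_cand) & abs(aL_cand - cs) <= w]))
  aR_cand <- sort(unique(aR_cand[!is.na(aR_cand) & abs(aR_cand - ce) <= w]))
  grid <- tidyr::expand_grid(aL = aL_cand, aR = aR_cand) |>
    dplyr::filter(.data$aR > .data$aL)
  sc <- vapply(seq_len(nrow(grid)), function(i) {
    .boundary_score(grid$aL[i], grid$aR[i], pairs, splits,
                    evidence$max_insert_bp)
  }, numeric(2))
  grid$score <- sc["pairs", ] + sc["splits", ]
  grid$n_split <- sc["splits", ]
  grid <- dplyr::arrange(grid, dplyr::desc(.data$score),
                         dplyr::desc(.data$n_split),
                         .data$aR - .data$aL, .data$aL)
  best <- grid[1, ]
  tibble(genome_id = candidate$genome_id,
         start = as.integer(best$aL), end = as.integer(best$aR),
         label = candidate$label, length_bp = as.integer(best$aR - best$aL),
         support_count = evidence$support_count,
         confidence = "junction")
}

#' Flanking coverage enrichment (lateral-transduction signal)
#'
#' Reports mean depth, enrichment over background, and the slope of a
#' least-squares fit of `log(depth + 1)` against distance from the prophage
#' edge over a window on each side of a call. Lateral transduction packages
#' host DNA adjacent to the prophage in successive capsid headfuls, which
#' appears as strong enrichment decaying with distance (negative slope) on
#' one side only.
#'
#' @param profile `vip_coverage` (background must be the post-segmentation
#'   estimate for meaningful enrichment).
#' @param call One-row call tibble.
#' @param window_bp Flank window size; must be >= 1.
#' @return Tibble with one row per side: `side`, `window_bp` (possibly
#'   truncated at a genome end, then flagged), `flank_mean_depth`,
#'   `enrichment`, `decay_slope`, `truncated`.
#' @export
flanking_enrichment <- function(profile, call, window_bp = 200000L) {
  stopifnot(inherits(profile, "vip_coverage"))
  if (length(window_bp) != 1L || is.na(window_bp) || window_bp < 1L) {
    abort("window_bp must be a positive integer")
  }
  glen <- length(profile$depth)
  bg <- profile$background
  one_side <- function(side) {
    if (side == "left") {
      lo <- max(0L, call$start - window_bp)
      hi <- call$start
      pos <- seq.int(lo, hi - 1L)
      dist <- call$start - pos  # 1 at the edge, increasing outward
    } else {
      lo <- call$end
      hi <- min(glen, call$end + window_bp)
      pos <- seq.int(lo, hi - 1L)
      dist <- pos - call$end + 1L
    }
    truncated <- (hi - lo) < window_bp
    if (truncated) {
      warn(paste0(side, " flank window truncated at genome end (",
                  hi - lo, " bp)"))
    }
    d <- profile$depth[pos + 1L]
    slope <- if (length(d) >= 2L) {
      unname(coef(lm(log(d + 1) ~ dist))[2])
    } else NA_real_
    tibble(side = side, window_bp = hi - lo,
           flank_mean_depth = mean(d),
           enrichment = if (bg > 0) mean(d) / bg else NA_real_,
           decay_slope = slope, truncated = truncated)
  }
  bind_rows(one_side("left"), one_side("right"))
}
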