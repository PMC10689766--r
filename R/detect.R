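# End-to-end detection: coverage -> islands -> junction evidence -> calls.

#' Detect active prophages on one genome
#'
#' Runs the full detection chain: per-base coverage, island segmentation
#' with iterative background re-estimation, junction-evidence collection per
#' island, and boundary refinement. Calls with at least `min_support`
#' junction observations get exact boundaries (`junction` tier); the rest
#' keep their coverage-island edges (`coverage_only` tier).
#'
#' @param alignments Alignment tibble ([read_alignments()]).
#' @param genome One-row genome tibble ([read_genome_fasta()]); when it
#'   carries a `sequence`, split reads are anchored against it and the
#'   per-call GC content relative to the host is reported.
#' @param min_fold,min_len_bp,merge_gap_bp Island segmentation parameters,
#'   see [segment_islands()].
#' @param search_window_bp,max_insert_bp,min_clip Junction parameters, see
#'   [collect_junction_evidence()].
#' @param min_support Junction-tier threshold, see [refine_boundaries()].
#' @return A `vip_detection` object: list with `calls` (tibble adding
#'   `mean_depth` and `gc_relative` to the [refine_boundaries()] columns),
#'   `islands`, `profile` (background updated to the final estimate),
#'   `evidence` (list of `vip_junctions`), and `params`.
#' @export
detect_prophages <- function(alignments, genome,
                             min_fold = 5, min_len_bp = 5000L,
                             merge_gap_bp = 2000L,
                             search_window_bp = 2000L,
                             max_insert_bp = 1500L,
                             min_clip = 20L,
                             min_support = 2L) {
  profile <- compute_coverage(alignments, genome)
  islands <- segment_islands(profile, min_fold = min_fold,
                             min_len_bp = min_len_bp,
                             merge_gap_bp = merge_gap_bp)
  profile$background <- attr(islands, "background")
  gseq <- if ("sequence" %in% names(genome)) genome else NULL
  host_gc <- if (!is.null(gseq)) gc_fraction(genome$sequence) else NA_real_
  evidence <- list()
  calls <- list()
  for (i in seq_len(nrow(islands))) {
    cand <- islands[i, ]
    ev <- collect_junction_evidence(alignments, cand,
                                    search_window_bp = search_window_bp,
                                    max_insert_bp = max_insert_bp,
                                    min_clip = min_clip, genome = gseq)
    call <- refine_boundaries(cand, ev, min_support = min_support)
    call$mean_depth <- mean(profile$depth[(call$start + 1L):call$end])
    call$gc_relative <- if (!is.null(gseq)) {
      gc_fraction(substr(genome$sequence, call$start + 1L, call$end)) - host_gc
    } else NA_real_
    evidence[[cand$label]] <- ev
    calls[[i]] <- call
  }
  calls <- if (length(calls)) list_rbind(calls) else
    tibble(genome_id = character(0), start = integer(0), end = integer(0),
           label = character(0), length_bp = integer(0),
           support_count = integer(0), confidence = character(0),
           mean_depth = numeric(0), gc_relative = numeric(0))
  if (nrow(calls)) {
    calls$label <- sprintf("%s_pp%02d", genome$genome_id, seq_len(nrow(calls)))
  }
  structure(
    list(calls = calls, islands = islands, profile = profile,
         evidence = evidence,
         params = list(min_fold = min_fold, min_len_bp = min_len_bp,
                       merge_gap_bp = merge_gap_bp,
                       search_window_bp = search_window_bp,
                       max_insert_bp = max_insert_bp, min_clip = min_clip,
                       min_support = min_support)),
    class = "vip_detection")
}

#' @export
print.vip_detection <- function(x, ...) {
  cat("<vip_detection> ", x$profile$genome_id, ": ", nrow(x$calls),
      " call(s), background depth ", signif(x$profile$background, 3),
      "\n", sep = "")
  if (nrow(x$calls)) print(as_report_coords(x$calls))
  invisible(x)
}

#' @export
tidy.vip_detection <- function(x, ...) x$calls

#' @export
glance.vip_detection <- function(x, ...) {
  tibble(genome_id = x$profile$genome_id,
         n_calls = nrow(x$calls),
         n_junction_tier = sum(x$calls$confidence == "junction"),
         background = x$profile$background,
         total_aligned_bases = sum(as.numeric(x$profile$depth)))
}

#' Write detection results to disk
#'
#' Emits a 0-based BED of calls and a 1-based inclusive TSV report.
#'
#' @param detection A `vip_detection` object.
#' @param bed_path,report_path Output paths (`NULL` to skip either).
#' @return The calls tibble, invisibly.
#' @export
write_detection <- function(detection, bed_path = NULL, report_path = NULL) {
  stopifnot(inherits(detection, "vip_detection"))
  if (!is.null(bed_path)) write_bed(detection$calls, bed_path)
  if (!is.null(report_path)) {
    readr::write_tsv(as_report_coords(detection$calls), report_path,
                     progress = FALSE)
  }
  invisible(detection$calls)
}
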