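# Benchmarking in silico prophage predictions against experimentally
# verified active prophages: per-pair nucleotide precision/recall, the
# strict >0.75 base-recall match rule, active-prophage recall, and the
# structural-gene x IS-element category rates.

.interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}

.check_same_genome <- function(pred, active) {
  if (!all(pred$genome_id == active$genome_id)) {
    abort("prediction and active prophage must lie on the same genome")
  }
}

#' Nucleotide precision of a prediction against an active prophage
#'
#' Overlap bases divided by prediction length.
#'
#' @param pred,active Interval tibbles (`genome_id`, `start`, `end`), both
#'   one row or equal length; recycled row-wise.
#' @return Numeric vector in `[0, 1]`.
#' @export
nucleotide_precision <- function(pred, active) {
  .check_same_genome(pred, active)
  .interval_overlap(pred$start, pred$end, active$start, active$end) /
    (pred$end - pred$start)
}

#' Nucleotide recall of a prediction against an active prophage
#'
#' Overlap bases divided by active-prophage length.
#'
#' @inheritParams nucleotide_precision
#' @return Numeric vector in `[0, 1]`.
#' @export
nucleotide_recall <- function(pred, active) {
  .check_same_genome(pred, active)
  .interval_overlap(pred$start, pred$end, active$start, active$end) /
    (active$end - active$start)
}

#' Match predictions to active prophages by the base-recall rule
#'
#' An active prophage counts as predicted when any single prediction covers
#' strictly more than `recall_threshold` of its bases; recall is never
#' summed across several predictions. Each active prophage reports its
#' best-recall prediction.
#'
#' @param preds,actives Interval tibbles with `label` columns.
#' @param recall_threshold Strict lower bound on base recall (default 0.75).
#' @return A `vip_match` object: list with `per_active` (tibble `active`,
#'   `best_pred`, `best_recall`, `precision_of_best`, `matched`) and
#'   `pairs` (all same-genome prediction/active pairs with their metrics),
#'   plus the threshold.
#' @export
match_predictions <- function(preds, actives, recall_threshold = 0.75) {
  stopifnot(is.data.frame(preds), is.data.frame(actives))
  pairs <- inner_join(
    dplyr::rename(preds, pred = "label", pred_start = "start",
                  pred_end = "end"),
    dplyr::rename(actives, active = "label", active_start = "start",
                  active_end = "end"),
    by = "genome_id", relationship = "many-to-many")
  if (nrow(pairs)) {
    ov <- .interval_overlap(pairs$pred_start, pairs$pred_end,
                            pairs$active_start, pairs$active_end)
    pairs$nucleotide_precision <- ov / (pairs$pred_end - pairs$pred_start)
    pairs$nucleotide_recall <- ov / (pairs$active_end - pairs$active_start)
  } else {
    pairs$nucleotide_precision <- numeric(0)
    pairs$nucleotide_recall <- numeric(0)
  }
  per_active <- map(seq_len(nrow(actives)), function(i) {
    p <- pairs[pairs$active == actives$label[i], , drop = FALSE]
    if (nrow(p) == 0L) {
      return(tibble(active = actives$label[i], best_pred = NA_character_,
                    best_recall = 0, precision_of_best = NA_real_,
                    matched = FALSE))
    }
    j <- which.max(p$nucleotide_recall)
    tibble(active = actives$label[i], best_pred = p$pred[j],
           best_recall = p$nucleotide_recall[j],
           precision_of_best = p$nucleotide_precision[j],
           matched = p$nucleotide_recall[j] > recall_threshold)
  }) |> list_rbind()
  structure(list(per_active = per_active,
                 pairs = as_tibble(pairs),
                 recall_threshold = recall_threshold),
            class = "vip_match")
}

#' @export
print.vip_match <- function(x, ...) {
  cat("<vip_match> ", sum(x$per_active$matched), "/", nrow(x$per_active),
      " active prophages matched at base recall > ", x$recall_threshold,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.vip_match <- function(x, ...) x$per_active

#' @export
glance.vip_match <- function(x, ...) {
  tibble(n_active = nrow(x$per_active),
         n_matched = sum(x$per_active$matched),
         active_prophage_recall = active_prophage_recall(x),
         recall_threshold = x$recall_threshold)
}

#' Active-prophage recall
#'
#' Fraction of experimentally active prophages that were predicted.
#'
#' @param matching A `vip_match` object, or a logical vector of per-active
#'   matched flags.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' active_prophage_recall(rep(c(TRUE, FALSE), c(117, 3)))  # 0.975
active_prophage_recall <- function(matching) {
  flags <- if (inherits(matching, "vip_match")) matching$per_active$matched
           else as.logical(matching)
  if (length(flags) == 0L) abort("no active prophages; recall undefined")
  mean(flags)
}

#' Activity rates by structural-gene and IS-element annotation
#'
#' Cross-tabulates predictions by presence of phage structural genes and of
#' IS elements, reporting per cell the prediction count, how many were
#' experimentally active, and the active fraction (missing, not 0, for
#' empty cells). Predictions with unknown flags are excluded from the four
#' cells and counted separately.
#'
#' @param predictions Tibble with logical (or NA) columns `has_structural`,
#'   `has_is`, and logical `active`.
#' @return Tibble: `has_structural`, `has_is`, `n`, `n_active`,
#'   `active_fraction`, plus an `n_unknown` attribute.
#' @export
category_rates <- function(predictions) {
  stopifnot(all(c("has_structural", "has_is", "active") %in% names(predictions)))
  known <- !is.na(predictions$has_structural) & !is.na(predictions$has_is)
  cells <- tidyr::expand_grid(has_structural = c(TRUE, FALSE),
                              has_is = c(TRUE, FALSE))
  res <- pmap(cells, function(has_structural, has_is) {
    sel <- known & predictions$has_structural == has_structural &
      predictions$has_is == has_is
    n <- sum(sel)
    n_active <- sum(predictions$active[sel])
    tibble(has_structural = has_structural, has_is = has_is,
           n = n, n_active = n_active,
           active_fraction = if (n > 0) n_active / n else NA_real_)
  }) |> list_rbind()
  attr(res, "n_unknown") <- sum(!known)
  res
}

#' Percent rate at reporting precision
#'
#' Rates in human-readable reports are printed as percentages at a small
#' number of significant figures; full precision is kept in TSV output.
#'
#' @param numer,denom Counts.
#' @param sig Significant figures (default 2).
#' @return `signif(100 * numer / denom, sig)`.
#' @export
#' @examples
#' percent_rate(1, 223)    # 0.45
#' percent_rate(448, 2025) # 22
percent_rate <- function(numer, denom, sig = 2) {
  if (any(denom == 0)) abort("denominator is zero")
  signif(100 * numer / denom, sig)
}
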