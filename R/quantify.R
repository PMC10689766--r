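# Absolute titre quantification. The core conversion: the eluted DNA mass
# per mL of culture, split across prophages by their read fractions, counted
# in genome-copy units of length L_prophage:
#
#   virions/mL = (m_DNA * N_A) / (M_nt * L_prophage) * (r_pp / r_tot)
#
# with m_DNA in grams per mL, N_A Avogadro's constant and M_nt = 617.96
# g/mol/bp the average molar mass of a DNA base pair.

#' Count reads per prophage call
#'
#' A retained alignment is assigned to a call when its leftmost position
#' lies within the call interval; `r_tot` is all retained mapped reads.
#' Leftmost-position binning keeps per-call counts exactly multinomial.
#' Calls must be disjoint.
#'
#' @param alignments Alignment tibble.
#' @param calls Call tibble (disjoint intervals with `label`).
#' @return List with `counts` (tibble `label`, `r_pp`), `r_tot`, and
#'   `residual` (reads assigned to no call).
#' @export
count_prophage_reads <- function(alignments, calls) {
  if (nrow(calls) > 1L) {
    o <- order(calls$genome_id, calls$start)
    cs <- calls[o, ]
    same <- cs$genome_id[-nrow(cs)] == cs$genome_id[-1]
    if (any(same & cs$end[-nrow(cs)] > cs$start[-1])) {
      abort("overlapping calls; resolve upstream before counting")
    }
  }
  r_tot <- nrow(alignments)
  r_pp <- map_int(seq_len(nrow(calls)), function(i) {
    sum(alignments$genome_id == calls$genome_id[i] &
          alignments$pos >= calls$start[i] &
          alignments$pos < calls$end[i])
  })
  list(counts = tibble(label = calls$label, r_pp = r_pp),
       r_tot = r_tot,
       residual = r_tot - sum(r_pp))
}

#' Absolute virion titre from DNA mass and read fraction
#'
#' @param m_dna_ng_per_ml Total eluted DNA mass in ng, adjusted per 1 mL of
#'   original overnight culture.
#' @param r_pp Reads mapped to the prophage region.
#' @param r_tot Total mapped reads (> 0).
#' @param l_prophage_bp Induced prophage genome length in bp.
#' @return Titre in virions (genome copies) per mL. Vectorised over all
#'   arguments.
#' @export
#' @examples
#' vip_titre(0.016, 100, 100, 41000)  # ~3.8e5 virions/mL
vip_titre <- function(m_dna_ng_per_ml, r_pp, r_tot, l_prophage_bp) {
  if (any(r_tot == 0)) abort("r_tot must be > 0")
  if (any(r_pp < 0 | r_pp > r_tot)) abort("need 0 <= r_pp <= r_tot")
  if (any(l_prophage_bp <= 0)) abort("l_prophage_bp must be positive")
  if (any(m_dna_ng_per_ml < 0)) abort("m_dna_ng_per_ml must be >= 0")
  (m_dna_ng_per_ml * 1e-9 * AVOGADRO) / (M_NT * l_prophage_bp) * (r_pp / r_tot)
}

#' Per-prophage titre table for one sample
#'
#' Combines read counting and the titre formula into the per-sample report.
#'
#' @inheritParams count_prophage_reads
#' @inheritParams vip_titre
#' @return Tibble: `label`, `length_bp`, `r_pp`, `r_tot`, `read_fraction`,
#'   `titre`, plus `confidence` when present in `calls`.
#' @export
quantify_prophages <- function(alignments, calls, m_dna_ng_per_ml) {
  cnt <- count_prophage_reads(alignments, calls)
  out <- tibble(
    label = calls$label,
    length_bp = calls$end - calls$start,
    r_pp = cnt$counts$r_pp,
    r_tot = cnt$r_tot,
    read_fraction = cnt$counts$r_pp / cnt$r_tot,
    titre = vip_titre(m_dna_ng_per_ml, cnt$counts$r_pp, cnt$r_tot,
                      calls$end - calls$start))
  if ("confidence" %in% names(calls)) out$confidence <- calls$confidence
  out
}

#' Detection limit of virion-DNA quantification
#'
#' The smallest titre measurable given the fluorometric mass detection
#' limit and the wet-lab volumes: the minimum detectable total eluted mass
#' is `qubit_limit_ng * elution_volume_ul / assay_volume_ul` (the assay
#' aliquot measures concentration, it does not consume the sample), scaled
#' per mL of supernatant, converted to genome copies of the mean prophage
#' length at read fraction 1, and divided by `1 - concentration_loss_fraction`
#' to express the limit in the unconcentrated supernatant.
#'
#' @param qubit_limit_ng Minimum detectable DNA mass in the assayed aliquot
#'   (default 0.1 ng).
#' @param elution_volume_ul Total elution volume (default 24 uL).
#' @param assay_volume_ul Aliquot used for the mass assay (default 5 uL).
#' @param supernatant_volume_ml Supernatant volume concentrated (default 30 mL).
#' @param mean_prophage_len_bp Mean induced prophage genome length
#'   (default 41000 bp).
#' @param concentration_loss_fraction Fraction of virions lost during
#'   concentration (default 0.47).
#' @return Detection limit in virions/mL of original supernatant.
#' @export
#' @examples
#' detection_limit()  # ~7.2e5 virions/mL with the default assay parameters
detection_limit <- function(qubit_limit_ng = 0.1,
                            elution_volume_ul = 24,
                            assay_volume_ul = 5,
                            supernatant_volume_ml = 30,
                            mean_prophage_len_bp = 41000,
                            concentration_loss_fraction = 0.47) {
  if (concentration_loss_fraction < 0 || concentration_loss_fraction >= 1) {
    abort("concentration_loss_fraction must be in [0, 1)")
  }
  if (assay_volume_ul > elution_volume_ul) {
    abort("assay volume cannot exceed elution volume")
  }
  if (any(c(elution_volume_ul, assay_volume_ul, supernatant_volume_ml,
            mean_prophage_len_bp) <= 0) || qubit_limit_ng < 0) {
    abort("volumes, lengths and mass limit must be positive")
  }
  min_mass_ng <- qubit_limit_ng * elution_volume_ul / assay_volume_ul
  m_dna_ng_per_ml <- min_mass_ng / supernatant_volume_ml
  vip_titre(m_dna_ng_per_ml, 1, 1, mean_prophage_len_bp) /
    (1 - concentration_loss_fraction)
}

#' Induction rate from titre, cell density and burst size
#'
#' The fraction of cells whose prophage induced, approximated as
#' `titre / (cfu_per_ml * burst_size)`.
#'
#' @param titre Virions/mL.
#' @param cfu_per_ml Viable cells per mL (> 0).
#' @param burst_size Virions released per induced cell (> 0; ~150 for
#'   lambda-like phages).
#' @return Dimensionless induction rate.
#' @export
induction_rate <- function(titre, cfu_per_ml, burst_size = 150) {
  if (any(cfu_per_ml <= 0) || any(burst_size <= 0)) {
    abort("cfu_per_ml and burst_size must be > 0")
  }
  if (any(titre < 0)) abort("titre must be >= 0")
  titre / (cfu_per_ml * burst_size)
}

#' Aggregate per-prophage titres for a strain
#'
#' @param titres Tibble with a `titre` column (one strain's prophages), or a
#'   numeric vector of titres.
#' @param cfu_per_ml Optional CFU/mL; when missing the virion/CFU ratio is
#'   reported as `NA`.
#' @return One-row tibble: `aggregate_titre`, `virions_per_cfu`.
#' @export
aggregate_strain <- function(titres, cfu_per_ml = NA_real_) {
  tv <- if (is.data.frame(titres)) titres$titre else titres
  agg <- sum(tv)
  tibble(aggregate_titre = agg,
         virions_per_cfu = if (is.na(cfu_per_ml)) NA_real_ else agg / cfu_per_ml)
}
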