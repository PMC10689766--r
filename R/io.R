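# Readers/writers for the standard formats the pipeline touches, plus the
# shared coordinate conventions. All coordinates held in memory are 0-based
# half-open; SAM/report writers convert at the boundary.

#' Read a genome FASTA into a tibble of genome records
#'
#' Each record becomes one row with the first whitespace-delimited token of
#' the header as `genome_id`. Sequences are uppercased and `U` is mapped to
#' `T`, so RNA-alphabet input is tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `genome_id`, `sequence`, `length`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "ACGT"), f)
#' read_genome_fasta(f)
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)  # raw read; U/lowercase tolerated
  if (length(set) == 0L) abort(paste0("FASTA file has no records: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  tibble(genome_id = ids, sequence = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write genome records to FASTA
#'
#' @param genomes Tibble with `genome_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  stopifnot(is.data.frame(genomes), all(c("genome_id", "sequence") %in% names(genomes)))
  set <- Biostrings::DNAStringSet(genomes$sequence)
  names(set) <- genomes$genome_id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# flag-bit helpers (SAM spec)
.flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read primary alignments from a SAM or BAM file
#'
#' Returns one row per retained alignment: primary (not secondary, not
#' supplementary), mapped, and with mapping quality at least `mapq_min`.
#' MAPQ 0 is the conventional encoding of multi-mapped reads, so the default
#' gate `mapq_min = 1` drops non-specific matches. SAM 1-based positions are
#' converted to 0-based.
#'
#' @param path SAM or BAM file. SAM text is converted on the fly.
#' @param mapq_min Minimum mapping quality retained (default 1).
#' @param genomes Optional genome tibble from [read_genome_fasta()]; when
#'   given, reference names in the file must all be present or an error is
#'   raised.
#' @param keep_seq Keep the SEQ field (needed for split-read anchoring
#'   checks); default `TRUE`.
#' @return Tibble with columns `read_id`, `genome_id`, `pos` (0-based
#'   leftmost), `strand`, `mate_pos`, `mate_strand`, `mapq`, `aligned_len`,
#'   `clip_left`, `clip_right`, `is_primary`, `is_proper_pair` and,
#'   if `keep_seq`, `seq`.
#' @export
read_alignments <- function(path, mapq_min = 1L, genomes = NULL, keep_seq = TRUE) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  is_sam <- !grepl("\\.bam$", path, ignore.case = TRUE)
  if (is_sam) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "mrnm", "mpos")
  if (keep_seq) what <- c(what, "seq")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = what)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (!is.null(genomes)) {
    refs <- unique(as.character(res$rname))
    missing_refs <- setdiff(refs, genomes$genome_id)
    if (length(missing_refs)) {
      abort(paste0("alignment reference(s) absent from provided genomes: ",
                   paste(missing_refs, collapse = ", ")))
    }
  }
  keep <- !is.na(res$mapq) & res$mapq >= mapq_min
  cig <- res$cigar[keep]
  aligned_len <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  clip_left <- map_int(seq_along(ops), function(i) {
    o <- ops[[i]]
    if (length(o) && o[1] %in% c("S", "H")) as.integer(lens[[i]][1]) else 0L
  })
  clip_right <- map_int(seq_along(ops), function(i) {
    o <- ops[[i]]
    k <- length(o)
    if (k && o[k] %in% c("S", "H")) as.integer(lens[[i]][k]) else 0L
  })
  flag <- res$flag[keep]
  has_mate <- .flag_bit(flag, 0x1L) & !.flag_bit(flag, 0x8L)
  out <- tibble(
    read_id = res$qname[keep],
    genome_id = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L,
    strand = ifelse(.flag_bit(flag, 0x10L), "-", "+"),
    mate_pos = ifelse(has_mate, res$mpos[keep] - 1L, NA_integer_),
    mate_strand = ifelse(has_mate,
                         ifelse(.flag_bit(flag, 0x20L), "-", "+"),
                         NA_character_),
    mapq = as.integer(res$mapq[keep]),
    aligned_len = as.integer(aligned_len),
    clip_left = clip_left,
    clip_right = clip_right,
    is_primary = TRUE,
    is_proper_pair = .flag_bit(flag, 0x2L)
  )
  if (keep_seq) out$seq <- as.character(res$seq)[keep]
  out
}

#' Read prophage/prediction intervals from BED or 1-based TSV
#'
#' BED input is 0-based half-open and used as-is. The `"tsv1"` dialect is a
#' header-bearing TSV with 1-based inclusive `start`/`end` columns
#' (the convention of prophage-prediction exports), converted to 0-based
#' half-open on read. The dialect must be declared; it is never guessed.
#'
#' @param path Input file.
#' @param dialect `"bed"` (default) or `"tsv1"`.
#' @return Tibble with `genome_id`, `start`, `end` (0-based half-open),
#'   `label`, plus any extra TSV columns.
#' @export
read_intervals <- function(path, dialect = c("bed", "tsv1")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("interval file not found: ", path))
  if (dialect == "bed") {
    df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
    if (ncol(df) < 3L) abort("BED requires at least 3 columns")
    out <- tibble(genome_id = as.character(df[[1]]),
                  start = as.integer(df[[2]]),
                  end = as.integer(df[[3]]),
                  label = if (ncol(df) >= 4L) as.character(df[[4]])
                          else paste0("iv", seq_len(nrow(df))))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("genome_id", "start", "end")
    if (!all(need %in% names(df))) {
      abort("tsv1 dialect requires header columns genome_id, start, end")
    }
    out <- tibble(genome_id = as.character(df$genome_id),
                  start = as.integer(df$start) - 1L,
                  end = as.integer(df$end),
                  label = if ("label" %in% names(df)) as.character(df$label)
                          else paste0("iv", seq_len(nrow(df))))
  }
  if (any(is.na(out$start) | is.na(out$end))) {
    abort("non-numeric interval coordinates")
  }
  bad <- out$start >= out$end | out$start < 0L
  if (any(bad)) {
    abort(paste0("invalid interval(s) after normalisation (start >= end or ",
                 "start < 0) at line(s): ", paste(which(bad), collapse = ", ")))
  }
  out
}

#' Write intervals as 4-column BED (0-based half-open)
#'
#' @param intervals Tibble with `genome_id`, `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("genome_id", "start", "end", "label") %in% names(intervals)))
  readr::write_tsv(intervals[, c("genome_id", "start", "end", "label")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Convert 0-based half-open intervals to a 1-based inclusive report table
#'
#' Human-readable report tables are always 1-based inclusive; the column
#' names carry the convention.
#'
#' @param intervals Tibble with `start`, `end` columns (0-based half-open).
#' @return The same tibble with `start`/`end` replaced by
#'   `start_1based`/`end_1based_incl`.
#' @export
as_report_coords <- function(intervals) {
  out <- intervals
  out$start_1based <- out$start + 1L
  out$end_1based_incl <- out$end
  out$start <- NULL
  out$end <- NULL
  dplyr::relocate(out, "start_1based", "end_1based_incl",
                  .after = dplyr::any_of("genome_id"))
}
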