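# Prophage clustering by intergenomic similarity, strain phagotypes,
# genome dereplication by prophage content, the within-phagotype protection
# statistic, and accessory-gene attribution to active-prophage regions.

#' Read a pairwise intergenomic-similarity matrix from TSV
#'
#' Expects a header row of prophage ids and a first column of ids; values
#' are percent similarity in `[0, 100]`.
#'
#' @param path TSV file.
#' @return Numeric matrix with matching dimnames.
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

.check_similarity <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("similarity matrix must be square")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    abort("similarity matrix must have identical row and column labels")
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("similarity matrix must be symmetric")
  }
  if (any(m < 0 | m > 100)) abort("similarities must be in [0, 100]")
  invisible(m)
}

#' Cluster prophages at a similarity threshold
#'
#' Single-linkage clustering: connected components of the graph with an
#' edge wherever pairwise similarity is at least `threshold_percent`.
#' Cluster ids are deterministic (the lexicographically smallest member
#' label).
#'
#' @param matrix Symmetric percent-similarity matrix (diagonal 100),
#'   labelled on both dimensions.
#' @param threshold_percent Similarity threshold, e.g. 95 (species level),
#'   70 (genus level), or 50.
#' @return Tibble `prophage_id`, `cluster_id`, with a `threshold_percent`
#'   attribute.
#' @export
cluster_by_similarity <- function(matrix, threshold_percent) {
  .check_similarity(matrix)
  adj <- matrix >= threshold_percent
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labs <- rownames(matrix)
  cluster_id <- vapply(split(labs, comp[labs]), min, character(1))[
    as.character(comp[labs])]
  out <- tibble(prophage_id = labs, cluster_id = unname(cluster_id))
  attr(out, "threshold_percent") <- threshold_percent
  out
}

.set_string <- function(x) paste(sort(unique(x)), collapse = "+")

#' Assign strain phagotypes from prophage cluster membership
#'
#' A phagotype is the combination of prophage clusters (typically
#' genus-level) a strain carries; strains with identical combinations share
#' a phagotype. A strain without prophages gets the empty phagotype.
#'
#' @param strain_sips Tibble `strain_id`, `prophage_id` (one row per active
#'   prophage; `NA` prophage rows are dropped so SIP-free strains can be
#'   listed).
#' @param clusters Cluster tibble from [cluster_by_similarity()]; every
#'   non-`NA` prophage must be present.
#' @param strains Optional character vector of all strains (defaults to
#'   those in `strain_sips`).
#' @return Tibble `strain_id`, `phagotype_id` (e.g. `"PT03"`),
#'   `cluster_set` (sorted `+`-joined cluster string, `""` when empty),
#'   `clusters` (list column of cluster-id vectors).
#' @export
assign_phagotypes <- function(strain_sips, clusters, strains = NULL) {
  strains <- strains %||% unique(strain_sips$strain_id)
  sips <- dplyr::filter(strain_sips, !is.na(.data$prophage_id))
  missing_cl <- setdiff(sips$prophage_id, clusters$prophage_id)
  if (length(missing_cl)) {
    abort(paste0("prophage(s) without cluster assignment: ",
                 paste(missing_cl, collapse = ", ")))
  }
  sips <- left_join(sips, clusters, by = "prophage_id")
  sets <- map(setNames(strains, strains), function(s) {
    sort(unique(sips$cluster_id[sips$strain_id == s]))
  })
  set_str <- map_chr(sets, .set_string)
  uniq <- sort(unique(set_str))
  pt_ids <- setNames(sprintf("PT%02d", seq_along(uniq)), uniq)
  tibble(strain_id = strains,
         phagotype_id = unname(pt_ids[set_str]),
         cluster_set = unname(set_str),
         clusters = unname(sets))
}

#' Read a donor-by-recipient plaque matrix from TSV
#'
#' Rows are supernatant donors, columns recipients; cell values are
#' interpreted as logical (0/1, TRUE/FALSE).
#'
#' @param path TSV file with donor ids in the first column.
#' @return Logical matrix with dimnames.
#' @export
read_plaque_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "logical"
  m
}

.relation_fun <- function(relation) {
  switch(relation,
    equal = function(d, r) identical(d, r),
    subset_either = function(d, r) all(d %in% r) || all(r %in% d),
    donor_subset_of_recipient = function(d, r) all(d %in% r),
    abort(paste0("unknown phagotype relation: ", relation)))
}

.within_mask <- function(strains, sets, relation_fun) {
  n <- length(strains)
  mask <- matrix(FALSE, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) mask[i, j] <- relation_fun(sets[[i]], sets[[j]])
    }
  }
  mask
}

#' Within-phagotype protection statistic from a plaque matrix
#'
#' Counts plaquing among ordered donor->recipient supernatant interactions
#' whose phagotype cluster sets satisfy `relation` (same phagotype, or
#' subset phagotypes), against all off-diagonal interactions. Lysogens are
#' expected to be protected from phages their own phagotype carries, so the
#' within-group plaquing fraction should be far below the overall one. A
#' seeded permutation test (shuffling which strain carries which cluster
#' set) gives a one-sided p-value for that deficit.
#'
#' @param plaques Logical donor-by-recipient matrix (diagonal ignored).
#' @param phagotypes Assignment tibble from [assign_phagotypes()] covering
#'   every strain in `plaques`.
#' @param relation `"subset_either"` (default: either set contains the
#'   other), `"equal"`, or `"donor_subset_of_recipient"`.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed for the permutation draw.
#' @return A `vip_protection` object; its `summary` tibble has rows
#'   `within` and `all` with `plaquing`, `total`, `fraction`, and the
#'   permutation p-value is in `p_value`.
#' @export
protection_statistic <- function(plaques, phagotypes,
                                 relation = c("subset_either", "equal",
                                              "donor_subset_of_recipient"),
                                 n_perm = 1000L, seed = NULL) {
  relation <- match.arg(relation)
  stopifnot(is.matrix(plaques),
            identical(rownames(plaques), colnames(plaques)))
  strains <- rownames(plaques)
  missing_s <- setdiff(strains, phagotypes$strain_id)
  if (length(missing_s)) {
    abort(paste0("strains missing from phagotype assignment: ",
                 paste(missing_s, collapse = ", ")))
  }
  sets <- phagotypes$clusters[match(strains, phagotypes$strain_id)]
  rel <- .relation_fun(relation)
  off_diag <- !diag(nrow(plaques))
  all_plaquing <- sum(plaques & off_diag, na.rm = TRUE)
  all_total <- sum(off_diag & !is.na(plaques))
  frac_within <- function(sets_perm) {
    mask <- .within_mask(strains, sets_perm, rel) & !is.na(plaques)
    c(sum(plaques & mask, na.rm = TRUE), sum(mask))
  }
  obs <- frac_within(sets)
  obs_frac <- if (obs[2] > 0) obs[1] / obs[2] else NA_real_
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(old(), add = TRUE)
    set.seed(seed)
  }
  perm_frac <- vapply(seq_len(n_perm), function(k) {
    p <- frac_within(sets[sample.int(length(sets))])
    if (p[2] > 0) p[1] / p[2] else NA_real_
  }, numeric(1))
  p_value <- if (is.na(obs_frac)) NA_real_ else
    (1 + sum(perm_frac <= obs_frac, na.rm = TRUE)) / (1 + sum(!is.na(perm_frac)))
  structure(
    list(summary = tibble(
           group = c("within", "all"),
           plaquing = c(obs[1], all_plaquing),
           total = c(obs[2], all_total),
           fraction = c(obs_frac,
                        if (all_total > 0) all_plaquing / all_total else NA_real_)),
         relation = relation, n_perm = n_perm, p_value = p_value),
    class = "vip_protection")
}

# save/restore RNG state so a user-supplied seed does not clobber the
# session stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}

#' @export
print.vip_protection <- function(x, ...) {
  s <- x$summary
  cat("<vip_protection> relation=", x$relation, "\n", sep = "")
  cat(sprintf("  within-group plaquing: %d/%d (%s%%)\n", s$plaquing[1],
              s$total[1], signif(100 * s$fraction[1], 2)))
  cat(sprintf("  all interactions:      %d/%d (%s%%)\n", s$plaquing[2],
              s$total[2], signif(100 * s$fraction[2], 2)))
  cat("  permutation p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.vip_protection <- function(x, ...) x$summary

#' @export
glance.vip_protection <- function(x, ...) {
  tibble(relation = x$relation,
         within_fraction = x$summary$fraction[1],
         all_fraction = x$summary$fraction[2],
         p_value = x$p_value, n_perm = x$n_perm)
}

#' Dereplicate genomes by predicted-prophage cluster content
#'
#' Genomes carrying the same combination of predicted-prophage clusters
#' form one group with a deterministic representative (the
#' lexicographically smallest genome id). Genomes without any prophage
#' share the empty-set group unless `distinguish_empty = TRUE`, which makes
#' each a singleton.
#'
#' @param genome_clusters Tibble `genome_id`, `cluster_id` (`NA` cluster
#'   rows mark prophage-free genomes).
#' @param distinguish_empty Keep prophage-free genomes as singletons
#'   (default `FALSE`).
#' @return Tibble `genome_id`, `group_id`, `representative`, `cluster_set`.
#' @export
dereplicate_by_prophage_content <- function(genome_clusters,
                                            distinguish_empty = FALSE) {
  genomes <- unique(genome_clusters$genome_id)
  sets <- map_chr(setNames(genomes, genomes), function(g) {
    .set_string(stats::na.omit(
      genome_clusters$cluster_id[genome_clusters$genome_id == g]))
  })
  key <- sets
  if (distinguish_empty) {
    empty <- key == ""
    key[empty] <- paste0("\r_singleton_", genomes[empty])
  }
  groups <- split(genomes, key)
  rep_of <- map_chr(groups, min)
  grp_ids <- setNames(sprintf("G%03d", seq_along(sort(names(groups)))),
                      sort(names(groups)))
  tibble(genome_id = genomes,
         group_id = unname(grp_ids[key]),
         representative = unname(rep_of[key]),
         cluster_set = unname(sets))
}

#' Fraction of accessory genes located in active-prophage regions
#'
#' A gene is attributed to an active-prophage (SIP) region when its
#' midpoint lies within one, which is robust to genes straddling att sites.
#'
#' @param genes Tibble `genome_id`, `start`, `end`, `class` (values
#'   `"core"`/`"accessory"`).
#' @param sips Interval tibble of active prophages.
#' @return One-row tibble: `n_accessory_in_sip`, `n_accessory`, `fraction`.
#' @export
accessory_in_sip_fraction <- function(genes, sips) {
  acc <- dplyr::filter(genes, .data$class == "accessory")
  if (nrow(acc) == 0L) {
    return(tibble(n_accessory_in_sip = 0L, n_accessory = 0L,
                  fraction = NA_real_))
  }
  mid <- (acc$start + acc$end) %/% 2L
  in_sip <- map_int(seq_len(nrow(acc)), function(i) {
    as.integer(any(sips$genome_id == acc$genome_id[i] &
                     sips$start <= mid[i] & mid[i] < sips$end))
  })
  tibble(n_accessory_in_sip = sum(in_sip), n_accessory = nrow(acc),
         fraction = sum(in_sip) / nrow(acc))
}
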