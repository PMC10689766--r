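# Shared fixtures and independent oracles. Oracles here are deliberately
# written as plain loops / enumeration, independent of the package's own
# code paths.

# small simulated lysogen used across detection/quantification tests
small_sim <- function(seed = 1L, genome_len_bp = 60000L,
                      prophages = tibble::tibble(
                        length_bp = 20000L, gc = 0.42, titre = 3e7,
                        insertion_pos = 20000L),
                      total_read_pairs = 4000L,
                      background_read_fraction = 0.1, ...) {
  cfg <- sim_config(seed = seed, genome_len_bp = genome_len_bp,
                    prophages = prophages,
                    total_read_pairs = total_read_pairs,
                    background_read_fraction = background_read_fraction,
                    ...)
  simulate_virion_reads(make_lysogen(cfg))
}

# exhaustive boundary search over every base-pair position in the search
# windows, mirroring the documented scoring and tie-break rules with plain
# loops over the evidence
brute_force_boundaries <- function(candidate, evidence) {
  w <- evidence$search_window_bp
  maxins <- evidence$max_insert_bp
  pairs <- evidence$pair_support[evidence$pair_support$orientation_ok, ]
  splits <- evidence$split_support
  aLs <- seq.int(candidate$start - w, candidate$start + w)
  aRs <- seq.int(candidate$end - w, candidate$end + w)
  best <- NULL
  for (aL in aLs) {
    for (aR in aRs) {
      if (aR <= aL) next
      np <- 0L
      for (i in seq_len(nrow(pairs))) {
        if (aL <= pairs$left_anchor_pos[i] &&
            aR >= pairs$right_anchor_pos[i] &&
            (aR - pairs$right_start[i]) +
              (pairs$left_end[i] - aL) <= maxins) np <- np + 1L
      }
      ns <- 0L
      for (i in seq_len(nrow(splits))) {
        hit <- if (splits$side[i] == "right") {
          splits$clip_pos[i] == aR &&
            (is.na(splits$partner_pos[i]) || splits$partner_pos[i] == aL)
        } else {
          splits$clip_pos[i] == aL &&
            (is.na(splits$partner_pos[i]) || splits$partner_pos[i] == aR)
        }
        if (hit) ns <- ns + 1L
      }
      cand <- list(aL = aL, aR = aR, score = np + ns, ns = ns,
                   width = aR - aL)
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$ns > best$ns) ||
          (cand$score == best$score && cand$ns == best$ns &&
             cand$width < best$width) ||
          (cand$score == best$score && cand$ns == best$ns &&
             cand$width == best$width && cand$aL < best$aL)) {
        best <- cand
      }
    }
  }
  best
}

# connected components by transitive closure of the adjacency matrix
brute_force_components <- function(sim_matrix, threshold) {
  adj <- sim_matrix >= threshold
  diag(adj) <- TRUE
  reach <- adj
  n <- nrow(adj)
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  labs <- rownames(sim_matrix)
  comp <- vapply(seq_len(n), function(i) min(labs[reach[i, ]]), character(1))
  setNames(comp, labs)
}

# random structured similarity matrix: clusters of related prophages
random_similarity_matrix <- function(n, seed) {
  set.seed(seed)
  groups <- sort(sample.int(max(2L, n %/% 3L), n, replace = TRUE))
  m <- matrix(runif(n * n, 0, 60), n, n)
  m <- (m + t(m)) / 2
  for (g in unique(groups)) {
    idx <- which(groups == g)
    m[idx, idx] <- runif(length(idx)^2, 60, 100)
    m[idx, idx] <- (m[idx, idx] + t(m[idx, idx])) / 2
  }
  diag(m) <- 100
  labs <- sprintf("phage%02d", seq_len(n))
  dimnames(m) <- list(labs, labs)
  m
}

# 3-sigma half-width for a multinomial proportion estimated from n draws
three_sigma <- function(p, n) 3 * sqrt(p * (1 - p) / n)
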