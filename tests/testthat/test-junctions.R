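test_that("junction evidence is empty without discordant pairs", {
  # concordant inward-facing pair fully inside the candidate
  aln <- tibble::tibble(
    read_id = c("p1", "p1"), genome_id = "g1", pos = c(12000L, 12350L),
    strand = c("+", "-"), mate_pos = c(12350L, 12000L),
    mate_strand = c("-", "+"), mapq = 60L, aligned_len = 150L,
    clip_left = 0L, clip_right = 0L, is_primary = TRUE,
    is_proper_pair = TRUE, seq = NA_character_)
  cand <- tibble::tibble(genome_id = "g1", start = 10000L, end = 30000L,
                         label = "c1")
  ev <- collect_junction_evidence(aln, cand)
  expect_equal(ev$support_count, 0L)
  expect_equal(nrow(ev$pair_support), 0L)
})

test_that("orientation-inconsistent edge pairs are recorded but not counted", {
  # both mates near the right edges but inward-facing (normal FR pair)
  aln <- tibble::tibble(
    read_id = c("p1", "p1"), genome_id = "g1", pos = c(10050L, 29800L),
    strand = c("+", "-"), mate_pos = c(29800L, 10050L),
    mate_strand = c("-", "+"), mapq = 60L, aligned_len = 150L,
    clip_left = 0L, clip_right = 0L, is_primary = TRUE,
    is_proper_pair = FALSE, seq = NA_character_)
  cand <- tibble::tibble(genome_id = "g1", start = 10000L, end = 30000L,
                         label = "c1")
  ev <- collect_junction_evidence(aln, cand)
  expect_equal(nrow(ev$pair_support), 1L)
  expect_false(ev$pair_support$orientation_ok)
  expect_equal(ev$support_count, 0L)
})

test_that("simulated junction pairs are recovered with little loss", {
  sim <- small_sim(seed = 21L, total_read_pairs = 8000L)
  pp <- sim$truth$prophages
  cand <- tibble::tibble(genome_id = "sim_chr", start = pp$start,
                         end = pp$end, label = "c1")
  ev <- collect_junction_evidence(sim$alignments, cand,
                                  genome = sim$truth$genome)
  # truth: pairs whose fragment wrapped the circular junction
  truth_junctions <- sum(!sim$alignments$is_proper_pair &
                           sim$alignments$read_of_pair == 1L &
                           sim$alignments$origin == pp$label)
  expect_gte(truth_junctions, 50L)
  # every junction fragment yields an oriented pair and/or a split read
  expect_gte(ev$support_count, ceiling(0.9 * truth_junctions))
  expect_gt(nrow(ev$split_support), 0L)
  # split anchors pin the true boundaries exactly
  expect_true(all(ev$split_support$partner_pos[ev$split_support$side == "right"]
                  == pp$start))
  expect_true(all(ev$split_support$clip_pos[ev$split_support$side == "right"]
                  == pp$end))
})

test_that("refinement recovers exact truth boundaries and tiers calls", {
  sim <- small_sim(seed = 22L)
  pp <- sim$truth$prophages
  det <- detect_prophages(sim$alignments, sim$truth$genome)
  expect_equal(nrow(det$calls), 1L)
  expect_equal(det$calls$start, pp$start)
  expect_equal(det$calls$end, pp$end)
  expect_equal(det$calls$confidence, "junction")
  expect_equal(det$calls$length_bp, pp$length_bp)

  # with no surviving evidence the island edges are kept, flagged
  cand <- det$islands[1, ]
  empty_ev <- collect_junction_evidence(
    sim$alignments[0, ], cand, genome = sim$truth$genome)
  call <- refine_boundaries(cand, empty_ev)
  expect_equal(call$confidence, "coverage_only")
  expect_equal(call$start, cand$start)
  expect_equal(call$end, cand$end)
})

test_that("a split read breaks ties between equal pair-support boundaries", {
  cand <- tibble::tibble(genome_id = "g1", start = 1000L, end = 5000L,
                         label = "c1")
  ev <- structure(list(
    candidate = cand,
    pair_support = tibble::tibble(
      left_anchor_pos = c(1010L, 1015L), left_end = c(1160L, 1165L),
      right_start = c(4700L, 4690L), right_anchor_pos = c(4850L, 4840L),
      orientation_ok = TRUE),
    split_support = tibble::tibble(side = "right", clip_pos = 4900L,
                                   partner_pos = 995L),
    support_count = 3L, search_window_bp = 2000L, max_insert_bp = 1500L),
    class = "vip_junctions")
  call <- refine_boundaries(cand, ev)
  # both pairs are satisfied by (995, 4900) too, so the split decides
  expect_equal(call$start, 995L)
  expect_equal(call$end, 4900L)
})

test_that("boundary search agrees with exhaustive enumeration (<=50 kb)", {
  for (seed in c(31L, 32L, 33L)) {
    sim <- small_sim(seed = seed, genome_len_bp = 40000L,
                     prophages = tibble::tibble(
                       length_bp = 16000L, gc = 0.45, titre = 3e7,
                       insertion_pos = 12000L),
                     total_read_pairs = 1500L)
    prof <- compute_coverage(sim$alignments, sim$truth$genome)
    isl <- segment_islands(prof)
    expect_equal(nrow(isl), 1L)
    ev <- collect_junction_evidence(sim$alignments, isl[1, ],
                                    search_window_bp = 150L,
                                    genome = sim$truth$genome)
    expect_gte(ev$support_count, 2L)  # junction-tier evidence present
    call <- refine_boundaries(isl[1, ], ev)
    bf <- brute_force_boundaries(isl[1, ], ev)
    expect_equal(call$start, bf$aL)
    expect_equal(call$end, bf$aR)
    # never outside candidate +/- window
    expect_lte(abs(call$start - isl$start[1]), 150L)
    expect_lte(abs(call$end - isl$end[1]), 150L)
  }
})

test_that("flanking enrichment flags a lateral-transduction gradient", {
  cfg <- sim_config(seed = 41L, genome_len_bp = 400000L,
                    prophages = tibble::tibble(
                      length_bp = 30000L, gc = 0.45, titre = 5e7,
                      insertion_pos = 120000L),
                    total_read_pairs = 60000L,
                    background_read_fraction = 0.05,
                    lateral_transduction = list(
                      side = "right", extent_bp = 200000L,
                      headful_bp = 40000L, edge_enrichment = 20))
  sim <- apply_lateral_transduction(simulate_virion_reads(make_lysogen(cfg)))
  expect_equal(nrow(sim$lateral), 5L)  # 5 headful steps
  expect_true(all(diff(sim$lateral$enrichment) < 0))
  prof <- compute_coverage(sim$alignments, sim$truth$genome)
  prof$background <- median(prof$depth[1:100000])  # clean host flank
  truth_call <- tibble::tibble(genome_id = "sim_chr",
                               start = sim$truth$prophages$start,
                               end = sim$truth$prophages$end)
  fl <- flanking_enrichment(prof, truth_call, window_bp = 100000L)
  right <- fl[fl$side == "right", ]
  left <- fl[fl$side == "left", ]
  expect_gt(right$enrichment, 5)
  expect_lt(right$decay_slope, 0)
  expect_lt(left$enrichment, 2)

  # flat flank: enrichment ~1, slope ~0
  sim0 <- small_sim(seed = 42L)
  p0 <- compute_coverage(sim0$alignments, sim0$truth$genome)
  isl <- segment_islands(p0)
  p0$background <- attr(isl, "background")
  fl0 <- flanking_enrichment(p0, tibble::tibble(
    genome_id = "sim_chr", start = sim0$truth$prophages$start,
    end = sim0$truth$prophages$end), window_bp = 10000L)
  expect_true(all(fl0$enrichment < 2))
  expect_true(all(abs(fl0$decay_slope) < 1e-3))
  expect_error(flanking_enrichment(p0, truth_call, window_bp = 0L),
               "positive")
})
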