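chain_matrix <- function() {
  labs <- c("A", "B", "C", "D")
  m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  m["A", "B"] <- m["B", "A"] <- 80
  m["B", "C"] <- m["C", "B"] <- 75
  m["C", "D"] <- m["D", "C"] <- 60
  diag(m) <- 100
  m
}

test_that("similarity clustering is single-linkage with deterministic ids", {
  m <- chain_matrix()
  cl <- cluster_by_similarity(m, 70)
  expect_equal(cl$cluster_id[match(c("A", "B", "C"), cl$prophage_id)],
               rep("A", 3))
  expect_equal(cl$cluster_id[cl$prophage_id == "D"], "D")
  # threshold above the scale isolates everything
  cl2 <- cluster_by_similarity(m, 101)
  expect_equal(cl2$cluster_id, cl2$prophage_id)
  # all-identical matrix collapses to one cluster
  m1 <- matrix(100, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(unique(cluster_by_similarity(m1, 95)$cluster_id), "x")
  # asymmetric input rejected
  bad <- m
  bad["A", "B"] <- 10
  expect_error(cluster_by_similarity(bad, 70), "symmetric")
})

test_that("clustering agrees with a transitive-closure oracle", {
  for (seed in c(71L, 72L, 73L)) {
    m <- random_similarity_matrix(12L, seed)
    for (thr in c(95, 70, 50)) {
      cl <- cluster_by_similarity(m, thr)
      oracle <- brute_force_components(m, thr)
      expect_equal(setNames(cl$cluster_id, cl$prophage_id), oracle)
    }
  }
})

test_that("higher thresholds refine lower-threshold clusterings", {
  for (seed in c(74L, 75L)) {
    m <- random_similarity_matrix(15L, seed)
    cl95 <- cluster_by_similarity(m, 95)
    cl70 <- cluster_by_similarity(m, 70)
    cl50 <- cluster_by_similarity(m, 50)
    refines <- function(fine, coarse) {
      j <- dplyr::inner_join(fine, coarse, by = "prophage_id",
                             suffix = c("_f", "_c"))
      all(tapply(j$cluster_id_c, j$cluster_id_f,
                 function(x) length(unique(x))) == 1L)
    }
    expect_true(refines(cl95, cl70))
    expect_true(refines(cl70, cl50))
  }
})

test_that("phagotypes group strains by identical cluster combinations", {
  m <- chain_matrix()
  cl <- cluster_by_similarity(m, 70)  # {A,B,C} -> A, {D} -> D
  sips <- tibble::tibble(
    strain_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
    prophage_id = c("A", "D", "B", "D", "C", NA))
  pt <- assign_phagotypes(sips, cl,
                          strains = c("s1", "s2", "s3", "s4", "s5"))
  sets <- setNames(pt$cluster_set, pt$strain_id)
  expect_equal(unname(sets["s1"]), "A+D")
  expect_equal(unname(sets["s2"]), "A")
  expect_equal(unname(sets["s4"]), "A")   # same genus cluster as s2
  expect_equal(unname(sets["s5"]), "")    # SIP-free strain: empty phagotype
  expect_equal(pt$phagotype_id[pt$strain_id == "s2"],
               pt$phagotype_id[pt$strain_id == "s4"])
  expect_equal(length(unique(pt$phagotype_id)), 4L)  # A+D, A, D, empty
  expect_error(assign_phagotypes(
    tibble::tibble(strain_id = "s9", prophage_id = "ZZ"), cl), "without")
})

test_that("protection statistic counts within-group interactions correctly", {
  # 4 strains: s1,s2 share phagotype {c1}; s3 = {c1,c2} (superset); s4 = {c9}
  pt <- tibble::tibble(
    strain_id = c("s1", "s2", "s3", "s4"),
    phagotype_id = c("PT1", "PT1", "PT2", "PT3"),
    cluster_set = c("c1", "c1", "c1+c2", "c9"),
    clusters = list("c1", "c1", c("c1", "c2"), "c9"))
  pm <- matrix(FALSE, 4, 4, dimnames = list(pt$strain_id, pt$strain_id))
  pm["s1", "s4"] <- TRUE  # cross-phagotype kill
  pm["s3", "s1"] <- TRUE  # within-subset kill (the rare exception)
  ps <- protection_statistic(pm, pt, relation = "subset_either",
                             n_perm = 200, seed = 1)
  s <- ps$summary
  # within pairs: (s1,s2)x2, (s1,s3)x2, (s2,s3)x2 = 6 ordered interactions
  expect_equal(s$total[s$group == "within"], 6)
  expect_equal(s$plaquing[s$group == "within"], 1)
  expect_equal(s$total[s$group == "all"], 12)
  expect_equal(s$plaquing[s$group == "all"], 2)
  # donor-subset relation drops the (s3 -> s1, s3 -> s2) direction
  ps2 <- protection_statistic(pm, pt, relation = "donor_subset_of_recipient",
                              n_perm = 10, seed = 1)
  expect_equal(ps2$summary$total[1], 4)
  expect_equal(ps2$summary$plaquing[1], 0)
  # equal relation keeps only the s1/s2 pair
  ps3 <- protection_statistic(pm, pt, relation = "equal", n_perm = 10, seed = 1)
  expect_equal(ps3$summary$total[1], 2)

  # all-false matrix: both fractions 0 and permutation p = 1
  pm0 <- pm & FALSE
  ps0 <- protection_statistic(pm0, pt, n_perm = 100, seed = 2)
  expect_equal(ps0$summary$fraction, c(0, 0))
  expect_equal(ps0$p_value, 1)

  # invariance under strain relabeling
  perm <- c("s3", "s1", "s4", "s2")
  pm_r <- pm[perm, perm]
  pt_r <- pt[match(perm, pt$strain_id), ]
  ps_r <- protection_statistic(pm_r, pt_r, relation = "subset_either",
                               n_perm = 10, seed = 1)
  expect_equal(ps_r$summary$plaquing, s$plaquing)
  expect_equal(ps_r$summary$total, s$total)
})

test_that("dereplication partitions genomes by prophage-cluster content", {
  gc <- tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g2", "g3", "g4"),
    cluster_id = c("c1", "c2", "c2", "c1", "c1", NA))
  d <- dereplicate_by_prophage_content(gc)
  expect_equal(d$group_id[d$genome_id == "g1"],
               d$group_id[d$genome_id == "g2"])
  expect_equal(d$representative[d$genome_id == "g2"], "g1")
  expect_equal(length(unique(d$group_id)), 3L)
  # partition: each genome in exactly one group
  expect_equal(sort(d$genome_id), c("g1", "g2", "g3", "g4"))
  # order invariance
  d2 <- dereplicate_by_prophage_content(gc[sample(nrow(gc)), ])
  expect_equal(dplyr::arrange(d2, genome_id), dplyr::arrange(d, genome_id))
  # empty sets: shared group by default, singletons when distinguished
  gc2 <- tibble::tibble(genome_id = c("a", "b"), cluster_id = NA_character_)
  expect_equal(length(unique(dereplicate_by_prophage_content(gc2)$group_id)), 1L)
  expect_equal(length(unique(dereplicate_by_prophage_content(
    gc2, distinguish_empty = TRUE)$group_id)), 2L)
})

test_that("accessory genes are attributed to SIP regions by midpoint", {
  sips <- tibble::tibble(genome_id = "g1", start = 1000L, end = 2000L,
                         label = "sip1")
  genes <- tibble::tibble(
    genome_id = "g1",
    start = c(900L, 1100L, 1500L, 1900L, 2500L, 100L, 950L, 1998L, 3000L, 4000L),
    end = c(1000L, 1200L, 1600L, 2000L, 2600L, 200L, 1060L, 2100L, 3100L, 4100L),
    class = "accessory")
  # midpoints: 950,1150,1550,1950,2550,150,1005,2049,3050,4050 -> 4 inside
  res <- accessory_in_sip_fraction(genes, sips)
  expect_equal(res$n_accessory_in_sip, 4L)
  expect_equal(res$n_accessory, 10L)
  expect_equal(percent_rate(res$n_accessory_in_sip, res$n_accessory), 40)
  # no SIPs -> zero attribution
  expect_equal(accessory_in_sip_fraction(genes, sips[0, ])$n_accessory_in_sip, 0L)
  # core genes are ignored
  genes$class[1:9] <- "core"
  expect_equal(accessory_in_sip_fraction(genes, sips)$n_accessory, 1L)
})
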