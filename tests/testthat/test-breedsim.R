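test_that("half-diallel plans enumerate unordered pairs", {
  plan <- half_diallel_plan(c("a", "b", "c"))
  expect_identical(nrow(plan), 3L)
  expect_identical(plan[, "p1"], c("a", "a", "b"))
  expect_identical(plan[, "p2"], c("b", "c", "c"))
  expect_identical(nrow(half_diallel_plan(paste0("p", 1:50))), 1225L)
  expect_error(half_diallel_plan("solo"), "parameter error")
  # no self-crosses, no duplicated pairs
  p10 <- half_diallel_plan(1:10)
  expect_true(all(p10[, 1] != p10[, 2]))
  expect_identical(anyDuplicated(paste(p10[, 1], p10[, 2])), 0L)
})

test_that("meiosis respects map structure in its exact cases", {
  map <- marker_map(paste0("m", 1:4), rep("1", 4), (1:4) * 1e6)
  # homozygous parent -> gamete is the shared haplotype whatever recombines
  homo <- rbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L))
  set.seed(1)
  expect_identical(meiosis_gamete(homo, map), c(1L, 0L, 1L, 0L))
  # zero-length chromosome (single marker): gamete = one parental allele
  map1 <- marker_map("m1", "1", 1e6)
  het <- rbind(1L, 0L)
  set.seed(2)
  g <- replicate(50, meiosis_gamete(het, map1))
  expect_true(all(g %in% 0:1))
  expect_true(any(g == 0L) && any(g == 1L))   # fair-coin start phase
  # heterozygous parent: every gamete is a mosaic of the two haplotypes
  het4 <- rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L))
  set.seed(3)
  for (r in 1:20) expect_true(all(meiosis_gamete(het4, map) %in% 0:1))
})

test_that("recombination fraction at 50 cM matches Haldane's map function", {
  # two markers 50 cM apart; expected r = (1 - exp(-1))/2 = 0.3161
  map <- marker_map(c("a", "b"), c("1", "1"), c(0, 50e6))
  parent <- rbind(c(1L, 1L), c(0L, 0L))
  n <- 2e4
  set.seed(11)
  rec <- vapply(seq_len(n), function(i) {
    g <- meiosis_gamete(parent, map)
    g[1] != g[2]
  }, TRUE)
  r_hat <- mean(rec)
  r_exp <- (1 - exp(-1)) / 2
  expect_lt(abs(r_hat - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
})

test_that("doubled haploids are exactly homozygous and allele-conserving", {
  map <- marker_map(paste0("m", 1:6), rep("1", 6), (1:6) * 1e6)
  set.seed(4)
  parent <- rbind(sample(0:1, 6, TRUE), sample(0:1, 6, TRUE))
  for (r in 1:10) {
    dh <- make_dh(parent, map)
    expect_identical(dh[1, ], dh[2, ])
    # every DH allele existed in the parent at that locus
    expect_true(all(dh[1, ] == parent[1, ] | dh[1, ] == parent[2, ]))
  }
})

test_that("genetic value equals the GEBV computed from the same effects", {
  panel <- simulate_panel(8, markers_per_chrom = 12, seed = 6)
  eff <- simulate_effects_phenotypes(panel, seed = 6)$effects
  g <- gebv(panel, eff)
  for (i in c(1, 4, 8)) {
    geno <- matrix(panel$alleles[i, , ], nrow = 2)
    expect_equal(genetic_value(geno, eff), unname(g[i]))
  }
  expect_error(genetic_value(matrix(0L, 2, 3), eff), "alignment error")
})

test_that("expected heterozygosity reproduces hand-computed frequencies", {
  # one locus, p = 0.5 -> 2pq = 0.5
  pop <- list(rbind(1L, 1L), rbind(0L, 0L))
  expect_equal(expected_heterozygosity(pop), 0.5)
  # fixed locus -> 0
  expect_equal(expected_heterozygosity(list(rbind(1L, 1L), rbind(1L, 1L))), 0)
  # two loci, p = (0.75, 0.25) -> mean(2 * 0.75 * 0.25, 2 * 0.25 * 0.75) = 0.375
  pop2 <- list(rbind(c(1L, 0L), c(1L, 0L)), rbind(c(1L, 1L), c(0L, 0L)))
  expect_equal(expected_heterozygosity(pop2), 0.375)
})

test_that("sim_config enforces its structural invariants", {
  expect_error(sim_config(n_parents = 10, new_parents_per_cycle = 5,
                          retained_parents = 4),
               "must equal n_parents")
  expect_error(sim_config(dh_per_cross = 3, selected_per_cross = 5), "<=")
  expect_error(run_breeding_simulation(simulate_panel(5, seed = 1),
                                       marker_effects(0, rep(0, 50),
                                                      paste0("m", 1:50)),
                                       paste0("ind", 1:3),
                                       sim_config(n_parents = 4,
                                                  new_parents_per_cycle = 1,
                                                  retained_parents = 3,
                                                  cycles = 1, replicates = 1)),
               "founder set")
})

test_that("a desk-scale simulation improves the trait and loses diversity", {
  panel <- simulate_panel(12, n_chromosomes = 2, markers_per_chrom = 30,
                          block_length = 3, n_ancestral_haplotypes = 3,
                          equifrequent = FALSE, seed = 21)
  eff <- simulate_effects_phenotypes(panel, h2 = 0.9, seed = 22)$effects
  cfg <- sim_config(n_parents = 8, dh_per_cross = 6, selected_per_cross = 2,
                    new_parents_per_cycle = 3, retained_parents = 5,
                    cycles = 6, replicates = 5, seed = 30)
  res <- run_breeding_simulation(panel, eff, paste0("ind", 1:8), cfg)
  expect_identical(nrow(res), 5L * 7L)
  # per replicate: lower (better) mean value at the end; selection never
  # worsens the parent mean because retained parents are the previous best
  by_rep <- split(res, res$replicate)
  gain <- vapply(by_rep, function(d)
    d$mean_genetic_value[d$cycle == 0] - d$mean_genetic_value[d$cycle == 6], 0)
  expect_true(all(gain >= 0))
  expect_gt(mean(gain), 0)
  # heterozygosity declines from start to finish in most replicates
  hloss <- vapply(by_rep, function(d)
    d$expected_heterozygosity[d$cycle == 0] -
      d$expected_heterozygosity[d$cycle == 6], 0)
  expect_gte(sum(hloss > 0), 4L)
})

test_that("with all-zero effects selection is neutral drift in value", {
  panel <- simulate_panel(8, markers_per_chrom = 10, seed = 31)
  eff <- marker_effects(2, rep(0, 10), panel$map$marker_id)
  cfg <- sim_config(n_parents = 6, dh_per_cross = 4, selected_per_cross = 2,
                    new_parents_per_cycle = 2, retained_parents = 4,
                    cycles = 3, replicates = 2, seed = 5)
  res <- run_breeding_simulation(panel, eff, paste0("ind", 1:6), cfg)
  expect_true(all(res$mean_genetic_value == 2))
  expect_true(all(res$genetic_variance == 0))
})

test_that("named founder lists label strategies and are seed-deterministic", {
  panel <- simulate_panel(10, markers_per_chrom = 12, seed = 41)
  eff <- simulate_effects_phenotypes(panel, seed = 41)$effects
  cfg <- sim_config(n_parents = 5, dh_per_cross = 3, selected_per_cross = 1,
                    new_parents_per_cycle = 2, retained_parents = 3,
                    cycles = 2, replicates = 2, seed = 9)
  founders <- list(ohs = paste0("ind", 1:5), gebv = paste0("ind", 6:10))
  r1 <- run_breeding_simulation(panel, eff, founders, cfg)
  r2 <- run_breeding_simulation(panel, eff, founders, cfg)
  expect_identical(sort(unique(r1$strategy)), c("gebv", "ohs"))
  expect_identical(r1, r2)
})
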