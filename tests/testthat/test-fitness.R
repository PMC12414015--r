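test_that("the four-line fixture reproduces its enumerated optima", {
  f1 <- make_fixture_f1()
  for (kind in c("ohs", "opv", "gebv_sum")) {
    prob <- selection_problem(f1$tensor, f1$expected$k, kind)
    bf <- brute_force_optimum(prob)
    exp_best <- switch(kind, ohs = f1$expected$ohs_best,
                       opv = f1$expected$opv_best,
                       gebv_sum = sum(sort(f1$expected$gebv_totals,
                                           decreasing = TRUE)[1:2]))
    exp_arg <- switch(kind, ohs = f1$expected$ohs_argmax,
                      opv = f1$expected$opv_argmax,
                      gebv_sum = f1$expected$gebv_argmax)
    expect_equal(bf$best_fitness, exp_best)
    expect_equal(bf$argmax, exp_arg)
  }
})

test_that("hand-audited subset values on the fixture are exact", {
  f1 <- make_fixture_f1()
  prob <- selection_problem(f1$tensor, 2L, "ohs")
  # {1,2}: block1 distinct maxima A=4,B=3,C=1 -> 4+3; block2 E=2,F=0 -> 2+0
  expect_equal(ohs_fitness(prob, c(1L, 2L)), 7 + 2)
  # {3,4}: block1 A=4,B=3,D=5,C=1 -> 5+4; block2 G=6,F=0 -> 6+0
  expect_equal(ohs_fitness(prob, c(3L, 4L)), 9 + 6)
  popv <- selection_problem(f1$tensor, 2L, "opv")
  expect_equal(opv_fitness(popv, c(1L, 2L)), 2 * (4 + 2))
  expect_equal(opv_fitness(popv, c(3L, 4L)), 2 * (5 + 6))
  pg <- selection_problem(f1$tensor, 2L, "gebv_sum")
  expect_equal(gebv_sum_fitness(pg, c(2L, 4L)), 8 + 6)
})

test_that("a block whose subset carries a single variant doubles its value", {
  values <- array(c(3, 1, 3, 0), dim = c(1L, 2L, 2L))
  variants <- array(c("X", "Y", "X", "Z"), dim = c(1L, 2L, 2L))
  tens <- block_value_tensor(values, variants, c("i1", "i2"))
  prob <- selection_problem(tens, 1L, "ohs")
  expect_equal(ohs_fitness(prob, 1L), 6)   # only variant X present -> 3 + 3
  expect_equal(ohs_fitness(prob, 2L), 1 + 0)  # variants Y=1, Z=0 both present
})

test_that("distinct-by-individual counts one value per line, not per variant", {
  f1 <- make_fixture_f1()
  pv <- selection_problem(f1$tensor, 2L, "ohs", distinct_by = "variant")
  pi <- selection_problem(f1$tensor, 2L, "ohs", distinct_by = "individual")
  # block1 {1,3}: variant view A=4,B=3 -> 7; individual view 4+4 -> 8
  # block2 {1,3}: G=6,E=2,F=0 -> 8 either way (one value per line: 2+6)
  expect_equal(ohs_fitness(pv, c(1L, 3L)), 7 + 8)
  expect_equal(ohs_fitness(pi, c(1L, 3L)), 8 + 8)
})

test_that("fast evaluators match the independent slow oracles on random instances", {
  for (seed in 1:6) {
    prob <- make_random_problem(seed, N = 12, k = 3, kind = "ohs")
    tens <- prob$tensor
    set.seed(seed + 900)
    for (r in 1:8) {
      s <- sort(sample.int(12, 3))
      expect_equal(ohs_fitness(prob, s), ref_ohs(tens, s))
      popv <- selection_problem(tens, 3, "opv")
      expect_equal(opv_fitness(popv, s), ref_opv(tens, s))
      pg <- selection_problem(tens, 3, "gebv_sum")
      expect_equal(gebv_sum_fitness(pg, s), ref_gebv_sum(tens, s))
    }
    pind <- selection_problem(tens, 3, "ohs", distinct_by = "individual")
    s <- sort(sample.int(12, 3))
    expect_equal(ohs_fitness(pind, s), ref_ohs(tens, s, "individual"))
  }
})

test_that("brute force agrees with the reference enumeration", {
  for (seed in 1:3) {
    prob <- make_random_problem(seed + 20, N = 9, k = 3, kind = "ohs")
    bf <- brute_force_optimum(prob)
    ref <- ref_enumerate(prob$tensor, 3, ref_ohs)
    expect_equal(bf$best_fitness, ref$best_fitness)
    expect_equal(bf$argmax, ref$argmax)
  }
})

test_that("structural fitness inequalities hold on random subsets", {
  for (seed in 4:8) {
    prob <- make_random_problem(seed, N = 14, k = 4, kind = "ohs")
    popv <- selection_problem(prob$tensor, 4, "opv")
    set.seed(seed)
    for (r in 1:10) {
      s <- sample.int(14, 4)
      # 2 * blockwise max dominates top1 + top2 of distinct values
      expect_gte(opv_fitness(popv, s), ohs_fitness(prob, s) - 1e-12)
      # permutation invariance of the subset
      expect_equal(ohs_fitness(prob, s), ohs_fitness(prob, rev(s)))
    }
    # growing the subset never hurts OHS: check along a nested chain
    p5 <- selection_problem(prob$tensor, 5, "ohs")
    s4 <- sort(sample.int(14, 4))
    s5 <- c(s4, setdiff(seq_len(14), s4)[1])
    expect_gte(ohs_fitness(p5, s5), ohs_fitness(prob, s4) - 1e-12)
  }
})

test_that("the GEBV-sum optimum is plain truncation selection", {
  prob <- make_random_problem(11, N = 12, k = 4, kind = "gebv_sum")
  bf <- brute_force_optimum(prob)
  trunc_sel <- sort(order(prob$ind_total, decreasing = TRUE)[1:4])
  expect_true(any(vapply(bf$argmax, identical, TRUE, trunc_sel)))
  expect_equal(bf$best_fitness, sum(prob$ind_total[trunc_sel]))
})

test_that("degenerate and guarded cases behave", {
  f1 <- make_fixture_f1()
  # k = N: the only subset is everyone
  pN <- selection_problem(f1$tensor, 4L, "ohs")
  bf <- brute_force_optimum(pN)
  expect_equal(bf$argmax, list(1:4))
  expect_equal(bf$best_fitness, ohs_fitness(pN, 1:4))
  # infeasible subsets are rejected
  p2 <- selection_problem(f1$tensor, 2L, "ohs")
  expect_error(ohs_fitness(p2, c(1L, 2L, 3L)), "constraint error")
  expect_error(evaluate_fitness(p2, rep(TRUE, 4)), "constraint error")
  # enumeration refuses oversized spaces
  big <- make_random_problem(2, N = 12, k = 6)
  expect_error(brute_force_optimum(big, cap = 100), "refusal")
})

test_that("search-space size uses log-gamma and matches exact arithmetic", {
  expect_equal(log10_combinations(5, 2), 1)          # C(5,2) = 10
  expect_equal(log10_combinations(10, 10), 0)        # single subset
  # spot check against exact integer combinatorics
  expect_equal(log10_combinations(60, 25), log10(choose(60, 25)), tolerance = 1e-12)
})
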