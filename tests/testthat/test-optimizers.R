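# Small shared problems: the exact 4-line fixture and a 12-line random one.
f1_problem <- function(kind = "ohs") {
  f1 <- make_fixture_f1()
  selection_problem(f1$tensor, 2L, kind)
}

test_that("repair_to_k is deterministic and priority-driven", {
  pr <- c(0.9, 0.1, 0.5, 0.7, 0.3)
  # too many selected: drop the lowest-priority selected indices
  expect_identical(which(repair_to_k(c(T, T, T, F, F), 2L, pr)), c(1L, 3L))
  # too few: add the highest-priority unselected indices
  expect_identical(which(repair_to_k(c(F, T, F, F, F), 3L, pr)), c(1L, 2L, 4L))
  # already feasible: unchanged
  expect_identical(repair_to_k(c(T, F, T, F, F), 2L, pr), c(T, F, T, F, F))
  # ties break to the lowest index
  expect_identical(which(repair_to_k(rep(FALSE, 4), 2L, rep(0.5, 4))), c(1L, 2L))
})

test_that("tournament selection returns the sampled maximum, ties to lowest index", {
  set.seed(1)
  fit <- c(3, 7, 5)
  for (r in 1:20) {
    i <- tournament_select(fit, 3L)
    expect_true(i %in% 1:3)
  }
  # with size >> n, the best member always appears in the sample
  set.seed(2)
  expect_true(all(replicate(20, tournament_select(fit, 50L)) == 2L))
  set.seed(3)
  expect_true(all(replicate(20, tournament_select(rep(1, 4), 50L)) == 1L))
})

test_that("crossover and mutation preserve cardinality over many seeded draws", {
  set.seed(10)
  for (r in 1:300) {
    N <- sample(4:15, 1)
    k <- sample.int(N - 1L, 1)
    p1 <- random_feasible_solution(N, k)
    p2 <- random_feasible_solution(N, k)
    kids <- one_point_crossover_with_repair(p1, p2, k)
    expect_identical(sum(kids[[1]]), k)
    expect_identical(sum(kids[[2]]), k)
    m <- swap_mutation(p1, 0.5)
    expect_identical(sum(m), k)
  }
  # k = N leaves nothing to swap
  expect_identical(swap_mutation(rep(TRUE, 3), 1), rep(TRUE, 3))
})

test_that("top-k decoding selects the largest keys with index tie-breaks", {
  expect_identical(which(topk_decode(c(0.1, 0.9, 0.4, 0.8), 2L)), c(2L, 4L))
  expect_identical(which(topk_decode(c(0.5, 0.5, 0.5), 2L)), c(1L, 2L))
  expect_error(topk_decode(c(0.1, 0.2), 3L), "exceeds")
})

test_that("DE mutation stays in the unit box and uses distinct donors", {
  set.seed(7)
  keys <- matrix(runif(40), nrow = 8)
  for (strat in c("rand/1/bin", "best/1/bin", "current-to-best/1/bin")) {
    for (r in 1:50) {
      m <- de_mutation(keys, 3L, which.max(rowSums(keys)), strat, 0.9)
      expect_true(all(m >= 0 & m <= 1))
      expect_length(m, ncol(keys))
    }
  }
  tiny <- matrix(runif(6), nrow = 3)
  expect_error(de_mutation(tiny, 1L, 2L, "rand/1/bin", 0.5), "config error")
})

test_that("PSO velocity update obeys its closed form when r1, r2 are degenerate", {
  # with p_best = g_best = x the stochastic terms vanish: v' = w v exactly
  v <- c(1, -2, 0.5); x <- c(1, 0, 1)
  set.seed(5)
  expect_equal(pso_velocity_update(v, x, x, x, 0.4, 1.5, 2.0), 0.4 * v)
  # attraction signs: x below both bests pushes the velocity up
  set.seed(6)
  v2 <- pso_velocity_update(rep(0, 3), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1),
                            0.5, 1.5, 2.0)
  expect_true(all(v2 >= 0))
  expect_equal(sigmoid(0), 0.5)
})

test_that("SA acceptance probability reproduces the Metropolis closed form", {
  expect_equal(sa_accept_probability(1, 2, 0.01), 1)     # uphill always
  expect_equal(sa_accept_probability(1, 1, 0.01), 1)     # ties accepted
  expect_equal(sa_accept_probability(2, 1, 0.5), exp(-2))
  expect_error(sa_accept_probability(1, 0, 0), "temperature")
})

test_that("SA empirical acceptance of a fixed worse move matches exp(delta/T)", {
  # criterion: frequency within 3 sigma of the closed form over 1e4 draws
  delta <- -0.02; temp <- 0.05
  p <- sa_accept_probability(0, delta, temp)
  set.seed(42)
  acc <- mean(runif(1e4) < p)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("every algorithm solves the exact four-line fixture", {
  pohs <- f1_problem("ohs")
  popv <- f1_problem("opv")
  ga_hits <- sum(vapply(1:10, function(s)
    run_ga(pohs, ga_config(pop_size = 20, generations = 10, seed = s))$final_fitness == 15, TRUE))
  expect_gte(ga_hits, 9)
  de_hits <- sum(vapply(1:10, function(s)
    run_de(popv, de_config(pop_size = 20, generations = 50, seed = s))$final_fitness == 22, TRUE))
  expect_gte(de_hits, 9)
  pso_hits <- sum(vapply(1:10, function(s)
    run_pso(pohs, pso_config(swarm_size = 20, iterations = 100, seed = s))$final_fitness == 15, TRUE))
  expect_gte(pso_hits, 9)
  sa_hits <- sum(vapply(1:10, function(s)
    run_sa(pohs, sa_config(seed = s))$final_fitness == 15, TRUE))
  expect_gte(sa_hits, 8)
})

test_that("identical (problem, config, seed) gives bit-identical traces", {
  prob <- make_random_problem(31, N = 12, k = 3)
  a <- run_ga(prob, ga_config(pop_size = 30, generations = 15, seed = 9))
  b <- run_ga(prob, ga_config(pop_size = 30, generations = 15, seed = 9))
  expect_identical(a$trace[, c("iteration", "best_fitness", "mean_fitness")],
                   b$trace[, c("iteration", "best_fitness", "mean_fitness")])
  expect_identical(a$final_include, b$final_include)
  d1 <- run_de(prob, de_config(pop_size = 20, generations = 15, seed = 4))
  d2 <- run_de(prob, de_config(pop_size = 20, generations = 15, seed = 4))
  expect_identical(d1$trace$best_fitness, d2$trace$best_fitness)
  p1 <- run_pso(prob, pso_config(swarm_size = 15, iterations = 20, seed = 4))
  p2 <- run_pso(prob, pso_config(swarm_size = 15, iterations = 20, seed = 4))
  expect_identical(p1$trace$best_fitness, p2$trace$best_fitness)
  s1 <- run_sa(prob, sa_config(total_iterations = 200, seed = 4))
  s2 <- run_sa(prob, sa_config(total_iterations = 200, seed = 4))
  expect_identical(s1$trace$best_fitness, s2$trace$best_fitness)
})

test_that("elitist and greedy best-fitness series are non-decreasing; SA best-so-far too", {
  prob <- make_random_problem(32, N = 12, k = 3)
  for (s in 1:3) {
    g <- run_ga(prob, ga_config(pop_size = 30, generations = 20, seed = s))
    expect_true(all(diff(g$trace$best_fitness) >= 0))
    d <- run_de(prob, de_config(pop_size = 20, generations = 20, seed = s))
    expect_true(all(diff(d$trace$best_fitness) >= 0))
    p <- run_pso(prob, pso_config(swarm_size = 15, iterations = 20, seed = s))
    expect_true(all(diff(p$trace$best_fitness) >= 0))
    a <- run_sa(prob, sa_config(total_iterations = 300, seed = s))
    expect_true(all(diff(a$trace$best_fitness) >= 0))
  }
})

test_that("every evaluated solution is feasible under randomized configs", {
  # the problem object hard-errors on infeasible subsets, so a clean run is
  # itself the proof; configs are randomized to stress the operators
  set.seed(77)
  for (r in 1:3) {
    prob <- make_random_problem(40 + r, N = sample(8:14, 1), k = sample(2:5, 1))
    expect_no_error(run_ga(prob, ga_config(pop_size = sample(10:40, 1),
                                           generations = 10,
                                           crossover_rate = runif(1),
                                           mutation_rate = runif(1, 0, 0.5),
                                           seed = r)))
    expect_no_error(run_de(prob, de_config(pop_size = sample(10:40, 1),
                                           generations = 10,
                                           F = runif(1, 0.2, 0.9),
                                           CR = runif(1, 0.1, 0.95), seed = r)))
    expect_no_error(run_pso(prob, pso_config(swarm_size = sample(10:30, 1),
                                             iterations = 10, seed = r)))
    expect_no_error(run_sa(prob, sa_config(total_iterations = 100, seed = r)))
  }
})

test_that("the trace object carries evaluation counts and selected identifiers", {
  prob <- make_random_problem(50, N = 10, k = 3)
  tr <- run_ga(prob, ga_config(pop_size = 12, generations = 5, seed = 1))
  expect_s3_class(tr, "gb_trace")
  expect_identical(sum(tr$final_include), 3L)
  expect_length(tr$final_ids, 3L)
  expect_gte(tr$n_evals, 12L)
  expect_identical(nrow(tr$trace), 6L)  # initial population plus 5 generations
  expect_equal(tr$final_fitness, ohs_fitness(prob, tr$final_include))
  # dispatcher honours a seed override
  tr2 <- select_founders(prob, "sa", sa_config(total_iterations = 50), seed = 3)
  expect_identical(tr2$config$seed, 3L)
})
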