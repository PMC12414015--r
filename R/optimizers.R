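# Four seeded, cardinality-constrained metaheuristics over founder subsets:
# genetic algorithm, differential evolution on random keys, binary particle
# swarm with feasibility repair, and simulated annealing. All share the
# convergence-trace output and a single per-run RNG stream (set.seed at entry;
# every stochastic draw consumes that stream in a fixed, documented order).

#' Optimizer configurations
#'
#' Constructors for the four algorithm configurations, with defaults matching
#' the tuned settings this package ships (GA: population 200, 250 generations,
#' crossover 0.8, swap-mutation 0.1, tournament size 3, 10% elitism,
#' stagnation restart after 3 flat generations replacing the worst 50%;
#' DE: population 200, 250 generations, F = 0.4, CR = 0.8, +/-10% jitter,
#' adaptive strategy pool; PSO: 100 particles, 100 iterations, c1 = 1.5,
#' c2 = 2.0, inertia decaying linearly 0.5 -> 0.3; SA: initial temperature
#' 0.01, geometric cooling 0.96, 1000 total iterations).
#'
#' @param pop_size,generations population size and generation count.
#' @param crossover_rate,mutation_rate,tournament_size,elitism_fraction GA
#'   operator parameters.
#' @param stagnation_generations,stagnation_replace_fraction GA restart rule:
#'   after this many generations without best-fitness improvement, this
#'   fraction of the population (the worst part; elites kept) is replaced by
#'   fresh random feasible solutions.
#' @param seed integer RNG seed for the run.
#' @return A classed configuration list.
#' @export
#' @name optimizer_configs
ga_config <- function(pop_size = 200L, generations = 250L, crossover_rate = 0.8,
                      mutation_rate = 0.1, tournament_size = 3L,
                      elitism_fraction = 0.1, stagnation_generations = 3L,
                      stagnation_replace_fraction = 0.5, seed = 1L) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size >= 2, elitism_fraction * pop_size >= 1,
            stagnation_replace_fraction >= 0, stagnation_replace_fraction <= 1)
  structure(list(pop_size = as.integer(pop_size), generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism_fraction = elitism_fraction,
                 stagnation_generations = as.integer(stagnation_generations),
                 stagnation_replace_fraction = stagnation_replace_fraction,
                 seed = as.integer(seed)),
            class = c("ga_config", "gb_config"))
}

#' @rdname optimizer_configs
#' @param F,CR differential-evolution scale factor and crossover probability.
#' @param jitter_fraction multiplicative uniform jitter (+/- this fraction)
#'   applied to F and CR per individual per generation.
#' @param strategy_pool subset of `c("rand/1/bin", "best/1/bin",
#'   "current-to-best/1/bin")`; one is drawn uniformly per individual per
#'   generation.
#' @export
de_config <- function(pop_size = 200L, generations = 250L, F = 0.4, CR = 0.8,
                      jitter_fraction = 0.1,
                      strategy_pool = c("rand/1/bin", "best/1/bin",
                                        "current-to-best/1/bin"),
                      seed = 1L) {
  stopifnot(F > 0, CR >= 0, CR <= 1, length(strategy_pool) >= 1)
  ok <- c("rand/1/bin", "best/1/bin", "current-to-best/1/bin")
  if (!all(strategy_pool %in% ok)) stop("unknown DE strategy")
  structure(list(pop_size = as.integer(pop_size), generations = as.integer(generations),
                 F = F, CR = CR, jitter_fraction = jitter_fraction,
                 strategy_pool = strategy_pool, seed = as.integer(seed)),
            class = c("de_config", "gb_config"))
}

#' @rdname optimizer_configs
#' @param swarm_size,iterations swarm size and iteration count.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param w_start,w_end inertia weight, decaying linearly over iterations.
#' @export
pso_config <- function(swarm_size = 100L, iterations = 100L, c1 = 1.5, c2 = 2.0,
                       w_start = 0.5, w_end = 0.3, seed = 1L) {
  stopifnot(c1 > 0, c2 > 0, w_start >= w_end, w_end >= 0)
  structure(list(swarm_size = as.integer(swarm_size), iterations = as.integer(iterations),
                 c1 = c1, c2 = c2, w_start = w_start, w_end = w_end,
                 seed = as.integer(seed)),
            class = c("pso_config", "gb_config"))
}

#' @rdname optimizer_configs
#' @param initial_temp,cooling_rate Metropolis temperature schedule
#'   `T_k = initial_temp * cooling_rate^k`.
#' @param iterations_per_temp Markov-chain length at each temperature.
#' @param total_iterations total step budget.
#' @param max_temps optional cap on the number of temperature levels; the walk
#'   stops at `min(total_iterations, max_temps * iterations_per_temp)` steps.
#' @export
sa_config <- function(initial_temp = 0.01, cooling_rate = 0.96,
                      iterations_per_temp = 10L, total_iterations = 1000L,
                      max_temps = NULL, seed = 1L) {
  stopifnot(initial_temp > 0, cooling_rate > 0, cooling_rate < 1,
            iterations_per_temp >= 1, total_iterations >= 1)
  structure(list(initial_temp = initial_temp, cooling_rate = cooling_rate,
                 iterations_per_temp = as.integer(iterations_per_temp),
                 total_iterations = as.integer(total_iterations),
                 max_temps = if (is.null(max_temps)) NULL else as.integer(max_temps),
                 seed = as.integer(seed)),
            class = c("sa_config", "gb_config"))
}

#' Uniformly random feasible subset
#'
#' @param N panel size.
#' @param k subset size, `1 <= k <= N`.
#' @return Logical inclusion vector with exactly `k` `TRUE`s.
#' @export
random_feasible_solution <- function(N, k) {
  if (k < 1L || k > N) stop("parameter error: need 1 <= k <= N")
  inc <- rep(FALSE, N)
  inc[sample.int(N, k)] <- TRUE
  inc
}

#' Repair an inclusion vector to exactly k selections
#'
#' While more than `k` items are selected, the selected index with the lowest
#' priority is dropped; while fewer, the unselected index with the highest
#' priority is added. Ties break to the lowest index, so the repair is
#' deterministic given the priority vector.
#'
#' @param include logical (or 0/1) inclusion vector.
#' @param k target cardinality.
#' @param priority numeric priority vector, same length as `include`.
#' @return Logical inclusion vector with exactly `k` `TRUE`s.
#' @export
repair_to_k <- function(include, k, priority) {
  include <- as.logical(include)
  N <- length(include)
  if (length(priority) != N) stop("priority must have length N")
  s <- sum(include)
  if (s > k) {
    sel <- which(include)
    drop_n <- s - k
    ord <- sel[order(priority[sel], sel)]
    include[ord[seq_len(drop_n)]] <- FALSE
  } else if (s < k) {
    uns <- which(!include)
    add_n <- k - s
    ord <- uns[order(-priority[uns], uns)]
    include[ord[seq_len(add_n)]] <- TRUE
  }
  include
}

#' Tournament selection
#'
#' Samples `size` population members with replacement and returns the index of
#' the fittest sampled member (ties break to the lowest population index).
#'
#' @param fitness numeric vector of population fitnesses.
#' @param size tournament size.
#' @return Index of the winner.
#' @export
tournament_select <- function(fitness, size) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  cand <- sort(unique(cand))
  cand[which.max(fitness[cand])]
}

#' One-point crossover with cardinality repair
#'
#' Splices two parent inclusion vectors at a uniform cut point in `1..N-1` and
#' repairs both children back to exactly `k` selections using a fresh
#' uniform-random priority vector per child.
#'
#' @param p1,p2 feasible parent inclusion vectors (equal length).
#' @param k target cardinality.
#' @return List of two feasible children.
#' @export
one_point_crossover_with_repair <- function(p1, p2, k) {
  N <- length(p1)
  cut <- sample.int(N - 1L, 1L)
  c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):N])
  c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):N])
  list(repair_to_k(c1, k, stats::runif(N)),
       repair_to_k(c2, k, stats::runif(N)))
}

#' Cardinality-preserving swap mutation
#'
#' Each selected index is, independently with probability `rate`, swapped with
#' a uniformly chosen currently-unselected index; the number of selections is
#' unchanged. With `k = N` there is nothing to swap with and the input is
#' returned unchanged.
#'
#' @param include feasible inclusion vector.
#' @param rate per-selected-index swap probability.
#' @return Mutated feasible inclusion vector.
#' @export
swap_mutation <- function(include, rate) {
  sel <- which(include)
  if (length(sel) == length(include) || rate <= 0) return(include)
  hits <- sel[stats::runif(length(sel)) < rate]
  for (i in hits) {
    uns <- which(!include)
    j <- uns[sample.int(length(uns), 1L)]
    include[i] <- FALSE
    include[j] <- TRUE
  }
  include
}

# Shared trace assembly -------------------------------------------------------

new_trace <- function(df, algorithm, config, final_include, final_fitness,
                      n_evals, problem) {
  structure(list(trace = df, algorithm = algorithm, config = config,
                 final_include = final_include,
                 final_ids = problem$tensor$individual_id[which(final_include)],
                 final_fitness = final_fitness, n_evals = n_evals),
            class = "gb_trace")
}

#' @export
print.gb_trace <- function(x, ...) {
  cat(sprintf("gb_trace [%s]: %d iterations, final fitness %.6g (%d evaluations)\n",
              toupper(x$algorithm), nrow(x$trace), x$final_fitness, x$n_evals))
  cat("selected:", paste(x$final_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gb_trace <- function(object, ...) {
  nt <- normalize_trace(object)
  cat(sprintf("%s run: final fitness %.6g after %d iterations; convergence AUC %.4f\n",
              toupper(object$algorithm), object$final_fitness,
              nrow(object$trace), convergence_auc(nt)))
  invisible(object)
}

#' @export
plot.gb_trace <- function(x, ...) {
  graphics::plot(x$trace$iteration, cummax(x$trace$best_fitness), type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = paste(toupper(x$algorithm), "convergence"), ...)
  graphics::lines(x$trace$iteration, x$trace$mean_fitness, lty = 3)
  invisible(x)
}

# Genetic algorithm ------------------------------------------------------------

#' Run the genetic algorithm
#'
#' Generational GA over binary inclusion chromosomes with strict cardinality:
#' tournament parent selection, one-point crossover with repair, swap mutation,
#' elitism (top fraction copied unchanged, so the best fitness is
#' non-decreasing), and a stagnation restart that replaces the worst part of
#' the population with fresh random feasible solutions after a run of flat
#' generations.
#'
#' @param problem a [selection_problem()].
#' @param cfg a [ga_config()].
#' @return A `gb_trace` (per-generation best/mean fitness, elapsed seconds,
#'   final solution).
#' @export
run_ga <- function(problem, cfg = ga_config()) {
  stopifnot(inherits(cfg, "ga_config"))
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  N <- problem$N; k <- problem$k
  n_evals <- 0L
  evalf <- function(inc) {
    check_feasible(problem, inc)
    n_evals <<- n_evals + 1L
    evaluate_fitness(problem, inc)
  }
  pop <- lapply(seq_len(cfg$pop_size), function(i) random_feasible_solution(N, k))
  fit <- vapply(pop, evalf, 0)
  n_elite <- ceiling(cfg$elitism_fraction * cfg$pop_size)
  trace <- vector("list", cfg$generations + 1L)
  record <- function(gen) data.frame(iteration = gen, best_fitness = max(fit),
                                     mean_fitness = mean(fit),
                                     elapsed_seconds = proc.time()[["elapsed"]] - t0)
  trace[[1L]] <- record(0L)
  stagnant <- 0L
  best_prev <- max(fit)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(-fit, seq_along(fit))
    elite_idx <- ord[seq_len(n_elite)]
    newpop <- pop[elite_idx]
    newfit <- fit[elite_idx]
    while (length(newpop) < cfg$pop_size) {
      i1 <- tournament_select(fit, cfg$tournament_size)
      i2 <- tournament_select(fit, cfg$tournament_size)
      if (stats::runif(1) < cfg$crossover_rate) {
        kids <- one_point_crossover_with_repair(pop[[i1]], pop[[i2]], k)
      } else {
        kids <- list(pop[[i1]], pop[[i2]])
      }
      for (kid in kids) {
        if (length(newpop) >= cfg$pop_size) break
        kid <- swap_mutation(kid, cfg$mutation_rate)
        newpop[[length(newpop) + 1L]] <- kid
        newfit <- c(newfit, evalf(kid))
      }
    }
    pop <- newpop
    fit <- newfit
    best_now <- max(fit)
    if (best_now > best_prev + 1e-12) {
      stagnant <- 0L
      best_prev <- best_now
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= cfg$stagnation_generations) {
        n_replace <- floor(cfg$stagnation_replace_fraction * cfg$pop_size)
        worst <- order(fit, -seq_along(fit))[seq_len(n_replace)]
        worst <- setdiff(worst, order(-fit, seq_along(fit))[seq_len(n_elite)])
        for (w in worst) {
          pop[[w]] <- random_feasible_solution(N, k)
          fit[w] <- evalf(pop[[w]])
        }
        stagnant <- 0L
      }
    }
    trace[[gen + 1L]] <- record(gen)
  }
  ibest <- which.max(fit)
  new_trace(do.call(rbind, trace), "ga", cfg, pop[[ibest]], fit[ibest],
            n_evals, problem)
}

# Differential evolution -------------------------------------------------------

#' Decode a real key vector to a feasible subset
#'
#' Selects the indices of the `k` largest keys; ties break to the lowest
#' index, so decoding is deterministic.
#'
#' @param keys numeric vector.
#' @param k subset size.
#' @return Logical inclusion vector.
#' @export
topk_decode <- function(keys, k) {
  if (k > length(keys)) stop("k exceeds key length")
  inc <- rep(FALSE, length(keys))
  inc[order(-keys, seq_along(keys))[seq_len(k)]] <- TRUE
  inc
}

#' Differential-evolution mutation step
#'
#' Builds the mutant key vector for one target under the named strategy, with
#' donor indices distinct from each other and from the target; the result is
#' clipped to `[0, 1]`.
#'
#' @param keys population key matrix (rows = members).
#' @param target_idx row index of the target.
#' @param best_idx row index of the current best member.
#' @param strategy one of `"rand/1/bin"`, `"best/1/bin"`,
#'   `"current-to-best/1/bin"`.
#' @param F_effective effective scale factor for this step.
#' @return Mutant key vector in `[0, 1]`.
#' @export
de_mutation <- function(keys, target_idx, best_idx, strategy, F_effective) {
  np <- nrow(keys)
  need <- if (strategy == "rand/1/bin") 3L else 2L
  if (np < need + 1L) stop("config error: DE population too small for ", strategy)
  pool <- setdiff(seq_len(np), target_idx)
  r <- pool[sample.int(length(pool), need)]
  v <- switch(strategy,
    "rand/1/bin" = keys[r[1], ] + F_effective * (keys[r[2], ] - keys[r[3], ]),
    "best/1/bin" = keys[best_idx, ] + F_effective * (keys[r[1], ] - keys[r[2], ]),
    "current-to-best/1/bin" =
      keys[target_idx, ] + F_effective * (keys[best_idx, ] - keys[target_idx, ]) +
      F_effective * (keys[r[1], ] - keys[r[2], ]))
  pmin(1, pmax(0, v))
}

#' Run differential evolution over random keys
#'
#' Members are continuous priority-key vectors in `[0, 1]^N` decoded to
#' subsets by [topk_decode()], so every evaluated solution is feasible by
#' construction. Per member and generation: a strategy is drawn uniformly from
#' the pool, F and CR receive multiplicative +/- jitter, binomial crossover
#' keeps at least one mutant coordinate, and greedy replacement (ties keep the
#' trial) makes each slot's fitness — and hence the population best —
#' non-decreasing.
#'
#' @param problem a [selection_problem()].
#' @param cfg a [de_config()].
#' @return A `gb_trace`.
#' @export
run_de <- function(problem, cfg = de_config()) {
  stopifnot(inherits(cfg, "de_config"))
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  N <- problem$N; k <- problem$k; np <- cfg$pop_size
  n_evals <- 0L
  evalf <- function(inc) {
    check_feasible(problem, inc)
    n_evals <<- n_evals + 1L
    evaluate_fitness(problem, inc)
  }
  keys <- matrix(stats::runif(np * N), np, N)
  fit <- vapply(seq_len(np), function(i) evalf(topk_decode(keys[i, ], k)), 0)
  trace <- vector("list", cfg$generations + 1L)
  record <- function(gen) data.frame(iteration = gen, best_fitness = max(fit),
                                     mean_fitness = mean(fit),
                                     elapsed_seconds = proc.time()[["elapsed"]] - t0)
  trace[[1L]] <- record(0L)
  for (gen in seq_len(cfg$generations)) {
    for (i in seq_len(np)) {
      best_idx <- which.max(fit)
      strat <- cfg$strategy_pool[sample.int(length(cfg$strategy_pool), 1L)]
      Fe <- cfg$F * (1 + stats::runif(1, -cfg$jitter_fraction, cfg$jitter_fraction))
      CRe <- cfg$CR * (1 + stats::runif(1, -cfg$jitter_fraction, cfg$jitter_fraction))
      CRe <- min(1, max(1e-12, CRe))
      mutant <- de_mutation(keys, i, best_idx, strat, Fe)
      jrand <- sample.int(N, 1L)
      mask <- stats::runif(N) < CRe
      mask[jrand] <- TRUE
      trial <- ifelse(mask, mutant, keys[i, ])
      tf <- evalf(topk_decode(trial, k))
      if (tf >= fit[i]) {
        keys[i, ] <- trial
        fit[i] <- tf
      }
    }
    trace[[gen + 1L]] <- record(gen)
  }
  ibest <- which.max(fit)
  new_trace(do.call(rbind, trace), "de", cfg, topk_decode(keys[ibest, ], k),
            fit[ibest], n_evals, problem)
}

# Particle swarm ---------------------------------------------------------------

#' Particle-swarm velocity update
#'
#' Componentwise `w*v + c1*r1*(p - x) + c2*r2*(g - x)` with fresh uniform
#' `r1`, `r2` scalars drawn per component.
#'
#' @param v,x,p_best,g_best velocity, position, personal-best and global-best
#'   vectors of equal length.
#' @param w,c1,c2 inertia, cognitive and social coefficients.
#' @return Updated velocity vector.
#' @export
pso_velocity_update <- function(v, x, p_best, g_best, w, c1, c2) {
  n <- length(v)
  stopifnot(length(x) == n, length(p_best) == n, length(g_best) == n)
  r1 <- stats::runif(n)
  r2 <- stats::runif(n)
  w * v + c1 * r1 * (p_best - x) + c2 * r2 * (g_best - x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Run binary particle swarm optimisation with feasibility repair
#'
#' Positions are binary inclusion vectors; velocities are real and updated by
#' the standard rule against the binary positions. The provisional position is
#' sampled componentwise as `Bernoulli(sigmoid(v))` and then repaired to
#' exactly `k` selections with priority `sigmoid(v)`, so every evaluated
#' particle is feasible; personal and global bests are updated only from these
#' post-repair evaluations. Inertia decays linearly from `w_start` to `w_end`.
#'
#' @param problem a [selection_problem()].
#' @param cfg a [pso_config()].
#' @return A `gb_trace` (best-so-far series is non-decreasing).
#' @export
run_pso <- function(problem, cfg = pso_config()) {
  stopifnot(inherits(cfg, "pso_config"))
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  N <- problem$N; k <- problem$k; ns <- cfg$swarm_size
  n_evals <- 0L
  evalf <- function(inc) {
    check_feasible(problem, inc)
    n_evals <<- n_evals + 1L
    evaluate_fitness(problem, inc)
  }
  X <- t(vapply(seq_len(ns), function(i) random_feasible_solution(N, k),
                logical(N)))
  V <- matrix(0, ns, N)
  fit <- vapply(seq_len(ns), function(i) evalf(X[i, ]), 0)
  P <- X
  pfit <- fit
  gi <- which.max(pfit)
  G <- P[gi, ]
  gfit <- pfit[gi]
  trace <- vector("list", cfg$iterations + 1L)
  record <- function(it) data.frame(iteration = it, best_fitness = gfit,
                                    mean_fitness = mean(fit),
                                    elapsed_seconds = proc.time()[["elapsed"]] - t0)
  trace[[1L]] <- record(0L)
  for (it in seq_len(cfg$iterations)) {
    w <- if (cfg$iterations > 1L)
      cfg$w_start + (cfg$w_end - cfg$w_start) * (it - 1L) / (cfg$iterations - 1L)
    else cfg$w_start
    for (i in seq_len(ns)) {
      V[i, ] <- pso_velocity_update(V[i, ], as.numeric(X[i, ]),
                                    as.numeric(P[i, ]), as.numeric(G),
                                    w, cfg$c1, cfg$c2)
      prob <- sigmoid(V[i, ])
      prov <- stats::runif(N) < prob
      X[i, ] <- repair_to_k(prov, k, prob)
      fit[i] <- evalf(X[i, ])
      if (fit[i] > pfit[i]) {
        pfit[i] <- fit[i]
        P[i, ] <- X[i, ]
      }
      if (fit[i] > gfit) {
        gfit <- fit[i]
        G <- X[i, ]
      }
    }
    trace[[it + 1L]] <- record(it)
  }
  new_trace(do.call(rbind, trace), "pso", cfg, as.logical(G), gfit,
            n_evals, problem)
}

# Simulated annealing ----------------------------------------------------------

#' Metropolis acceptance probability
#'
#' 1 when the neighbour is at least as fit; otherwise
#' `exp((neighbor - current) / temp)`.
#'
#' @param current,neighbor fitness of the current and neighbouring solutions.
#' @param temp temperature, strictly positive.
#' @return Acceptance probability in `(0, 1]`.
#' @export
sa_accept_probability <- function(current, neighbor, temp) {
  if (temp <= 0) stop("parameter error: temperature must be > 0")
  if (neighbor >= current) 1 else exp((neighbor - current) / temp)
}

#' Run simulated annealing
#'
#' Single-solution walk over feasible subsets: each step swaps one uniformly
#' chosen selected index with one uniformly chosen unselected index (the
#' minimal cardinality-preserving move), accepts by the Metropolis criterion,
#' and cools geometrically, `T_j = initial_temp * cooling_rate^j`, after every
#' `iterations_per_temp` steps. The best solution seen is tracked at every
#' step.
#'
#' @param problem a [selection_problem()].
#' @param cfg a [sa_config()].
#' @return A `gb_trace` whose `best_fitness` column is the best-so-far series.
#' @export
run_sa <- function(problem, cfg = sa_config()) {
  stopifnot(inherits(cfg, "sa_config"))
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  N <- problem$N; k <- problem$k
  n_evals <- 0L
  evalf <- function(inc) {
    check_feasible(problem, inc)
    n_evals <<- n_evals + 1L
    evaluate_fitness(problem, inc)
  }
  total <- cfg$total_iterations
  if (!is.null(cfg$max_temps))
    total <- min(total, cfg$max_temps * cfg$iterations_per_temp)
  cur <- random_feasible_solution(N, k)
  cur_fit <- evalf(cur)
  best <- cur
  best_fit <- cur_fit
  trace <- vector("list", total)
  for (s in seq_len(total)) {
    temp <- cfg$initial_temp * cfg$cooling_rate^((s - 1L) %/% cfg$iterations_per_temp)
    nb <- cur
    if (k < N) {
      sel <- which(nb)
      uns <- which(!nb)
      i <- sel[sample.int(length(sel), 1L)]
      j <- uns[sample.int(length(uns), 1L)]
      nb[i] <- FALSE
      nb[j] <- TRUE
    }
    nb_fit <- evalf(nb)
    p <- sa_accept_probability(cur_fit, nb_fit, temp)
    if (nb_fit >= cur_fit || stats::runif(1) < p) {
      cur <- nb
      cur_fit <- nb_fit
    }
    if (cur_fit > best_fit) {
      best <- cur
      best_fit <- cur_fit
    }
    trace[[s]] <- data.frame(iteration = s, best_fitness = best_fit,
                             mean_fitness = cur_fit,
                             elapsed_seconds = proc.time()[["elapsed"]] - t0)
  }
  new_trace(do.call(rbind, trace), "sa", cfg, best, best_fit, n_evals, problem)
}

#' Select founder parents with a chosen metaheuristic
#'
#' Thin dispatcher over [run_ga()], [run_de()], [run_pso()] and [run_sa()].
#'
#' @param problem a [selection_problem()].
#' @param algorithm one of `"ga"`, `"de"`, `"pso"`, `"sa"`.
#' @param config matching configuration object; defaults to the algorithm's
#'   default configuration.
#' @param seed optional seed overriding the configuration's.
#' @return A `gb_trace`.
#' @export
select_founders <- function(problem, algorithm = c("ga", "de", "pso", "sa"),
                            config = NULL, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(config))
    config <- switch(algorithm, ga = ga_config(), de = de_config(),
                     pso = pso_config(), sa = sa_config())
  if (!is.null(seed)) config$seed <- as.integer(seed)
  switch(algorithm,
         ga = run_ga(problem, config),
         de = run_de(problem, config),
         pso = run_pso(problem, config),
         sa = run_sa(problem, config))
}
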