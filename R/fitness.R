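# Group-fitness functions over a candidate founder subset, and an exhaustive
# enumeration oracle. All fitness functions maximise; effects are assumed to be
# on the desirability scale already.

#' Define a founder-selection problem
#'
#' Packages a block-value tensor with the subset size `k` and the group-fitness
#' criterion, precomputing the flat per-copy value/identity matrices used by
#' the fast evaluators.
#'
#' Criteria:
#' * `ohs` (Optimal Haplotype Selection): per block, the sum of the two best
#'   *distinct* haplotype values present among the selected individuals' `2k`
#'   copies; a block with a single distinct variant contributes its value twice
#'   (the ultimate genotype is homozygous there). Distinctness is by variant
#'   identity (`distinct_by = "variant"`, default) or by donor individual
#'   (`distinct_by = "individual"`, i.e. each individual contributes its best
#'   copy and the two best individuals count).
#' * `opv` (Optimal Population Value): twice the value of the ideal gamete
#'   assembled block-wise from the subset (per-block maximum over all selected
#'   copies; `opv_variant = "whole_genome"` instead doubles the best single
#'   haploid genome, the literal one-max reading).
#' * `gebv_sum`: sum over selected individuals of their total (two-copy,
#'   all-block) value; maximised exactly by top-k truncation.
#'
#' @param tensor a [block_value_tensor()].
#' @param k subset size (number of founder parents to select).
#' @param fitness `"ohs"`, `"opv"` or `"gebv_sum"`.
#' @param distinct_by OHS distinctness rule, `"variant"` or `"individual"`.
#' @param opv_variant `"per_block"` (default) or `"whole_genome"`.
#' @return A list of class `gb_problem`.
#' @export
selection_problem <- function(tensor, k,
                              fitness = c("ohs", "opv", "gebv_sum"),
                              distinct_by = c("variant", "individual"),
                              opv_variant = c("per_block", "whole_genome")) {
  stopifnot(inherits(tensor, "block_value_tensor"))
  fitness <- match.arg(fitness)
  distinct_by <- match.arg(distinct_by)
  opv_variant <- match.arg(opv_variant)
  d <- dim(tensor$values)
  B <- d[1]; N <- d[2]
  k <- as.integer(k)
  if (k < 1L || k > N) stop("k must satisfy 1 <= k <= N")
  # flatten copies: column 2i-1 is individual i's copy 1, column 2i its copy 2
  V <- matrix(0, B, 2L * N)
  ID <- matrix(0L, B, 2L * N)
  for (m in 1:2) V[, seq(m, 2L * N, by = 2L)] <- tensor$values[, , m]
  if (distinct_by == "individual") {
    ID <- matrix(rep(seq_len(N), each = 2L), B, 2L * N, byrow = TRUE)
  } else {
    for (b in seq_len(B)) {
      vid <- character(2L * N)
      for (m in 1:2) vid[seq(m, 2L * N, by = 2L)] <- tensor$variants[b, , m]
      ID[b, ] <- match(vid, unique(vid))
    }
  }
  ind_total <- as.numeric(colSums(matrix(tensor$values[, , 1], B, N)) +
                            colSums(matrix(tensor$values[, , 2], B, N)))
  copy_total <- colSums(V)
  structure(list(tensor = tensor, k = k, fitness = fitness,
                 distinct_by = distinct_by, opv_variant = opv_variant,
                 N = N, B = B, V = V, ID = ID,
                 ind_total = ind_total, copy_total = copy_total),
            class = "gb_problem")
}

#' @export
print.gb_problem <- function(x, ...) {
  cat(sprintf("gb_problem: select k = %d of N = %d individuals, %s fitness over %d blocks\n",
              x$k, x$N, toupper(x$fitness), x$B))
  invisible(x)
}

as_include <- function(problem, subset) {
  if (is.logical(subset)) {
    if (length(subset) != problem$N) stop("include vector has wrong length")
    return(subset)
  }
  inc <- rep(FALSE, problem$N)
  inc[as.integer(subset)] <- TRUE
  inc
}

check_feasible <- function(problem, include) {
  if (sum(include) != problem$k)
    stop("constraint error: subset must select exactly k = ", problem$k,
         " individuals (got ", sum(include), ")")
  invisible(TRUE)
}

copy_cols <- function(sel_idx) as.vector(rbind(2L * sel_idx - 1L, 2L * sel_idx))

eval_ohs <- function(problem, sel_idx) {
  cols <- copy_cols(sel_idx)
  Vs <- problem$V[, cols, drop = FALSE]
  Is <- problem$ID[, cols, drop = FALSE]
  B <- nrow(Vs)
  j1 <- max.col(Vs, ties.method = "first")
  rows <- seq_len(B)
  m1 <- Vs[cbind(rows, j1)]
  i1 <- Is[cbind(rows, j1)]
  mask <- Is == matrix(i1, B, ncol(Is))
  Vs[mask] <- -Inf
  j2 <- max.col(Vs, ties.method = "first")
  m2 <- Vs[cbind(rows, j2)]
  m2[!is.finite(m2)] <- m1[!is.finite(m2)]  # single distinct variant: doubled
  sum(m1 + m2)
}

eval_opv <- function(problem, sel_idx) {
  cols <- copy_cols(sel_idx)
  if (problem$opv_variant == "whole_genome")
    return(2 * max(problem$copy_total[cols]))
  Vs <- problem$V[, cols, drop = FALSE]
  j <- max.col(Vs, ties.method = "first")
  2 * sum(Vs[cbind(seq_len(nrow(Vs)), j)])
}

#' Evaluate a subset's group fitness
#'
#' @param problem a [selection_problem()].
#' @param subset logical inclusion vector of length N, or an integer vector of
#'   selected indices; must select exactly `k` individuals.
#' @return Scalar fitness (to be maximised).
#' @export
evaluate_fitness <- function(problem, subset) {
  include <- as_include(problem, subset)
  check_feasible(problem, include)
  sel_idx <- which(include)
  switch(problem$fitness,
         ohs = eval_ohs(problem, sel_idx),
         opv = eval_opv(problem, sel_idx),
         gebv_sum = sum(problem$ind_total[sel_idx]))
}

#' Optimal Haplotype Selection group fitness
#'
#' Sum over blocks of the two best distinct haplotype values present in the
#' subset (see [selection_problem()] for the distinctness rule and the
#' single-variant fallback).
#'
#' @inheritParams evaluate_fitness
#' @export
ohs_fitness <- function(problem, subset) {
  include <- as_include(problem, subset)
  check_feasible(problem, include)
  eval_ohs(problem, which(include))
}

#' Optimal Population Value group fitness
#'
#' Twice the block-wise maximum haplotype value over the subset — the doubled
#' value of the ideal gamete obtainable under unrestricted recombination.
#'
#' @inheritParams evaluate_fitness
#' @export
opv_fitness <- function(problem, subset) {
  include <- as_include(problem, subset)
  check_feasible(problem, include)
  eval_opv(problem, which(include))
}

#' Summed-GEBV group fitness (truncation baseline)
#'
#' Sum over the selected individuals of their total two-copy, all-block value;
#' its exact maximiser is top-k truncation on per-individual totals.
#'
#' @inheritParams evaluate_fitness
#' @export
gebv_sum_fitness <- function(problem, subset) {
  include <- as_include(problem, subset)
  check_feasible(problem, include)
  sum(problem$ind_total[which(include)])
}

#' Exhaustive enumeration oracle
#'
#' Enumerates all `choose(N, k)` subsets (in lexicographic order) and returns
#' the maximum fitness together with every tied argmax subset. Refuses
#' instances beyond `cap` subsets.
#'
#' @param problem a [selection_problem()].
#' @param cap maximum number of subsets to enumerate (default 2e6).
#' @return List with `best_fitness` and `argmax` (list of integer index
#'   vectors, lexicographic order).
#' @export
brute_force_optimum <- function(problem, cap = 2e6) {
  n_sub <- choose(problem$N, problem$k)
  if (n_sub > cap) stop("refusal: choose(N, k) = ", n_sub, " exceeds cap ", cap)
  evalf <- switch(problem$fitness,
                  ohs = function(s) eval_ohs(problem, s),
                  opv = function(s) eval_opv(problem, s),
                  gebv_sum = function(s) sum(problem$ind_total[s]))
  best <- -Inf
  argmax <- list()
  combs <- utils::combn(problem$N, problem$k)
  for (ci in seq_len(ncol(combs))) {
    s <- combs[, ci]
    f <- evalf(s)
    if (f > best + 1e-12) {
      best <- f
      argmax <- list(s)
    } else if (abs(f - best) <= 1e-12) {
      argmax <- c(argmax, list(s))
    }
  }
  list(best_fitness = best, argmax = argmax)
}

#' Order of magnitude of the founder-subset search space
#'
#' `log10(choose(n, k))` computed with log-gamma, exact far beyond double
#' overflow. Selecting 50 founders from a panel of 583 lines, for instance,
#' gives about `10^72.9` possible subsets.
#'
#' @param n panel size.
#' @param k subset size.
#' @return `log10` of the number of k-subsets of n items.
#' @export
log10_combinations <- function(n, k) lchoose(n, k) / log(10)
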