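# Shared fixtures and independent reference implementations used as oracles.

# Build a panel directly from a list of per-individual 2 x M matrices.
panel_from_copies <- function(copies, map = NULL, ids = NULL) {
  N <- length(copies)
  M <- ncol(copies[[1]])
  alleles <- array(0L, dim = c(N, 2L, M))
  for (i in seq_len(N)) alleles[i, , ] <- copies[[i]]
  if (is.null(map)) map <- marker_map(paste0("m", 1:M), rep("1", M), (1:M) * 1e6)
  if (is.null(ids)) ids <- paste0("ind", 1:N)
  haplotype_panel(ids, alleles, map)
}

# Inbred panel with prescribed dosage matrix (entries 0/2).
panel_from_dosage <- function(D, map = NULL) {
  copies <- lapply(seq_len(nrow(D)), function(i) {
    h <- as.integer(D[i, ] / 2)
    rbind(h, h)
  })
  panel_from_copies(copies, map)
}

# Random small selection instance built through the full pipeline.
make_random_problem <- function(seed, N = 12, k = 3, kind = "ohs",
                                markers = 30, block_length = 5) {
  panel <- simulate_panel(N, markers_per_chrom = markers,
                          block_length = block_length, seed = seed * 7 + 1)
  sim <- simulate_effects_phenotypes(panel, h2 = 0.8, seed = seed * 7 + 2)
  blk <- build_blocks(panel)
  tens <- catalog_block_values(panel, blk, sim$effects)
  selection_problem(tens, k, kind)
}

# --- Independent reference fitness implementations -----------------------
# Straight from the tensor arrays, no shared code with the package's fast
# evaluators; deliberately simple and slow.

ref_ohs <- function(tensor, subset, distinct_by = "variant") {
  B <- dim(tensor$values)[1]
  total <- 0
  for (b in seq_len(B)) {
    vals <- c(); ids <- c()
    for (n in subset) for (m in 1:2) {
      vals <- c(vals, tensor$values[b, n, m])
      ids <- c(ids, if (distinct_by == "variant") tensor$variants[b, n, m]
               else as.character(n))
    }
    per_id <- tapply(vals, ids, max)
    top <- sort(per_id, decreasing = TRUE)
    total <- total + if (length(top) >= 2) top[1] + top[2] else 2 * top[1]
  }
  unname(total)
}

ref_opv <- function(tensor, subset) {
  B <- dim(tensor$values)[1]
  2 * sum(vapply(seq_len(B), function(b) max(tensor$values[b, subset, ]), 0))
}

ref_gebv_sum <- function(tensor, subset) {
  sum(tensor$values[, subset, , drop = FALSE])
}

ref_enumerate <- function(tensor, k, fitf, ...) {
  N <- dim(tensor$values)[2]
  best <- -Inf; argmax <- list()
  cmb <- utils::combn(N, k)
  for (ci in seq_len(ncol(cmb))) {
    s <- cmb[, ci]
    f <- fitf(tensor, s, ...)
    if (f > best + 1e-12) { best <- f; argmax <- list(s) }
    else if (abs(f - best) <= 1e-12) argmax <- c(argmax, list(s))
  }
  list(best_fitness = best, argmax = argmax)
}
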