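# Recurrent breeding simulation for comparing founder strategies: half-diallel
# crossing of the parent set, doubled-haploid progeny via simulated meiosis
# (Poisson crossovers, no interference), within-cross and global truncation on
# true genetic values, and per-cycle genetic gain / variance / heterozygosity.

#' Simulation configuration
#'
#' Defaults mirror a closed recurrent programme: 50 parents crossed in a
#' half-diallel (1225 crosses), 50 doubled-haploid progeny per cross of which
#' the 10 best move forward, 15 new parents entering per cycle with 35
#' retained, for 100 cycles and 10 replicates.
#'
#' @param n_parents parent-set size per cycle.
#' @param dh_per_cross doubled-haploid progeny simulated per cross.
#' @param selected_per_cross progeny retained per cross (<= `dh_per_cross`).
#' @param new_parents_per_cycle,retained_parents parent turnover; must sum to
#'   `n_parents`.
#' @param cycles number of recurrent cycles.
#' @param replicates independent simulation replicates.
#' @param cm_per_mb genetic-to-physical scaling used when the map lacks `pos_cm`
#'   (default 1 cM/Mb).
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 50L, dh_per_cross = 50L,
                       selected_per_cross = 10L, new_parents_per_cycle = 15L,
                       retained_parents = 35L, cycles = 100L, replicates = 10L,
                       cm_per_mb = 1.0, seed = 1L) {
  if (new_parents_per_cycle + retained_parents != n_parents)
    stop("new_parents_per_cycle + retained_parents must equal n_parents")
  if (selected_per_cross > dh_per_cross)
    stop("selected_per_cross must be <= dh_per_cross")
  structure(list(n_parents = as.integer(n_parents),
                 dh_per_cross = as.integer(dh_per_cross),
                 selected_per_cross = as.integer(selected_per_cross),
                 new_parents_per_cycle = as.integer(new_parents_per_cycle),
                 retained_parents = as.integer(retained_parents),
                 cycles = as.integer(cycles), replicates = as.integer(replicates),
                 cm_per_mb = cm_per_mb, seed = as.integer(seed)),
            class = "sim_config")
}

#' Half-diallel crossing plan
#'
#' All unordered parent pairs, no selfs, no reciprocals: `n(n-1)/2` crosses in
#' lexicographic order.
#'
#' @param parent_ids vector of parent identifiers (length >= 2).
#' @return Two-column matrix of parent pairs.
#' @export
half_diallel_plan <- function(parent_ids) {
  n <- length(parent_ids)
  if (n < 2L) stop("parameter error: need >= 2 parents")
  idx <- utils::combn(n, 2L)
  cbind(p1 = parent_ids[idx[1, ]], p2 = parent_ids[idx[2, ]])
}

# Genetic map positions in cM per chromosome, from pos_cm or pos_bp scaling.
genetic_positions <- function(map, cm_per_mb = 1.0) {
  if (!is.null(map$pos_cm)) map$pos_cm else map$pos_bp / 1e6 * cm_per_mb
}

#' Simulate one meiotic gamete
#'
#' Per chromosome, the crossover count is Poisson with mean equal to the map
#' length in Morgans (Haldane model: no interference), crossover positions are
#' uniform on the genetic map and the starting phase is a fair coin; the
#' recombinant haplotype is read off against the marker positions. A
#' zero-length chromosome co-inherits all its markers.
#'
#' @param geno `2 x M` integer matrix (rows = chromosome copies).
#' @param map a [marker_map()] of length M.
#' @param cm_per_mb scaling used when `pos_cm` is absent.
#' @return Length-M integer haplotype.
#' @export
meiosis_gamete <- function(geno, map, cm_per_mb = 1.0) {
  M <- ncol(geno)
  cm <- genetic_positions(map, cm_per_mb)
  gam <- integer(M)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- cm[idx]
    len_m <- (max(pos) - min(pos)) / 100
    phase0 <- sample.int(2L, 1L)
    if (len_m <= 0) {
      gam[idx] <- geno[phase0, idx]
      next
    }
    nco <- stats::rpois(1L, len_m)
    if (nco == 0L) {
      gam[idx] <- geno[phase0, idx]
      next
    }
    co <- sort(stats::runif(nco, min(pos), max(pos)))
    n_before <- findInterval(pos, co)
    phase <- 1L + (phase0 - 1L + n_before) %% 2L
    gam[idx] <- geno[cbind(phase, idx)]
  }
  gam
}

#' Produce a doubled-haploid line
#'
#' One meiotic gamete duplicated into both chromosome copies, so the line is
#' exactly homozygous at every locus.
#'
#' @inheritParams meiosis_gamete
#' @return `2 x M` integer matrix with identical rows.
#' @export
make_dh <- function(geno, map, cm_per_mb = 1.0) {
  g <- meiosis_gamete(geno, map, cm_per_mb)
  rbind(g, g)
}

#' True genetic value of an individual
#'
#' `intercept + sum over copies and loci of allele x effect`; identical to the
#' GEBV computed from the same effects.
#'
#' @param geno `2 x M` integer matrix.
#' @param effects a [marker_effects()] (raw trait scale: for a resistance
#'   score, lower is better).
#' @return Scalar genetic value.
#' @export
genetic_value <- function(geno, effects) {
  if (ncol(geno) != length(effects$effect))
    stop("alignment error: genotype and effects differ in marker count")
  effects$intercept + sum(colSums(geno) * unname(effects$effect))
}

#' Expected heterozygosity of a population
#'
#' Mean over loci of `2p(1-p)` with `p` the major-allele frequency over all
#' chromosome copies in the population; at most 0.5 per biallelic locus.
#'
#' @param pop list of `2 x M` genotype matrices.
#' @return Scalar in `[0, 0.5]`.
#' @export
expected_heterozygosity <- function(pop) {
  if (!length(pop)) stop("need >= 1 individual")
  allele_sum <- Reduce(`+`, lapply(pop, colSums))
  p <- allele_sum / (2 * length(pop))
  mean(2 * p * (1 - p))
}

panel_genotype <- function(panel, id) {
  i <- match(id, panel$individual_id)
  if (is.na(i)) stop("lookup error: founder id not in panel: ", id)
  matrix(panel$alleles[i, , ], nrow = 2L)
}

#' Run the recurrent breeding simulation
#'
#' Per replicate and cycle: the current parents are crossed in a half-diallel;
#' each cross yields one F1 (one gamete from each parent) from which
#' `dh_per_cross` doubled-haploid lines are simulated; the
#' `selected_per_cross` lowest-genetic-value DH lines per cross are pooled;
#' the next parent set is the `new_parents_per_cycle` best (lowest value)
#' lines of that pool plus the `retained_parents` best of the previous parent
#' set. Selection uses true genetic values throughout — founder strategies
#' differ only in the founder sets supplied. Metrics (mean genetic value,
#' genetic variance, expected heterozygosity of the parent set) are recorded
#' at cycle 0 (founders) and after every cycle. The population is closed: no
#' mutation or migration, so every allele present at cycle t existed at t-1.
#'
#' @param panel a [haplotype_panel()] holding the founder genotypes.
#' @param effects a [marker_effects()] on the raw trait scale (lower = better).
#' @param founders either a vector of founder ids (one strategy) or a named
#'   list of such vectors (one per strategy), each of length `n_parents`.
#' @param cfg a [sim_config()].
#' @return data.frame with columns `strategy`, `replicate`, `cycle`,
#'   `mean_genetic_value`, `genetic_variance`, `expected_heterozygosity`.
#' @export
run_breeding_simulation <- function(panel, effects, founders, cfg = sim_config()) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(effects, "marker_effects"))
  check_effects_alignment(panel, effects)
  if (!is.list(founders)) founders <- list(default = founders)
  if (is.null(names(founders))) names(founders) <- paste0("strategy", seq_along(founders))
  for (f in founders)
    if (length(f) != cfg$n_parents)
      stop("each founder set must have n_parents = ", cfg$n_parents, " ids")
  set.seed(cfg$seed)
  map <- panel$map
  eff <- unname(effects$effect)
  value_of <- function(g) effects$intercept + sum(colSums(g) * eff)
  out <- list()
  for (strat in names(founders)) {
    founder_geno <- lapply(founders[[strat]], function(id) panel_genotype(panel, id))
    for (rep_i in seq_len(cfg$replicates)) {
      parents <- founder_geno
      pvals <- vapply(parents, value_of, 0)
      metrics <- function(cyc) data.frame(
        strategy = strat, replicate = rep_i, cycle = cyc,
        mean_genetic_value = mean(pvals),
        genetic_variance = stats::var(pvals),
        expected_heterozygosity = expected_heterozygosity(parents),
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- metrics(0L)
      for (cyc in seq_len(cfg$cycles)) {
        plan <- half_diallel_plan(seq_along(parents))
        kept <- list()
        kept_vals <- numeric(0)
        for (cr in seq_len(nrow(plan))) {
          pA <- parents[[as.integer(plan[cr, 1])]]
          pB <- parents[[as.integer(plan[cr, 2])]]
          f1 <- rbind(meiosis_gamete(pA, map, cfg$cm_per_mb),
                      meiosis_gamete(pB, map, cfg$cm_per_mb))
          dhs <- lapply(seq_len(cfg$dh_per_cross),
                        function(i) make_dh(f1, map, cfg$cm_per_mb))
          vals <- vapply(dhs, value_of, 0)
          sel <- order(vals, seq_along(vals))[seq_len(cfg$selected_per_cross)]
          kept <- c(kept, dhs[sel])
          kept_vals <- c(kept_vals, vals[sel])
        }
        new_idx <- order(kept_vals, seq_along(kept_vals))[seq_len(cfg$new_parents_per_cycle)]
        ret_idx <- order(pvals, seq_along(pvals))[seq_len(cfg$retained_parents)]
        parents <- c(kept[new_idx], parents[ret_idx])
        pvals <- c(kept_vals[new_idx], pvals[ret_idx])
        out[[length(out) + 1L]] <- metrics(cyc)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
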