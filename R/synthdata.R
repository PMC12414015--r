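# Seeded synthetic-data generators: inbred diploid panels with planted
# block-structured LD, additive marker effects with replicated trial scores on
# a bounded ordinal-like scale, and the small hand-enumerated fitness fixture.

#' Simulate an inbred panel with planted LD blocks
#'
#' Markers are laid out in consecutive planted blocks of `block_length`
#' markers. For each block an ancestral pool of `n_ancestral_haplotypes`
#' binary haplotypes is generated (with two haplotypes the pool is a sequence
#' and its complement, so every marker is polymorphic and within-block r^2 is
#' exactly 1); each individual draws one ancestral haplotype per block,
#' independently across blocks, and carries it on both copies (fully inbred).
#' With `equifrequent = TRUE` the ancestral haplotypes are assigned in
#' shuffled round-robin, making within-block frequencies exactly balanced.
#' Marker positions are evenly spaced at `marker_spacing_bp`.
#'
#' @param n_individuals panel size N.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param block_length markers per planted block.
#' @param n_ancestral_haplotypes ancestral pool size per block (>= 2 for
#'   polymorphism; 1 gives a monomorphic panel).
#' @param equifrequent balance ancestral-haplotype frequencies exactly.
#' @param marker_spacing_bp physical spacing between adjacent markers
#'   (default 1 Mb, i.e. 1 cM at the default genetic scaling).
#' @param seed RNG seed.
#' @return A [haplotype_panel()]; the planted block boundaries are attached as
#'   attribute `planted_blocks` (data.frame `chrom`, `start`, `end` in marker
#'   indices).
#' @export
simulate_panel <- function(n_individuals, n_chromosomes = 1L,
                           markers_per_chrom = 50L, block_length = 5L,
                           n_ancestral_haplotypes = 2L, equifrequent = TRUE,
                           marker_spacing_bp = 1e6, seed = 1L) {
  stopifnot(block_length >= 1, n_ancestral_haplotypes >= 1, n_individuals >= 1)
  set.seed(seed)
  N <- n_individuals
  M <- n_chromosomes * markers_per_chrom
  alleles <- array(0L, dim = c(N, 2L, M))
  planted <- list()
  col <- 0L
  for (ch in seq_len(n_chromosomes)) {
    left <- markers_per_chrom
    while (left > 0L) {
      len <- min(block_length, left)
      pool <- matrix(stats::rbinom(n_ancestral_haplotypes * len, 1L, 0.5),
                     n_ancestral_haplotypes, len)
      if (n_ancestral_haplotypes == 2L) {
        pool[2L, ] <- 1L - pool[1L, ]  # complement: every marker polymorphic
      } else if (n_ancestral_haplotypes > 2L) {
        const <- which(apply(pool, 2, function(x) length(unique(x)) == 1L))
        for (j in const) pool[1L, j] <- 1L - pool[1L, j]
      }
      draw <- if (equifrequent && n_ancestral_haplotypes > 1L)
        sample(rep_len(seq_len(n_ancestral_haplotypes), N))
      else sample.int(n_ancestral_haplotypes, N, replace = TRUE)
      hap <- pool[draw, , drop = FALSE]
      idx <- col + seq_len(len)
      alleles[, 1L, idx] <- hap
      alleles[, 2L, idx] <- hap
      planted[[length(planted) + 1L]] <-
        data.frame(chrom = as.character(ch), start = as.integer(idx[1]),
                   end = as.integer(idx[len]))
      col <- col + len
      left <- left - len
    }
  }
  map <- marker_map(paste0("m", seq_len(M)),
                    rep(as.character(seq_len(n_chromosomes)), each = markers_per_chrom),
                    rep(seq_len(markers_per_chrom) * marker_spacing_bp, n_chromosomes))
  panel <- haplotype_panel(paste0("ind", seq_len(N)), recode_major(alleles), map)
  attr(panel, "planted_blocks") <- do.call(rbind, planted)
  panel
}

#' Simulate additive effects and replicated trial scores
#'
#' Marker effects are centred Gaussian; true genetic values are
#' `g = dosage %*% effect`; the residual variance is set so that
#' `var(g) / var(g + e) = h2`; replicate scores are a common affine rescaling
#' of `g + e` into the trait scale (default 1-9, emulating ordinal disease
#' scores analysed with linear models), clipped at the bounds. The returned
#' effects and truth are on the rescaled score scale.
#'
#' @param panel a [haplotype_panel()].
#' @param h2 broad-sense heritability of a single replicate, in `(0, 1]`.
#' @param replicates replicate scores per individual.
#' @param trait_min,trait_max trait scale bounds.
#' @param effect_sd standard deviation of the raw marker effects.
#' @param seed RNG seed.
#' @return List with `effects` (a [marker_effects()] on the score scale),
#'   `phenotypes` (data.frame `individual_id`, `replicate`, `score`) and
#'   `truth` (list: `genetic_value` named vector on the score scale, `h2`).
#' @export
simulate_effects_phenotypes <- function(panel, h2 = 0.5, replicates = 2L,
                                        trait_min = 1, trait_max = 9,
                                        effect_sd = 1, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), h2 > 0, h2 <= 1)
  set.seed(seed)
  D <- dosage_matrix(panel)
  N <- nrow(D); M <- ncol(D)
  e_raw <- stats::rnorm(M, 0, effect_sd)
  g <- as.numeric(D %*% e_raw)
  vg <- stats::var(g)
  if (vg == 0) stop("parameter error: zero genetic variance in panel at h2 > 0")
  ve <- vg * (1 - h2) / h2
  noise <- matrix(stats::rnorm(N * replicates, 0, sqrt(ve)), N, replicates)
  raw <- g + noise  # recycled by column: raw[i, r] = g[i] + noise[i, r]
  lo <- min(raw); hi <- max(raw)
  a <- trait_min - lo * (trait_max - trait_min) / (hi - lo)
  b <- (trait_max - trait_min) / (hi - lo)
  scores <- pmin(trait_max, pmax(trait_min, a + b * raw))
  pheno <- data.frame(
    individual_id = rep(panel$individual_id, times = replicates),
    replicate = rep(seq_len(replicates), each = N),
    score = as.numeric(scores))
  effects <- marker_effects(a, b * e_raw, panel$map$marker_id)
  truth <- list(genetic_value = stats::setNames(a + b * g, panel$individual_id),
                h2 = h2)
  list(effects = effects, phenotypes = pheno, truth = truth)
}

#' The hand-enumerated fitness fixture
#'
#' A 4-individual, 2-block value tensor whose optima are known by exhaustive
#' enumeration: with `k = 2`, the OHS optimum is 15 (tied argmax subsets
#' \{1,3\}, \{2,3\}, \{3,4\}), the OPV optimum is 22 (unique argmax \{3,4\}),
#' and the per-individual totals are 10, 8, 13, 6 so the summed-GEBV argmax is
#' \{1,3\}. The same tensor ships as a TSV under `extdata/f1_block_values.tsv`.
#'
#' @return List with `tensor` (a [block_value_tensor()]) and `expected`
#'   (list of the enumerated optima above).
#' @export
make_fixture_f1 <- function() {
  values <- array(0, dim = c(2L, 4L, 2L))
  variants <- array("", dim = c(2L, 4L, 2L))
  # block 1: ind1 (4,4)=(A,A); ind2 (3,1)=(B,C); ind3 (4,3)=(A,B); ind4 (5,1)=(D,C)
  values[1, , 1] <- c(4, 3, 4, 5); variants[1, , 1] <- c("A", "B", "A", "D")
  values[1, , 2] <- c(4, 1, 3, 1); variants[1, , 2] <- c("A", "C", "B", "C")
  # block 2: ind1 (2,0)=(E,F); ind2 (2,2)=(E,E); ind3 (6,0)=(G,F); ind4 (0,0)=(F,F)
  values[2, , 1] <- c(2, 2, 6, 0); variants[2, , 1] <- c("E", "E", "G", "F")
  values[2, , 2] <- c(0, 2, 0, 0); variants[2, , 2] <- c("F", "E", "F", "F")
  tensor <- block_value_tensor(values, variants, paste0("ind", 1:4))
  expected <- list(
    k = 2L,
    ohs_best = 15, ohs_argmax = list(c(1L, 3L), c(2L, 3L), c(3L, 4L)),
    opv_best = 22, opv_argmax = list(c(3L, 4L)),
    gebv_totals = c(10, 8, 13, 6), gebv_argmax = list(c(1L, 3L)))
  list(tensor = tensor, expected = expected)
}
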