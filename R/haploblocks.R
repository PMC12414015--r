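# Linkage-disequilibrium r^2, haplotype-block construction, and per-block
# haplotype values (summed additive effects over the markers of a block).

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the major-allele dosage columns of two loci
#' across all individuals. In an inbred panel this genotypic r^2 coincides
#' with the classical haplotype-frequency r^2 and needs no phasing.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j marker indices (1-based, in map order).
#' @return r^2 in `[0, 1]`.
#' @export
pairwise_r2 <- function(panel, i, j) {
  D <- dosage_matrix(panel)
  dosage_r2(D[, i], D[, j])
}

dosage_r2 <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined LD: monomorphic locus")
  stats::cor(x, y)^2
}

# r^2 treating undefined (monomorphic) pairs as zero, i.e. below any threshold.
safe_r2 <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Construct haplotype blocks from adjacent-marker LD
#'
#' Greedy one-pass chaining per chromosome: the open block is extended to the
#' next marker when its r^2 with the previous marker, or with the block's left
#' boundary marker, meets the threshold; otherwise the block is closed and a
#' new one opened. Monomorphic pairs count as below threshold, so monomorphic
#' markers end up in singleton blocks (markers failing the LD rule always do).
#' Blocks never span chromosomes, and the output partitions the map: every
#' marker belongs to exactly one block.
#'
#' @param panel a [haplotype_panel()] with its map sorted (enforced at
#'   construction).
#' @param r2_threshold LD threshold in `(0, 1]`; adjacency requires
#'   `r^2 >= r2_threshold`. Default 0.5.
#' @return A `data.frame` of class `haplo_blocks` with columns `block_id`,
#'   `chrom`, `start` and `end` (1-based marker indices into the map,
#'   inclusive) and `n_markers`.
#' @export
build_blocks <- function(panel, r2_threshold = 0.5) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!(r2_threshold > 0 && r2_threshold <= 1))
    stop("r2_threshold must be in (0, 1]")
  D <- dosage_matrix(panel)
  map <- panel$map
  out <- list()
  bid <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    start <- idx[1]
    prev <- idx[1]
    for (i in idx[-1]) {
      ok <- safe_r2(D[, prev], D[, i]) >= r2_threshold ||
        safe_r2(D[, start], D[, i]) >= r2_threshold
      if (!ok) {
        bid <- bid + 1L
        out[[bid]] <- data.frame(block_id = bid, chrom = ch,
                                 start = start, end = prev)
        start <- i
      }
      prev <- i
    }
    bid <- bid + 1L
    out[[bid]] <- data.frame(block_id = bid, chrom = ch, start = start, end = prev)
  }
  blocks <- do.call(rbind, out)
  blocks$n_markers <- blocks$end - blocks$start + 1L
  class(blocks) <- c("haplo_blocks", "data.frame")
  blocks
}

#' Export haplotype blocks as a BED-like TSV
#'
#' Columns: `chrom`, `start_bp`, `end_bp`, `block_id`, `n_markers`.
#'
#' @param blocks a [build_blocks()] result.
#' @param panel the panel the blocks were built from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, panel, path) {
  stopifnot(inherits(blocks, "haplo_blocks"))
  bed <- data.frame(chrom = blocks$chrom,
                    start_bp = panel$map$pos_bp[blocks$start],
                    end_bp = panel$map$pos_bp[blocks$end],
                    block_id = blocks$block_id,
                    n_markers = blocks$n_markers)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-block haplotype values and variant identities
#'
#' For every block, individual and chromosome copy, the haplotype value is the
#' sum of major-allele indicators times the marker effects over the block's
#' markers; the variant identity is the within-block allele string. Identical
#' variant strings therefore always carry identical values within a block.
#' Marker effects should already be on the desirability scale (see
#' [desirability_transform()]).
#'
#' @param panel a [haplotype_panel()].
#' @param blocks a [build_blocks()] result (or any partition of the map with
#'   columns `start`, `end`).
#' @param effects a [marker_effects()] aligned with the panel.
#' @return A list of class `block_value_tensor` with `values` and `variants`
#'   (`B x N x 2` arrays), `block_id` and `individual_id`.
#' @export
catalog_block_values <- function(panel, blocks, effects) {
  stopifnot(inherits(panel, "haplotype_panel"))
  check_effects_alignment(panel, effects)
  N <- dim(panel$alleles)[1]
  B <- nrow(blocks)
  values <- array(0, dim = c(B, N, 2L))
  variants <- array("", dim = c(B, N, 2L))
  e <- unname(effects$effect)
  for (m in 1:2) {
    H <- matrix(panel$alleles[, m, ], nrow = N)  # N x M haplotype slice
    for (b in seq_len(B)) {
      idx <- blocks$start[b]:blocks$end[b]
      sub <- H[, idx, drop = FALSE]
      values[b, , m] <- as.numeric(sub %*% e[idx])
      variants[b, , m] <- apply(sub, 1, paste, collapse = "")
    }
  }
  structure(list(values = values, variants = variants,
                 block_id = blocks$block_id,
                 individual_id = panel$individual_id),
            class = "block_value_tensor")
}

#' Construct a block-value tensor directly
#'
#' Mainly used by generators and tests; validates the defining invariant that
#' identical variant identities within a block carry identical values.
#'
#' @param values `B x N x 2` numeric array of haplotype values.
#' @param variants `B x N x 2` character array of variant identities.
#' @param individual_id optional individual names.
#' @return A list of class `block_value_tensor`.
#' @export
block_value_tensor <- function(values, variants, individual_id = NULL) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == 2L,
            identical(dim(values), dim(variants)))
  B <- dim(values)[1]; N <- dim(values)[2]
  for (b in seq_len(B)) {
    v <- as.vector(values[b, , ]); id <- as.vector(variants[b, , ])
    if (any(tapply(v, id, function(z) max(z) - min(z)) > 1e-9))
      stop("identical variant ids must have identical values within a block")
  }
  if (is.null(individual_id)) individual_id <- paste0("ind", seq_len(N))
  structure(list(values = values, variants = variants,
                 block_id = seq_len(B), individual_id = individual_id),
            class = "block_value_tensor")
}

#' @export
print.block_value_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("block_value_tensor:", d[1], "blocks x", d[2], "individuals x 2 copies\n")
  invisible(x)
}

#' Write / read a block-value tensor as TSV
#'
#' Long format with columns `block_id`, `individual_id`, `copy`, `variant_id`,
#' `value`; the round trip is an identity on valid tensors.
#'
#' @param tensor a [block_value_tensor()].
#' @param path output (or input) path.
#' @return `write_block_values` returns `path` invisibly; `read_block_values`
#'   returns a [block_value_tensor()].
#' @export
write_block_values <- function(tensor, path) {
  stopifnot(inherits(tensor, "block_value_tensor"))
  d <- dim(tensor$values)
  grid <- expand.grid(b = seq_len(d[1]), n = seq_len(d[2]), m = 1:2)
  tab <- data.frame(block_id = tensor$block_id[grid$b],
                    individual_id = tensor$individual_id[grid$n],
                    copy = grid$m,
                    variant_id = tensor$variants[as.matrix(grid)],
                    value = tensor$values[as.matrix(grid)])
  tab <- tab[order(grid$b, grid$n, grid$m), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_values
#' @export
read_block_values <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(variant_id = "character"))
  blocks <- unique(tab$block_id)
  inds <- unique(tab$individual_id)
  B <- length(blocks); N <- length(inds)
  values <- array(0, dim = c(B, N, 2L))
  variants <- array("", dim = c(B, N, 2L))
  bi <- match(tab$block_id, blocks)
  ni <- match(tab$individual_id, inds)
  values[cbind(bi, ni, tab$copy)] <- tab$value
  variants[cbind(bi, ni, tab$copy)] <- tab$variant_id
  block_value_tensor(values, variants, inds)
}
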