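# Data model: marker maps, phased haplotype panels, phenotypes, marker effects.

#' Construct and validate a marker map
#'
#' A marker map records, for each marker, its chromosome and physical position
#' (1-based base pairs, as in VCF) and optionally a genetic position in
#' centimorgans. Markers must be unique and, within each chromosome, sorted by
#' strictly increasing physical position; genetic positions, when present, must
#' be non-decreasing within a chromosome.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom character vector of chromosome names.
#' @param pos_bp integer vector of physical positions (bp, >= 0).
#' @param pos_cm optional numeric vector of genetic positions (cM, >= 0).
#' @return A `data.frame` of class `marker_map`.
#' @export
marker_map <- function(marker_id, chrom, pos_bp, pos_cm = NULL) {
  marker_id <- as.character(marker_id)
  chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  n <- length(marker_id)
  if (length(chrom) != n || length(pos_bp) != n)
    stop("marker_id, chrom and pos_bp must have equal length")
  if (anyDuplicated(marker_id))
    stop("marker ids must be unique")
  if (any(!is.finite(pos_bp)) || any(pos_bp < 0))
    stop("pos_bp must be finite and >= 0")
  map <- data.frame(marker_id = marker_id, chrom = chrom, pos_bp = pos_bp,
                    stringsAsFactors = FALSE)
  if (!is.null(pos_cm)) {
    pos_cm <- as.numeric(pos_cm)
    if (length(pos_cm) != n) stop("pos_cm must match marker count")
    if (any(!is.finite(pos_cm)) || any(pos_cm < 0))
      stop("pos_cm must be finite and >= 0")
    map$pos_cm <- pos_cm
  }
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$pos_bp, strictly = TRUE))
      stop("map not sorted: pos_bp must be strictly increasing within chromosome ", ch)
    if (!is.null(sub$pos_cm) && is.unsorted(sub$pos_cm))
      stop("pos_cm must be non-decreasing within chromosome ", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Construct and validate a haplotype panel
#'
#' The panel stores, for `N` individuals at `M` biallelic loci, the two
#' chromosome copies as a binary `N x 2 x M` array where 1 denotes the
#' major allele (per-locus convention after recoding) and 0 the minor allele.
#'
#' @param individual_id character vector of unique individual names (length N).
#' @param alleles `N x 2 x M` array with entries in \{0, 1\}.
#' @param map a [marker_map()] of length M.
#' @return A list of class `haplotype_panel` with elements `individual_id`,
#'   `alleles` and `map`.
#' @export
haplotype_panel <- function(individual_id, alleles, map) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id)) stop("individual ids must be unique")
  if (!is.array(alleles) || length(dim(alleles)) != 3L)
    stop("alleles must be an N x 2 x M array")
  d <- dim(alleles)
  if (d[2] != 2L) stop("copy axis must have length exactly 2 (diploid)")
  if (d[1] < 1L || d[3] < 1L) stop("need N >= 1 individuals and M >= 1 markers")
  if (d[1] != length(individual_id))
    stop("individual_id length does not match allele array")
  if (!inherits(map, "marker_map")) stop("map must be a marker_map")
  if (nrow(map) != d[3]) stop("map length does not match number of markers")
  if (anyNA(alleles)) stop("missing genotypes are not supported; filter upstream")
  if (!all(alleles %in% c(0, 1))) stop("allele entries must be 0 or 1")
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- list(individual_id, c("copy1", "copy2"), map$marker_id)
  structure(list(individual_id = individual_id, alleles = alleles, map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  d <- dim(x$alleles)
  cat("haplotype_panel:", d[1], "individuals x", d[3], "markers (",
      length(unique(x$map$chrom)), "chromosome(s), diploid phased )\n")
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

# Recode columns so allele 1 is the major allele (frequency >= 0.5 across all
# copies); exact ties keep the input coding. Returns the recoded N x 2 x M array.
recode_major <- function(alleles) {
  freq <- apply(alleles, 3, mean)
  flip <- which(freq < 0.5)
  if (length(flip)) alleles[, , flip] <- 1L - alleles[, , flip]
  alleles
}

#' Read a haplotype panel from VCF or TSV
#'
#' Supported inputs: a phased VCF of biallelic SNPs (GT with `|` separator;
#' unphased homozygous calls are accepted since their phase is trivial), or a
#' TSV matrix. The TSV dialect has a header of marker ids, a first column
#' `individual_id`, and either an integer `copy` column (1/2; one row per
#' individual-copy) or, with `assume_inbred = TRUE`, one dosage row (0/2) per
#' individual that is expanded to two identical copies. After reading, alleles
#' are recoded per locus so that code 1 is the major allele (frequency >= 0.5
#' across all copies; exact ties keep the input allele-1 coding).
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` or `"tsv"`; `"auto"` guesses from the file extension.
#' @param assume_inbred logical; treat individuals as fully inbred. Required to
#'   accept dosage input; any heterozygous call then raises an inbreeding
#'   violation error.
#' @param map an optional [marker_map()] (or path to a map TSV with columns
#'   `marker_id`, `chrom`, `pos_bp` and optionally `pos_cm`) for TSV input. If
#'   omitted, markers are placed on one chromosome at 1 Mb spacing.
#' @return A [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path, format = c("auto", "vcf", "tsv"),
                                 assume_inbred = FALSE, map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_panel_vcf(path, assume_inbred)
  else read_panel_tsv(path, assume_inbred, map)
}

read_panel_vcf <- function(path, assume_inbred) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-variant VCF: `[` drops to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) stop("multi-allelic site in VCF: only biallelic SNPs supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (anyNA(gt) || any(gt %in% c(".", "./.", ".|.")))
    stop("missing genotypes are not supported; filter upstream")
  ids <- colnames(gt)
  M <- nrow(gt); N <- length(ids)
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  if (!all(a1 %in% c("0", "1")) || !all(a2 %in% c("0", "1")))
    stop("multi-allelic or missing allele codes in GT")
  het <- a1 != a2
  unphased <- sep == "/"
  if (assume_inbred && any(het))
    stop("inbreeding violation: heterozygous genotype under assume_inbred")
  if (!assume_inbred && any(het & unphased))
    stop("phase error: unphased heterozygous genotype; phase the VCF or set assume_inbred")
  alleles <- array(0L, dim = c(N, 2L, M))
  alleles[, 1L, ] <- t(matrix(as.integer(a1), M, N))
  alleles[, 2L, ] <- t(matrix(as.integer(a2), M, N))
  mid <- fix[, "ID"]
  if (anyNA(mid) || any(mid == ".")) mid <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  map <- marker_map(mid, fix[, "CHROM"], as.numeric(fix[, "POS"]))
  haplotype_panel(ids, recode_major(alleles), map)
}

read_panel_tsv <- function(path, assume_inbred, map) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(tab)) stop("TSV must have an individual_id column")
  has_copy <- "copy" %in% names(tab)
  meta_cols <- c("individual_id", if (has_copy) "copy")
  marker_ids <- setdiff(names(tab), meta_cols)
  if (!length(marker_ids)) stop("TSV has no marker columns")
  G <- as.matrix(tab[, marker_ids, drop = FALSE])
  if (anyNA(G)) stop("missing genotypes are not supported; filter upstream")
  if (!is.numeric(G)) stop("parse error: marker columns must be numeric")
  M <- length(marker_ids)
  if (has_copy) {
    ids <- unique(tab$individual_id)
    N <- length(ids)
    if (nrow(tab) != 2L * N || !all(sort(unique(tab$copy)) %in% 1:2))
      stop("copy rows must come in pairs (copy 1 and 2) per individual")
    if (!all(G %in% c(0, 1))) stop("haplotype rows must be binary 0/1")
    alleles <- array(0L, dim = c(N, 2L, M))
    for (i in seq_len(N)) {
      rows <- which(tab$individual_id == ids[i])
      if (length(rows) != 2L || !setequal(tab$copy[rows], 1:2))
        stop("individual ", ids[i], " must have exactly copies 1 and 2")
      alleles[i, 1L, ] <- as.integer(G[rows[tab$copy[rows] == 1L], ])
      alleles[i, 2L, ] <- as.integer(G[rows[tab$copy[rows] == 2L], ])
    }
  } else {
    if (!assume_inbred)
      stop("phase error: dosage rows require assume_inbred = TRUE")
    if (any(G == 1)) stop("inbreeding violation: dosage 1 under assume_inbred")
    if (!all(G %in% c(0, 2))) stop("dosage entries must be 0 or 2 for inbred lines")
    ids <- tab$individual_id
    if (anyDuplicated(ids)) stop("duplicate individual_id in dosage TSV")
    N <- length(ids)
    alleles <- array(0L, dim = c(N, 2L, M))
    alleles[, 1L, ] <- as.integer(G / 2L)
    alleles[, 2L, ] <- alleles[, 1L, ]
  }
  if (is.null(map)) {
    map <- marker_map(marker_ids, rep("1", M), seq_len(M) * 1e6)
  } else {
    if (is.character(map)) map <- read_marker_map(map)
    if (!identical(map$marker_id, marker_ids))
      stop("alignment error: map marker ids do not match TSV header")
  }
  haplotype_panel(ids, recode_major(alleles), map)
}

#' Read a marker map TSV
#'
#' Columns: `marker_id`, `chrom`, `pos_bp` and optionally `pos_cm`.
#'
#' @param path path to the map TSV.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(tab))) stop("map TSV needs columns marker_id, chrom, pos_bp")
  marker_map(tab$marker_id, tab$chrom, tab$pos_bp, tab$pos_cm)
}

#' Major-allele dosage matrix
#'
#' Sums the major-allele indicators over the two chromosome copies, giving an
#' `N x M` integer matrix with entries in \{0, 1, 2\}.
#'
#' @param panel a [haplotype_panel()].
#' @return Integer matrix with individuals as rows and markers as columns.
#' @export
dosage_matrix <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  D <- panel$alleles[, 1L, , drop = FALSE] + panel$alleles[, 2L, , drop = FALSE]
  D <- array(D, dim = dim(panel$alleles)[c(1, 3)])
  dimnames(D) <- list(panel$individual_id, panel$map$marker_id)
  storage.mode(D) <- "integer"
  D
}

#' Construct a table of additive marker effects
#'
#' @param intercept scalar intercept (population mean on the trait scale).
#' @param effect numeric vector of additive effects of the major allele, one
#'   per marker.
#' @param marker_id character vector of marker names matching `effect`.
#' @return A list of class `marker_effects`.
#' @export
marker_effects <- function(intercept, effect, marker_id) {
  effect <- as.numeric(effect)
  intercept <- as.numeric(intercept)
  if (length(intercept) != 1L || !is.finite(intercept)) stop("intercept must be a finite scalar")
  if (any(!is.finite(effect))) stop("effects must be finite")
  if (length(marker_id) != length(effect)) stop("marker_id must match effect length")
  structure(list(intercept = intercept,
                 effect = stats::setNames(effect, as.character(marker_id))),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat("marker_effects:", length(x$effect), "markers, intercept",
      format(x$intercept), "\n")
  invisible(x)
}

check_effects_alignment <- function(panel, effects) {
  if (!identical(names(effects$effect), panel$map$marker_id))
    stop("alignment error: effects do not match panel markers")
  invisible(TRUE)
}

#' Write / read marker effects as TSV
#'
#' The TSV has columns `marker_id` and `effect`; the intercept travels in a
#' `#intercept=<value>` comment line so that `read_effects(write_effects(x))`
#' is an identity to full precision.
#'
#' @param effects a [marker_effects()] object.
#' @param path output (or input) path.
#' @param panel optional [haplotype_panel()]; when supplied, the marker ids are
#'   checked against the panel map and a mismatch raises an alignment error.
#' @return `write_effects` returns `path` invisibly; `read_effects` returns a
#'   [marker_effects()].
#' @export
write_effects <- function(effects, path) {
  stopifnot(inherits(effects, "marker_effects"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#intercept=%s", format(effects$intercept, digits = 17)), con)
  writeLines("marker_id\teffect", con)
  writeLines(paste(names(effects$effect),
                   vapply(unname(effects$effect), format, "", digits = 17),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path, panel = NULL) {
  lines <- readLines(path)
  hl <- grep("^#intercept=", lines, value = TRUE)
  if (length(hl) != 1L) stop("parse error: missing #intercept header line")
  intercept <- as.numeric(sub("^#intercept=", "", hl))
  tab <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                           stringsAsFactors = FALSE)
  if (!all(c("marker_id", "effect") %in% names(tab)))
    stop("parse error: effects TSV needs marker_id and effect columns")
  if (nrow(tab) == 0L || anyNA(tab$effect) || !is.numeric(tab$effect))
    stop("parse error: empty or non-numeric effect column")
  eff <- marker_effects(intercept, tab$effect, tab$marker_id)
  if (!is.null(panel)) check_effects_alignment(panel, eff)
  eff
}
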