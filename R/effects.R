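# Phenotype adjustment (BLUEs), trial heritability, ridge-regression BLUP
# marker effects, genomic estimated breeding values, and the trait-direction
# (desirability) convention.

check_phenotypes <- function(pheno) {
  need <- c("individual_id", "replicate", "score")
  if (!is.data.frame(pheno) || !all(need %in% names(pheno)))
    stop("phenotypes need columns individual_id, replicate, score")
  if (anyNA(pheno$score)) stop("missing scores are not supported")
  if (any(pheno$replicate < 1)) stop("replicate must be >= 1")
  invisible(TRUE)
}

#' Best linear unbiased estimates of genotype means
#'
#' Fits a two-factor fixed-effect model `score ~ genotype + replicate` by least
#' squares and returns genotype means adjusted for an additive replicate
#' effect, averaged over replicate levels. With a single replicate, or with
#' balanced data and no replicate effect, the BLUE reduces to the per-genotype
#' arithmetic mean.
#'
#' @param pheno data.frame with columns `individual_id`, `replicate`, `score`.
#' @return Named numeric vector of BLUEs, one per individual (sorted by id).
#' @export
compute_blues <- function(pheno) {
  check_phenotypes(pheno)
  geno <- factor(pheno$individual_id)
  rep_f <- factor(pheno$replicate)
  if (nlevels(rep_f) == 1L) {
    means <- tapply(pheno$score, geno, mean)
    return(stats::setNames(as.numeric(means), levels(geno)))
  }
  fit <- stats::lm(score ~ 0 + geno + rep_f,
                   data = data.frame(score = pheno$score, geno = geno, rep_f = rep_f))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("confounding error: genotype and replicate effects are not separable")
  g <- cf[paste0("geno", levels(geno))]
  r <- cf[paste0("rep_f", levels(rep_f)[-1])]
  stats::setNames(as.numeric(g + mean(c(0, r))), levels(geno))
}

#' Broad-sense heritability from a replicated trial
#'
#' One-way random-effects model with genotypes random, solved in closed form
#' from the expected mean squares of the genotype ANOVA:
#' `sigma2_g = max(0, (MSG - MSE) / r)` with `r` the (mean) replicate count,
#' and `H2 = sigma2_g / (sigma2_g + sigma2_e)` — the ratio of genetic to total
#' phenotypic variance at the plot level. For balanced data the variance
#' components coincide with REML.
#'
#' @param pheno data.frame with columns `individual_id`, `replicate`, `score`.
#' @return A list of class `heritability_estimate` with elements `sigma2_g`,
#'   `sigma2_e`, `H2` and `r_bar`.
#' @export
estimate_heritability <- function(pheno) {
  check_phenotypes(pheno)
  geno <- factor(pheno$individual_id)
  if (nlevels(geno) < 2L) stop("need >= 2 individuals")
  counts <- table(geno)
  if (all(counts < 2L)) stop("need >= 2 replicates for identifiability")
  r_bar <- mean(as.numeric(counts))
  if (stats::var(pheno$score) == 0) {
    warning("all scores identical: zero genetic and residual variance, H2 = 0")
    out <- list(sigma2_g = 0, sigma2_e = 0, H2 = 0, r_bar = r_bar)
    class(out) <- "heritability_estimate"
    return(out)
  }
  # one-way ANOVA mean squares computed directly (no F-test needed)
  fit <- stats::lm(pheno$score ~ geno)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((pheno$score - mean(pheno$score))^2)
  msg <- (sst - sse) / (nlevels(geno) - 1L)
  df_e <- length(pheno$score) - nlevels(geno)
  mse <- if (df_e > 0L) sse / df_e else 0
  s2g <- max(0, (msg - mse) / r_bar)
  h2 <- if (s2g + mse > 0) s2g / (s2g + mse) else 0
  structure(list(sigma2_g = s2g, sigma2_e = mse, H2 = h2, r_bar = r_bar),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H2 = %.4f  (sigma2_g = %.4g, sigma2_e = %.4g, r_bar = %.2f)\n",
              x$H2, x$sigma2_g, x$sigma2_e, x$r_bar))
  invisible(x)
}

# Restricted log-likelihood of the ridge ratio lambda = sigma2_e / sigma2_u for
# y = 1*mu + W u + e, evaluated from the spectral decomposition of W W' on the
# space of contrasts orthogonal to the intercept. `d` are eigenvalues, `z2`
# the squared transformed contrasts.
reml_loglik_lambda <- function(lambda, d, z2) {
  v <- d + lambda
  n <- length(d)
  s2u <- sum(z2 / v) / n
  -0.5 * (n * log(s2u) + sum(log(v)) + n)
}

#' Ridge-regression BLUP of additive marker effects
#'
#' Solves `(W'W + lambda I) u = W'(y - mu)` with `W` the column-centred
#' major-allele dosage matrix and `mu = mean(y)`. The shrinkage ratio
#' `lambda = sigma2_e / sigma2_u` can be given directly or estimated by
#' maximising the restricted likelihood of the equivalent single-variance-
#' component model over a log-spaced grid (refined by golden-section search).
#'
#' @param panel a [haplotype_panel()].
#' @param blues numeric vector of adjusted phenotypes, one per panel
#'   individual (in panel order, or named by individual id).
#' @param lambda positive ridge ratio, or `"reml"` (default) to estimate it.
#' @param grid log10 range and resolution of the REML grid.
#' @return A list of class `rrblup_fit` with elements `effects` (a
#'   [marker_effects()]), `lambda`, and `gebv` (fitted genomic values).
#' @export
fit_rrblup <- function(panel, blues, lambda = "reml",
                       grid = list(from = -4, to = 8, length = 61)) {
  stopifnot(inherits(panel, "haplotype_panel"))
  N <- dim(panel$alleles)[1]
  if (N < 2L) stop("degenerate error: need N >= 2 individuals")
  if (!is.null(names(blues))) blues <- blues[panel$individual_id]
  if (length(blues) != N || anyNA(blues)) stop("blues must align with panel individuals")
  y <- as.numeric(blues)
  D <- dosage_matrix(panel)
  W <- scale(D, center = TRUE, scale = FALSE)
  mu <- mean(y)
  yc <- y - mu
  if (identical(lambda, "reml")) {
    K <- tcrossprod(W)  # N x N
    eg <- eigen(K, symmetric = TRUE)
    # drop the contrast aligned with the intercept (K %*% 1 = 0 exactly since
    # W is column-centred): it carries no information about the ratio
    ones <- rep(1 / sqrt(N), N)
    align <- abs(crossprod(eg$vectors, ones))
    drop_i <- which.max(align)
    keep <- setdiff(seq_len(N), drop_i)
    d <- pmax(eg$values[keep], 0)
    z2 <- as.numeric(crossprod(eg$vectors[, keep, drop = FALSE], yc))^2
    lg <- 10^seq(grid$from, grid$to, length.out = grid$length)
    ll <- vapply(lg, reml_loglik_lambda, 0, d = d, z2 = z2)
    i <- which.max(ll)
    lo <- lg[max(1, i - 1)]; hi <- lg[min(length(lg), i + 1)]
    opt <- stats::optimize(function(l10) reml_loglik_lambda(10^l10, d, z2),
                           c(log10(lo), log10(hi)), maximum = TRUE)
    lambda <- 10^opt$maximum
  } else {
    lambda <- as.numeric(lambda)
    if (!is.finite(lambda) || lambda < 0) stop("parameter error: lambda must be >= 0")
  }
  M <- ncol(W)
  if (M <= N) {
    u <- solve(crossprod(W) + diag(lambda, M), crossprod(W, yc))
  } else {
    # dual form: u = W' (WW' + lambda I)^-1 yc, cheaper when M > N
    u <- crossprod(W, solve(tcrossprod(W) + diag(lambda, N), yc))
  }
  eff <- marker_effects(mu, as.numeric(u), panel$map$marker_id)
  structure(list(effects = eff, lambda = lambda,
                 gebv = gebv(panel, eff)),
            class = "rrblup_fit")
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat(sprintf("rrblup_fit: %d marker effects, lambda = %.4g, intercept = %.4g\n",
              length(x$effects$effect), x$lambda, x$effects$intercept))
  invisible(x)
}

#' @export
coef.rrblup_fit <- function(object, ...) {
  c(`(Intercept)` = object$effects$intercept, object$effects$effect)
}

#' @export
predict.rrblup_fit <- function(object, panel, ...) {
  gebv(panel, object$effects)
}

#' Genomic estimated breeding values
#'
#' `intercept + dosage %*% effect` for every individual in the panel.
#'
#' @param panel a [haplotype_panel()].
#' @param effects a [marker_effects()] aligned with the panel.
#' @return Named numeric vector of GEBVs.
#' @export
gebv <- function(panel, effects) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(effects, "marker_effects"))
  check_effects_alignment(panel, effects)
  D <- dosage_matrix(panel)
  stats::setNames(as.numeric(effects$intercept + D %*% effects$effect),
                  panel$individual_id)
}

#' Orient marker effects so that maximisation is always desirable
#'
#' All group-fitness functions in this package maximise. For traits scored so
#' that low is good (e.g. disease infection on a 1-9 scale, where resistance
#' means a low score), the additive effects are negated — the intercept is left
#' untouched — so downstream fitness maximisation favours low trait values.
#' Applying the transform twice restores the input.
#'
#' @param effects a [marker_effects()].
#' @param direction `"maximize"` (identity) or `"minimize"` (negate effects).
#' @return A [marker_effects()].
#' @export
desirability_transform <- function(effects, direction = c("minimize", "maximize")) {
  stopifnot(inherits(effects, "marker_effects"))
  direction <- match.arg(direction)
  if (direction == "maximize") return(effects)
  marker_effects(effects$intercept, -effects$effect, names(effects$effect))
}
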