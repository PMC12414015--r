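# Normalised convergence analysis: min-max scaled traces, area under the
# convergence curve, selected-set overlap tables, and multi-run grids.

#' Min-max normalise a convergence trace
#'
#' Iterations are scaled to `[0, 1]`; the best-so-far fitness series (the
#' cumulative maximum of the recorded best fitness) is min-max scaled to
#' `[0, 1]` within the trace. A constant-fitness trace maps to `y == 1` by
#' convention: such a run sits at its best from the first record.
#'
#' @param trace a `gb_trace` or a data.frame with columns `iteration` and
#'   `best_fitness` (>= 2 rows, non-constant iteration axis).
#' @return A data.frame of class `normalized_trace` with columns `x`, `y`.
#' @export
normalize_trace <- function(trace) {
  if (inherits(trace, "gb_trace")) trace <- trace$trace
  if (nrow(trace) < 2L) stop("degenerate error: need >= 2 trace points")
  it <- trace$iteration
  if (max(it) == min(it)) stop("degenerate error: constant iteration axis")
  b <- cummax(trace$best_fitness)
  x <- (it - min(it)) / (max(it) - min(it))
  y <- if (max(b) == min(b)) rep(1, length(b)) else (b - min(b)) / (max(b) - min(b))
  structure(data.frame(x = x, y = y), class = c("normalized_trace", "data.frame"))
}

#' Area under the normalised convergence curve
#'
#' Trapezoidal integral of normalised best-so-far fitness over normalised
#' iteration; 1 means the run was at its eventual best from the first record,
#' values near 0 mean all improvement came at the very end.
#'
#' @param nt a [normalize_trace()] result.
#' @return AUC in `[0, 1]`.
#' @export
convergence_auc <- function(nt) {
  stopifnot(inherits(nt, "normalized_trace"))
  x <- nt$x; y <- nt$y
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Intersection structure of selected founder sets
#'
#' For two or more named id-sets, returns the size of every non-empty region
#' of the Venn partition (labelled by the `&`-joined member names, in a
#' deterministic order) and the pairwise intersection-size matrix.
#'
#' @param selections named list (>= 2) of id vectors.
#' @return List with `regions` (data.frame: `region`, `size`) and `pairwise`
#'   (matrix of intersection sizes; diagonal = set sizes).
#' @export
overlap_table <- function(selections) {
  if (length(selections) < 2L) stop("need >= 2 sets")
  if (is.null(names(selections)) || any(names(selections) == ""))
    names(selections) <- paste0("set", seq_along(selections))
  sets <- lapply(selections, unique)
  nm <- names(sets)
  uni <- unique(unlist(sets))
  memb <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  memb <- matrix(memb, nrow = length(uni), dimnames = list(NULL, nm))
  key <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  sizes <- table(key)
  # order regions by number of member sets then label
  ord <- order(vapply(strsplit(names(sizes), "&", fixed = TRUE), length, 0L),
               names(sizes))
  regions <- data.frame(region = names(sizes)[ord],
                        size = as.integer(sizes)[ord],
                        stringsAsFactors = FALSE)
  pw <- outer(seq_along(sets), seq_along(sets),
              Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pw) <- list(nm, nm)
  list(regions = regions, pairwise = pw)
}

#' Run a benchmark grid of optimizer configurations
#'
#' Runs every configuration at every seed on one problem and tabulates final
#' fitness, convergence AUC and elapsed wall time. Identical (config, seed)
#' pairs would collide and are rejected.
#'
#' @param problem a [selection_problem()].
#' @param configs named list; each element is either a configuration object
#'   (class `gb_config`) or a list `list(algorithm =, config =)`.
#' @param seeds integer vector of seeds to run each configuration at.
#' @return data.frame with one row per (config, seed): `config_id`,
#'   `algorithm`, `seed`, `final_fitness`, `auc`, `elapsed_seconds`.
#' @export
benchmark_grid <- function(problem, configs, seeds) {
  if (is.null(names(configs)) || anyDuplicated(names(configs)))
    stop("collision error: configs must have unique names")
  if (anyDuplicated(seeds)) stop("collision error: duplicate seeds")
  rows <- list()
  for (cid in names(configs)) {
    entry <- configs[[cid]]
    if (inherits(entry, "gb_config")) {
      algo <- sub("_config$", "", class(entry)[1])
      cfg <- entry
    } else {
      algo <- entry$algorithm
      cfg <- entry$config
    }
    for (s in seeds) {
      tr <- select_founders(problem, algo, cfg, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        config_id = cid, algorithm = algo, seed = s,
        final_fitness = tr$final_fitness,
        auc = convergence_auc(normalize_trace(tr)),
        elapsed_seconds = utils::tail(tr$trace$elapsed_seconds, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
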