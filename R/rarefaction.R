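#' Rarefied value of a diversity metric
#'
#' Draws `reps` uniform subsamples of `m` compounds without replacement from
#' a region group, evaluates the metric on each subsample, and returns the
#' mean over subsamples where the metric is defined. Subsampling to a common
#' size puts groups of very different sampling effort on one footing; the
#' default `m = 7` equals the number of NPClassifier pathways, the smallest
#' size at which every pathway could in principle appear.
#'
#' Metric values that are undefined on a subsample (e.g. Pielou J when a
#' subsample hits a single pathway) are excluded from the mean; the fraction
#' of such null replicates is attached as attribute `null_fraction`. If all
#' replicates are null the result is `NA` with a warning.
#'
#' @param group A `"region_group"` with at least `m` compounds.
#' @param metric Function `region_group -> numeric(1)`, e.g.
#'   `function(g) compound_diversity(g)$FAD` or `function(g) pielou(g$pathways)`.
#' @param m Subsample size (default 7; must be at least 2).
#' @param reps Number of subsamples (default 1000).
#' @param seed Optional integer seed giving a reproducible, caller-isolated
#'   random stream.
#' @return Mean metric value over non-null subsamples, with attribute
#'   `null_fraction`.
#' @seealso [rarefy_group()] for the fast all-metrics-at-once version used
#'   by the pipeline.
#' @export
rarefied_metric <- function(group, metric, m = 7L, reps = 1000L,
                            seed = NULL) {
  stopifnot(m >= 2L, reps >= 1L)
  N <- length(group$structures)
  if (N < m)
    stop("group ", group$region, " has ", N, " compounds, fewer than the ",
         "subsample size m = ", m)
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(N, m)
      metric(subset_group(group, idx))
    }, numeric(1))
  })
  finish_rarefied(vals, paste0("metric on group ", group$region))
}

subset_group <- function(group, idx) {
  structure(list(
    region = group$region,
    structures = group$structures[idx],
    pathways = group$pathways[idx],
    fingerprints = group$fingerprints[idx],
    species = group$species),
    class = "region_group")
}

finish_rarefied <- function(vals, what) {
  ok <- !is.na(vals)
  if (!any(ok)) {
    warning("all rarefaction replicates undefined for ", what, call. = FALSE)
    out <- NA_real_
  } else out <- mean(vals[ok])
  attr(out, "null_fraction") <- mean(!ok)
  out
}

#' Rarefied values of all diversity metrics of a group
#'
#' The pipeline workhorse: draws one shared set of subsamples and evaluates
#' every compound-level and pathway-level metric on each, so all rarefied
#' metrics of a region are estimated from the same subsamples (sharing
#' subsamples across metrics is cheaper than redrawing and introduces no
#' bias in the means). Distances are looked up in one precomputed matrix, so
#' each replicate costs a submatrix sum plus a tabulation.
#'
#' @param group A `"region_group"` with at least `m` compounds.
#' @param m,reps,seed As in [rarefied_metric()].
#' @param D Optional precomputed Tanimoto distance matrix of the group.
#' @return Named numeric vector with elements `FAD`, `MFAD`, `APWD`, `H`,
#'   `Hbc`, `G`, `J` (means over non-null subsamples), with attribute
#'   `null_fraction` (named vector of per-metric null-replicate fractions).
#' @export
rarefy_group <- function(group, m = 7L, reps = 1000L, seed = NULL, D = NULL) {
  stopifnot(m >= 2L, reps >= 1L)
  N <- length(group$structures)
  if (N < m)
    stop("group ", group$region, " has ", N, " compounds, fewer than the ",
         "subsample size m = ", m)
  if (is.null(D)) D <- tanimoto_matrix(group$fingerprints)
  metric_names <- c("FAD", "MFAD", "APWD", "H", "Hbc", "G", "J")
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(N, m)
      fad <- sum(D[idx, idx])
      pw <- pathway_metric_row(group$pathways[idx])
      c(FAD = fad, MFAD = fad / m, APWD = fad / (m^2 - m),
        H = pw[["H"]], Hbc = pw[["Hbc"]], G = pw[["G"]], J = pw[["J"]])
    }, numeric(7))
  })
  out <- apply(vals, 1L, function(v) mean(v, na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  nulls <- apply(vals, 1L, function(v) mean(is.na(v)))
  if (any(is.na(out)))
    warning("all rarefaction replicates undefined for metric(s) ",
            paste(metric_names[is.na(out)], collapse = ", "),
            " on group ", group$region, call. = FALSE)
  attr(out, "null_fraction") <- nulls
  out
}
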