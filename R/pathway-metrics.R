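#' Pathway abundance summary for a compound group
#'
#' Collapses a group's compounds onto the seven NPClassifier biosynthetic
#' pathways and records the quantities all pathway-level metrics are built
#' from: per-pathway counts, total `N`, number of apparent pathways `P`,
#' relative abundances `p`, and the singleton count `f1` (pathways
#' represented by exactly one compound), which drives the sample-coverage
#' estimate.
#'
#' @param x Either a character vector of pathway labels (one per compound)
#'   or a named numeric vector of per-pathway counts.
#' @return A list of class `"pathway_counts"` with elements `counts`, `N`,
#'   `P`, `p`, `f1`.
#' @export
#' @examples
#' pc <- pathway_counts(c("alkaloids", "alkaloids", "terpenoids"))
#' shannon(pc); pielou(pc)
pathway_counts <- function(x) {
  if (is.character(x) || is.factor(x)) {
    counts <- table(as.character(x))
    counts <- setNames(as.numeric(counts), names(counts))
  } else if (is.numeric(x)) {
    counts <- x
    if (is.null(names(counts)))
      names(counts) <- paste0("class", seq_along(counts))
    if (any(counts < 0) || any(counts != floor(counts)))
      stop("counts must be non-negative integers")
  } else stop("x must be a vector of labels or of counts")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 1) stop("pathway_counts needs at least one compound")
  structure(list(
    counts = counts,
    N = N,
    P = length(counts),
    p = counts / N,
    f1 = sum(counts == 1)),
    class = "pathway_counts")
}

as_pathway_counts <- function(x) {
  if (inherits(x, "pathway_counts")) x else pathway_counts(x)
}

#' Shannon entropy of pathway abundances
#'
#' `H = -sum(p_i * log(p_i))` over pathways with positive abundance, in nats.
#' Ranges from 0 (one pathway) to `log(P)` (uniform abundances).
#'
#' @param pc A [pathway_counts()] object (or a vector coercible to one).
#' @return Shannon index H (numeric).
#' @export
shannon <- function(pc) {
  pc <- as_pathway_counts(pc)
  -sum(pc$p * log(pc$p))
}

#' Estimated sample coverage of a pathway sample
#'
#' `C = 1 - f1 / N`: one minus the fraction of compounds whose pathway is a
#' singleton. Low coverage signals that many pathways are observed only
#' once, i.e. the sample likely misses pathway mass.
#'
#' @inheritParams shannon
#' @return Coverage in `[0, 1]`.
#' @export
sample_coverage <- function(pc) {
  pc <- as_pathway_counts(pc)
  1 - pc$f1 / pc$N
}

#' Bias-controlled Shannon entropy (coverage-adjusted estimator)
#'
#' The Chao-Shen-style entropy estimator that shrinks abundances by the
#' estimated sample coverage `C` and reweights by the probability that each
#' pathway appears at least once in a sample of size `N`:
#' `Hbc = -sum( p_i C * log(p_i C) / (1 - (1 - p_i C)^N) )`.
#' When every pathway is a singleton, `C = 0` and the estimator degenerates;
#' `NA` is returned with a warning so the region keeps an explicit missing
#' cell rather than a spurious number.
#'
#' @inheritParams shannon
#' @return Hbc (numeric), or `NA` when coverage is zero.
#' @export
shannon_bc <- function(pc) {
  pc <- as_pathway_counts(pc)
  C <- 1 - pc$f1 / pc$N
  if (C == 0) {
    warning("sample coverage is 0 (all pathways singletons); Hbc undefined",
            call. = FALSE)
    return(NA_real_)
  }
  pC <- pc$p * C
  terms <- pC * log(pC) / (1 - (1 - pC)^pc$N)
  # p_i C == 1 only when P == 1 and C == 1: the term is 0 by the
  # x log x -> 0 limit but evaluates 0/0 numerically
  terms[pC == 1] <- 0
  -sum(terms)
}

#' Gini-Simpson diversity of pathway abundances
#'
#' `G = 1 - sum(p_i^2)`: the probability that two compounds drawn at random
#' come from different pathways. 0 for a single pathway, at most `1 - 1/P`.
#'
#' @inheritParams shannon
#' @return G in `[0, 1)`.
#' @export
gini_simpson <- function(pc) {
  pc <- as_pathway_counts(pc)
  1 - sum(pc$p^2)
}

#' Pielou evenness of pathway abundances
#'
#' `J = H / log(P)`: Shannon entropy relative to its maximum, a pure
#' evenness measure in `[0, 1]`. Undefined when only one pathway is present
#' (`P = 1`), in which case `NA` is returned.
#'
#' @inheritParams shannon
#' @return J in `[0, 1]`, or `NA` when `P = 1`.
#' @export
pielou <- function(pc) {
  pc <- as_pathway_counts(pc)
  if (pc$P == 1L) return(NA_real_)
  shannon(pc) / log(pc$P)
}

# All pathway metrics of one label vector at once (single tabulation);
# used by the rarefaction and pipeline hot paths.
pathway_metric_row <- function(labels) {
  pc <- pathway_counts(labels)
  H <- shannon(pc)
  c(H = H,
    Hbc = suppressWarnings(shannon_bc(pc)),
    C = sample_coverage(pc),
    G = gini_simpson(pc),
    J = if (pc$P == 1L) NA_real_ else H / log(pc$P))
}
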