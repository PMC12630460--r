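#' Parse a rooted phylogeny from Newick text or file
#'
#' A thin, validating wrapper around [ape::read.tree()]. Polytomies are
#' preserved. Trees with no (or partially missing) branch lengths get zero
#' lengths with a warning; duplicated leaf labels are a hard error because
#' species sets are matched by name.
#'
#' @param x Newick string or path to a Newick file.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
parse_newick <- function(x) {
  tree <- if (length(x) == 1L && file.exists(x)) ape::read.tree(x)
          else ape::read.tree(text = x)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of branch lengths of the minimal subtree spanning the species present
#' in the tree. By default the subtree is rooted at the species' most recent
#' common ancestor (MRCA), so a single species has PD 0; with
#' `include_root = TRUE` the path from the tree root down to the MRCA is
#' included as well.
#'
#' Implementation: each retained leaf contributes its root path (edge set);
#' PD is the total length of the union of these paths minus, under the MRCA
#' convention, the length of their intersection (the shared MRCA-to-root
#' stem).
#'
#' @param tree A `"phylo"` object.
#' @param species Character vector of species names; names absent from the
#'   tree are dropped with a message giving the count.
#' @param include_root Include the root-to-MRCA stem (default FALSE).
#' @return Faith's PD (numeric); `NA` with a warning if no species matches
#'   the tree.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))       # 2
#' faith_pd(tr, c("A", "B", "C"))  # 5
faith_pd <- function(tree, species, include_root = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  tips <- match(unique(species), tree$tip.label)
  n_missing <- sum(is.na(tips))
  if (n_missing > 0)
    message(n_missing, " species not in the tree; dropped from PD")
  tips <- tips[!is.na(tips)]
  if (!length(tips)) {
    warning("no species in common with the tree; PD undefined",
            call. = FALSE)
    return(NA_real_)
  }
  # edge index leading into each node (NA for the root)
  edge_to <- match(seq_len(max(tree$edge)), tree$edge[, 2L])
  paths <- lapply(tips, function(tip) {
    path <- integer(0)
    node <- tip
    repeat {
      e <- edge_to[node]
      if (is.na(e)) break
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    path
  })
  union_edges <- Reduce(union, paths)
  total <- sum(tree$edge.length[union_edges])
  if (!include_root) {
    stem <- Reduce(intersect, paths)
    total <- total - sum(tree$edge.length[stem])
  }
  total
}

# Fitted LOWESS values at the observed x, averaging over tied x so records
# sharing an x value share a fitted value.
lowess_fitted <- function(x, y, frac = 2/3, iters = 3L) {
  fit <- lowess(x, y, f = frac, iter = iters)
  ux <- unique(fit$x)
  if (length(ux) == 1L) return(rep(mean(fit$y), length(x)))
  approx(fit$x, fit$y, xout = x, ties = mean, rule = 2)$y
}

#' Species-richness-independent phylogenetic diversity
#'
#' PD and species richness (SR) are strongly coupled: regions holding more
#' species accumulate more branch length. To isolate the PD signal not
#' explained by SR, a robust LOWESS curve (local linear fits with
#' robustifying iterations) of PD on SR is fitted across regions and the
#' residual `PD - fitted(SR)` is reported as `PD_resid`.
#'
#' @param records Data frame with numeric columns `SR` and `PD` (extra
#'   columns pass through); at least 10 complete rows are required — LOWESS
#'   residuals on fewer points are dominated by the fit's own noise.
#' @param frac LOWESS smoothing fraction (default 2/3).
#' @param iters Robustifying iterations (default 3).
#' @return `records` with a `PD_resid` column added (NA where SR or PD is
#'   missing).
#' @export
sr_independent_pd <- function(records, frac = 2/3, iters = 3L) {
  stopifnot(is.data.frame(records), all(c("SR", "PD") %in% names(records)))
  ok <- is.finite(records$SR) & is.finite(records$PD)
  if (sum(ok) < 10L)
    stop("need at least 10 complete (SR, PD) records to residualize PD; ",
         "got ", sum(ok))
  fitted <- lowess_fitted(records$SR[ok], records$PD[ok], frac, iters)
  records$PD_resid <- NA_real_
  records$PD_resid[ok] <- records$PD[ok] - fitted
  records
}
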