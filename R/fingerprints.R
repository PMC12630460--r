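#' Binary molecular fingerprint
#'
#' A fingerprint is a set of "on" bit indices in a bit space of size
#' `n_bits`. Bit indices are zero-based, matching the convention of the
#' cheminformatics toolkits that produce hashed fingerprints.
#'
#' @param bits Integer vector of set bit indices (0-based); duplicates are
#'   collapsed. May be empty, in which case a warning is emitted (an empty
#'   fingerprint carries no structural information).
#' @param n_bits Size of the bit space (default 2048).
#' @return An object of class `"fingerprint"`: a list with elements `bits`
#'   (sorted integer vector) and `n_bits`.
#' @export
#' @examples
#' fingerprint(c(4, 17, 130))
fingerprint <- function(bits, n_bits = 2048L) {
  n_bits <- as.integer(n_bits)
  bits <- sort(unique(as.integer(bits)))
  if (anyNA(bits)) stop("fingerprint bits must not contain NA")
  if (length(bits) && (bits[1L] < 0L || bits[length(bits)] >= n_bits))
    stop("fingerprint bit indices must lie in [0, n_bits)")
  if (!length(bits))
    warning("empty fingerprint (no bits set)", call. = FALSE)
  structure(list(bits = bits, n_bits = n_bits), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", length(x$bits), " of ", x$n_bits, " bits set\n",
      sep = "")
  invisible(x)
}

#' Tanimoto (Jaccard) distance between two fingerprints
#'
#' Returns `1 - |A intersect B| / |A union B|` on the sets of "on" bits: 0
#' for identical fingerprints, 1 for fingerprints sharing no bits. Two empty
#' fingerprints are defined to be at distance 0 (with a warning), since
#' nothing distinguishes them.
#'
#' @param a,b `fingerprint` objects with equal `n_bits`.
#' @return A single numeric distance in `[0, 1]`.
#' @seealso [tanimoto_matrix()] for all pairwise distances of a group.
#' @export
#' @examples
#' tanimoto_distance(fingerprint(c(1, 2, 3)), fingerprint(c(3, 4)))  # 0.75
tanimoto_distance <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits)
    stop("fingerprints live in different bit spaces (n_bits differ)")
  u <- length(union(a$bits, b$bits))
  if (u == 0L) {
    warning("Tanimoto distance between two empty fingerprints defined as 0",
            call. = FALSE)
    return(0)
  }
  1 - length(intersect(a$bits, b$bits)) / u
}

#' Pairwise Tanimoto distance matrix
#'
#' Computes the full symmetric matrix of Tanimoto distances for a list of
#' fingerprints. Intersection counts are obtained from a sparse 0/1
#' incidence matrix cross-product, so groups of a few thousand compounds are
#' handled quickly; the dense N x N result is the only O(N^2) object.
#'
#' @param fps List of `fingerprint` objects sharing one `n_bits`.
#' @param labels Optional character labels (e.g. structure strings) used as
#'   dimnames.
#' @return Numeric N x N matrix, symmetric with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
tanimoto_matrix <- function(fps, labels = NULL) {
  stopifnot(is.list(fps), length(fps) >= 1L)
  n_bits <- unique(vapply(fps, function(f) f$n_bits, integer(1)))
  if (length(n_bits) != 1L)
    stop("all fingerprints must share one n_bits")
  sizes <- vapply(fps, function(f) length(f$bits), integer(1))
  n <- length(fps)
  if (any(sizes == 0L))
    warning(sum(sizes == 0L), " empty fingerprint(s) in group; distances ",
            "involving them default to 1 (0 between two empty ones)",
            call. = FALSE)
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), sizes),
    j = unlist(lapply(fps, `[[`, "bits"), use.names = FALSE) + 1L,
    x = 1,
    dims = c(n, n_bits))
  inter <- as.matrix(Matrix::tcrossprod(inc))
  uni <- outer(sizes, sizes, `+`) - inter
  d <- ifelse(uni > 0, 1 - inter / uni, 0)
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

#' Structure-hashing fingerprinter
#'
#' Returns a function mapping structure strings to deterministic pseudo-random
#' fingerprints derived from a hash of the string. Identical structures always
#' receive identical fingerprints, and distinct structures receive
#' (with high probability) well-separated bit sets. This backend carries no
#' chemical information: it is intended for synthetic structure identifiers
#' and for exercising the pipeline without a chemistry toolkit. Supply your
#' own fingerprinter (e.g. hashed circular fingerprints from a
#' cheminformatics backend) for real structures.
#'
#' @param n_bits Bit-space size (default 2048).
#' @param n_set Number of bits drawn per structure before deduplication
#'   (default 64); the realised count can be slightly lower due to hash
#'   collisions.
#' @return A function `character -> list of fingerprint`.
#' @export
#' @examples
#' fp <- hash_fingerprinter()(c("SYN-000001", "SYN-000002"))
#' tanimoto_distance(fp[[1]], fp[[2]])
hash_fingerprinter <- function(n_bits = 2048L, n_set = 64L) {
  force(n_bits); force(n_set)
  function(structures) {
    out <- lapply(structures, function(s) {
      state <- string_hash(s)
      bits <- numeric(n_set)
      for (k in seq_len(n_set)) {
        # small-multiplier LCG: products stay below 2^53, exact in doubles
        state <- (69069 * state + 1) %% 2147483647
        bits[k] <- state %% n_bits
      }
      fingerprint(unique(bits), n_bits = n_bits)
    })
    names(out) <- structures
    out
  }
}
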