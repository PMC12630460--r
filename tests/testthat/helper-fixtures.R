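# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A region group with random sparse fingerprints and random pathway labels.
random_group <- function(n, n_bits = 256L, bits_per = 24L,
                         pathways = npc_pathways(), region = "FIJ") {
  structs <- sprintf("CMP-%04d", seq_len(n))
  fps <- lapply(seq_len(n), function(i)
    fingerprint(sample.int(n_bits, bits_per) - 1L, n_bits = n_bits))
  names(fps) <- structs
  structure(list(region = region,
                 structures = structs,
                 pathways = sample(pathways, n, replace = TRUE),
                 fingerprints = fps,
                 species = sprintf("Species_%02d", 1:3)),
            class = "region_group")
}

# Independent brute-force oracle for FAD: explicit double loop over all
# ordered pairs (diagonal included; it contributes 0).
brute_force_fad <- function(fps) {
  n <- length(fps)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) total <- total + tanimoto_distance(fps[[i]], fps[[j]])
  }
  total
}

# Independent brute-force oracle for Faith PD: mark every edge on each
# leaf-to-root path with ape::nodepath, then sum marked lengths, subtracting
# the MRCA-to-root stem unless include_root.
brute_force_pd <- function(tree, species, include_root = FALSE) {
  tips <- match(species, tree$tip.label)
  tips <- tips[!is.na(tips)]
  if (!length(tips)) return(NA_real_)
  root <- length(tree$tip.label) + 1L
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  mark <- function(path_nodes) {
    keys <- paste(path_nodes[-length(path_nodes)], path_nodes[-1L])
    match(keys, edge_key)
  }
  paths <- lapply(tips, function(t) mark(ape::nodepath(tree, root, t)))
  marked <- unique(unlist(paths))
  total <- sum(tree$edge.length[marked])
  if (!include_root && length(tips) >= 1L) {
    shared <- Reduce(intersect, paths)
    total <- total - sum(tree$edge.length[shared])
  }
  total
}

# A random non-degenerate pathway count vector.
random_counts <- function(max_classes = 7L, max_count = 30L) {
  P <- sample(1:max_classes, 1L)
  setNames(sample.int(max_count, P, replace = TRUE),
           sample(npc_pathways(), P))
}
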