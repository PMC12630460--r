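#' Standardize structure strings to their parent fragment
#'
#' Reduces multi-fragment structure strings (dot-separated components, e.g.
#' salts or solvates) to the single fragment with the most heavy atoms, then
#' optionally canonicalizes it with a pluggable chemistry backend. Ties on
#' heavy-atom count are broken by the lexicographically smallest
#' (canonicalized) fragment so the result is deterministic. The operation is
#' idempotent: standardizing an already standardized string returns it
#' unchanged.
#'
#' Inputs that cannot be interpreted (empty strings, `NA`) yield `NA` with a
#' warning rather than an error, so a malformed record never aborts a batch.
#'
#' @param x Character vector of structure strings (SMILES or synthetic
#'   structure identifiers; identifiers contain no `.` and pass through
#'   unchanged).
#' @param canonicalize Optional function `character -> character` applied to
#'   fragments for tie-breaking and to the selected fragment. Defaults to the
#'   identity, so the package has no hard chemistry dependency; see
#'   [ob_canonicalizer()] for an Open Babel backend.
#' @return Character vector of standardized structures (`NA` where the input
#'   was rejected).
#' @export
#' @examples
#' standardize_structure("CCO.Cl")               # "CCO"
#' standardize_structure("[Na+].CC(=O)[O-]")     # "CC(=O)[O-]"
standardize_structure <- function(x, canonicalize = NULL) {
  canon <- if (is.null(canonicalize)) identity else canonicalize
  out <- vapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1L]]
    frags <- frags[nzchar(frags)]
    if (!length(frags)) return(NA_character_)
    res <- tryCatch({
      counts <- vapply(frags, heavy_atom_count, numeric(1))
      best <- frags[counts == max(counts)]
      best <- canon(best)
      sort(best)[1L]
    }, error = function(e) NA_character_)
    res
  }, character(1), USE.NAMES = FALSE)
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    warning(sum(bad), " structure string(s) could not be standardized; ",
            "records rejected (NA)", call. = FALSE)
  out
}

#' Count heavy (non-hydrogen) atoms in a SMILES fragment
#'
#' Bracket atoms `[...]` count as one heavy atom unless the bracket encodes a
#' hydrogen (e.g. `[H]`, `[2H]`, `[H+]`). Outside brackets, two-letter organic
#' subset symbols (`Cl`, `Br`) are counted before single-letter ones
#' (`B C N O S P F I` and their aromatic forms). Strings that are plain
#' identifiers rather than SMILES simply count their letter symbols, which is
#' harmless: the count is only used to rank fragments within one input.
#'
#' @param frag A single-fragment structure string.
#' @return Number of heavy atoms (numeric).
#' @keywords internal
#' @export
heavy_atom_count <- function(frag) {
  stopifnot(is.character(frag), length(frag) == 1L)
  n <- 0
  m <- gregexpr("\\[[^]]*\\]", frag)[[1L]]
  if (m[1L] != -1L) {
    brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1L]]
    is_h <- grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", brackets)
    n <- n + sum(!is_h)
    frag <- gsub("\\[[^]]*\\]", "", frag)
  }
  n <- n + lengths(regmatches(frag, gregexpr("Cl|Br", frag)))
  frag <- gsub("Cl|Br", "", frag)
  n + lengths(regmatches(frag, gregexpr("[BCNOSPFIbcnosp]", frag)))
}

#' Open Babel canonicalization backend
#'
#' Returns a `character -> character` function suitable for the
#' `canonicalize` argument of [standardize_structure()], backed by the
#' ChemmineOB interface to Open Babel. Strings Open Babel cannot parse map to
#' `NA` (the caller then rejects the record with a warning). Requires the
#' suggested ChemmineOB package.
#'
#' @return A canonicalization function.
#' @export
ob_canonicalizer <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("the ChemmineOB package is required for ob_canonicalizer()")
  function(x) {
    vapply(x, function(s) {
      out <- tryCatch(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
        error = function(e) "")
      out <- sub("[\t\n ].*$", "", out)
      if (!nzchar(out)) NA_character_ else out
    }, character(1), USE.NAMES = FALSE)
  }
}

#' Assemble a compound-occurrence table
#'
#' One row per (taxon, structure) record with its biosynthetic pathway and
#' the set of native WGSRPD Level-3 regions the record fans out to
#' (pipe-separated in the `regions` column).
#'
#' @param taxon Character vector of accepted species names.
#' @param structure Character vector of standardized structure strings.
#' @param pathway Character vector; each entry one of [npc_pathways()].
#' @param regions Character vector of pipe-separated region codes (e.g.
#'   `"FIJ|NWG"`), non-empty per record.
#' @return A `data.frame` of class `"compound_occurrences"`.
#' @export
compound_occurrences <- function(taxon, structure, pathway, regions) {
  df <- data.frame(taxon = as.character(taxon),
                   structure = as.character(structure),
                   pathway = as.character(pathway),
                   regions = as.character(regions),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$structure) | is.na(df$structure)))
    stop("empty or NA structure strings are not allowed")
  if (any(!nzchar(df$regions) | is.na(df$regions)))
    stop("every record needs at least one region code")
  bad <- !(df$pathway %in% npc_pathways())
  if (any(bad))
    stop("unknown pathway label(s): ",
         paste(unique(df$pathway[bad]), collapse = ", "))
  class(df) <- c("compound_occurrences", "data.frame")
  df
}

#' Read a compound-occurrence CSV
#'
#' Expects UTF-8 CSV with header columns `taxon,structure,pathway,regions`
#' (regions pipe-separated). Rows with a missing or empty pathway cell are
#' dropped with a message (uncategorised compounds carry no pathway
#' information); rows with a pathway label outside the seven recognised
#' classes are dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @return A `"compound_occurrences"` data frame.
#' @seealso [write_occurrence_table()] for the inverse; the two round-trip.
#' @export
read_occurrence_table <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("taxon", "structure", "pathway", "regions")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("occurrence table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  drop <- is.na(df$pathway) | !nzchar(df$pathway)
  if (any(drop)) {
    message("dropping ", sum(drop), " record(s) with no pathway label")
    df <- df[!drop, , drop = FALSE]
  }
  unknown <- !(df$pathway %in% npc_pathways())
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " record(s) with unrecognised ",
            "pathway label(s): ",
            paste(unique(df$pathway[unknown]), collapse = ", "),
            call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
  }
  rownames(df) <- NULL
  compound_occurrences(df$taxon, df$structure, df$pathway, df$regions)
}

#' Write a compound-occurrence table to CSV
#'
#' @param occ A `"compound_occurrences"` data frame.
#' @param path Output CSV path.
#' @export
write_occurrence_table <- function(occ, path) {
  write.csv(as.data.frame(occ), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a species-to-region distribution CSV
#'
#' @param path CSV with header columns `taxon,region_code`, one row per
#'   (species, native region) pair.
#' @return A data frame with columns `taxon` and `region_code`.
#' @export
read_distribution_table <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("taxon", "region_code")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("distribution table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Group compound occurrences by botanical region
#'
#' Fans each record out to all its native regions and builds one group per
#' region. Within a group compounds are unique by standardized structure
#' (duplicate region-compound pairs collapse); if one structure arrives with
#' two different pathway labels the first is kept and a warning reports the
#' conflict. The group's species set contains every taxon contributing at
#' least one compound to the region.
#'
#' @param occ A `"compound_occurrences"` data frame (structures already
#'   standardized).
#' @param fingerprints Optional named list of [fingerprint()] objects keyed
#'   by structure string. Structures without an entry (or all structures,
#'   when `NULL`) are fingerprinted with `fingerprinter`.
#' @param fingerprinter Function `character -> list of fingerprint` used for
#'   structures lacking a supplied fingerprint (default
#'   [hash_fingerprinter()]).
#' @param validate_regions Check region codes against the bundled WGSRPD
#'   list, warning on unknown codes (default TRUE).
#' @return Named list of `"region_group"` objects, ordered by first
#'   appearance. Each has elements `region`, `structures`, `pathways`,
#'   `fingerprints` (parallel vectors/list) and `species`.
#' @export
build_region_groups <- function(occ, fingerprints = NULL,
                                fingerprinter = hash_fingerprinter(),
                                validate_regions = TRUE) {
  stopifnot(is.data.frame(occ))
  region_list <- strsplit(occ$regions, "|", fixed = TRUE)
  if (validate_regions)
    validate_region_codes(unlist(region_list, use.names = FALSE))

  all_structs <- unique(occ$structure)
  need <- setdiff(all_structs, names(fingerprints))
  if (length(need)) {
    generated <- fingerprinter(need)
    fingerprints <- c(fingerprints, generated)
  }

  lens <- lengths(region_list)
  flat <- data.frame(
    region = unlist(region_list, use.names = FALSE),
    taxon = rep.int(occ$taxon, lens),
    structure = rep.int(occ$structure, lens),
    pathway = rep.int(occ$pathway, lens),
    stringsAsFactors = FALSE)

  conflicts <- character(0)
  groups <- list()
  for (reg in unique(flat$region)) {
    sub <- flat[flat$region == reg, , drop = FALSE]
    first <- !duplicated(sub$structure)
    kept <- sub[first, , drop = FALSE]
    # detect pathway conflicts among the rows collapsed by dedup
    pw_by_struct <- tapply(sub$pathway, sub$structure, function(p) length(unique(p)))
    conflicted <- names(pw_by_struct)[pw_by_struct > 1L]
    if (length(conflicted)) conflicts <- union(conflicts, conflicted)
    groups[[reg]] <- structure(list(
      region = reg,
      structures = kept$structure,
      pathways = kept$pathway,
      fingerprints = fingerprints[kept$structure],
      species = unique(sub$taxon)),
      class = "region_group")
  }
  if (length(conflicts))
    warning("structure(s) with conflicting pathway labels (first label ",
            "kept): ", paste(head(conflicts, 5L), collapse = ", "),
            if (length(conflicts) > 5L) ", ...", call. = FALSE)
  groups
}

#' @export
print.region_group <- function(x, ...) {
  cat("<region_group> ", x$region, ": ", length(x$structures),
      " compounds, ", length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Discard region groups below a minimum compound count
#'
#' Groups smaller than the rarefaction subsample size cannot be rarefied, so
#' the analysis discards them up front (default minimum 7 compounds).
#'
#' @param groups List of `"region_group"` objects.
#' @param min_size Minimum number of unique compounds (default 7).
#' @return The retained groups, original order preserved. Warns if nothing
#'   survives.
#' @export
filter_groups <- function(groups, min_size = 7L) {
  stopifnot(min_size >= 1L)
  keep <- vapply(groups, function(g) length(g$structures) >= min_size,
                 logical(1))
  out <- groups[keep]
  if (!length(out))
    warning("no region group has at least ", min_size, " compounds",
            call. = FALSE)
  out
}

#' Write the per-region diversity table to CSV
#'
#' Missing metric values (e.g. Pielou J where a single pathway is present)
#' serialize as empty cells.
#'
#' @param profiles Data frame of per-region diversity profiles, as returned
#'   by [compute_diversity_profiles()].
#' @param path Output CSV path.
#' @export
write_diversity_table <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-region diversity table written by [write_diversity_table()]
#'
#' @param path CSV path.
#' @return Data frame with `region` as character and all metric columns
#'   numeric (empty cells become `NA`).
#' @export
read_diversity_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$region <- as.character(df$region)
  df
}
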