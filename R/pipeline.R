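#' Compute per-region diversity profiles
#'
#' Runs the full metric pipeline: standardize structures, group records by
#' region, drop groups below the minimum size, then compute for each region
#' the compound-level metrics (N, FAD, MFAD, APWD), the pathway-level
#' metrics (H, Hbc, C, G, J), their rarefied counterparts (mean over
#' `rarefy_reps` subsamples of size `rarefy_m`), and — when a tree is
#' supplied — species richness SR, Faith's PD and (with at least 10 regions)
#' the SR-independent PD residual.
#'
#' Each region's rarefaction uses its own random stream derived from the
#' master seed and the region code, so results are independent of region
#' processing order.
#'
#' @param occurrences A `"compound_occurrences"` data frame.
#' @param fingerprints Optional named list of fingerprints by structure;
#'   missing ones come from `fingerprinter`.
#' @param tree Optional `"phylo"` object for SR/PD.
#' @param min_size Minimum compounds per retained region (default 7).
#' @param rarefy_m,rarefy_reps Rarefaction subsample size and replicate
#'   count (defaults 7 and 1000).
#' @param seed Master seed for rarefaction streams (default 1).
#' @param include_root Root convention for [faith_pd()] (default FALSE:
#'   MRCA-spanning).
#' @param lowess_frac,lowess_iters LOWESS settings for
#'   [sr_independent_pd()].
#' @param fingerprinter Fallback fingerprinter, as in
#'   [build_region_groups()].
#' @param canonicalize Structure canonicalization backend passed to
#'   [standardize_structure()] (default identity).
#' @return Data frame with one row per retained region: `region`, `N`,
#'   `SR`, `FAD`, `MFAD`, `APWD`, `H`, `Hbc`, `C`, `G`, `J`, `PD`,
#'   `PD_resid` and the `rarefied_*` columns. Undefined values are `NA`.
#' @export
compute_diversity_profiles <- function(occurrences, fingerprints = NULL,
                                       tree = NULL, min_size = 7L,
                                       rarefy_m = 7L, rarefy_reps = 1000L,
                                       seed = 1L, include_root = FALSE,
                                       lowess_frac = 2/3, lowess_iters = 3L,
                                       fingerprinter = hash_fingerprinter(),
                                       canonicalize = NULL) {
  occ <- occurrences
  occ$structure <- standardize_structure(occ$structure, canonicalize)
  occ <- occ[!is.na(occ$structure), , drop = FALSE]
  groups <- build_region_groups(occ, fingerprints = fingerprints,
                                fingerprinter = fingerprinter)
  groups <- filter_groups(groups, min_size = min_size)
  if (!length(groups)) {
    return(empty_profile_frame())
  }
  rows <- lapply(groups, function(g) {
    D <- tanimoto_matrix(g$fingerprints, labels = g$structures)
    cd <- compound_diversity(g, D = D)
    pw <- pathway_metric_row(g$pathways)
    rare <- rarefy_group(g, m = rarefy_m, reps = rarefy_reps,
                         seed = region_seed(seed, g$region), D = D)
    sr <- NA_real_; pd <- NA_real_
    if (!is.null(tree)) {
      present <- intersect(g$species, tree$tip.label)
      sr <- length(present)
      pd <- if (sr >= 1L) faith_pd(tree, present,
                                   include_root = include_root)
            else NA_real_
    }
    data.frame(region = g$region, N = cd$N, SR = sr,
               FAD = cd$FAD, MFAD = cd$MFAD, APWD = cd$APWD,
               H = pw[["H"]], Hbc = pw[["Hbc"]], C = pw[["C"]],
               G = pw[["G"]], J = pw[["J"]],
               PD = pd, PD_resid = NA_real_,
               rarefied_FAD = rare[["FAD"]],
               rarefied_MFAD = rare[["MFAD"]],
               rarefied_APWD = rare[["APWD"]],
               rarefied_H = rare[["H"]],
               rarefied_Hbc = rare[["Hbc"]],
               rarefied_G = rare[["G"]],
               rarefied_J = rare[["J"]],
               stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(tree) && sum(is.finite(profiles$PD)) >= 10L) {
    profiles <- sr_independent_pd(profiles, frac = lowess_frac,
                                  iters = lowess_iters)
  } else if (!is.null(tree)) {
    message("fewer than 10 regions with PD; skipping SR-independent PD")
  }
  profiles
}

empty_profile_frame <- function() {
  data.frame(region = character(0), N = numeric(0), SR = numeric(0),
             FAD = numeric(0), MFAD = numeric(0), APWD = numeric(0),
             H = numeric(0), Hbc = numeric(0), C = numeric(0),
             G = numeric(0), J = numeric(0), PD = numeric(0),
             PD_resid = numeric(0), rarefied_FAD = numeric(0),
             rarefied_MFAD = numeric(0), rarefied_APWD = numeric(0),
             rarefied_H = numeric(0), rarefied_Hbc = numeric(0),
             rarefied_G = numeric(0), rarefied_J = numeric(0),
             stringsAsFactors = FALSE)
}

#' Association analysis of a diversity table
#'
#' Yeo-Johnson-normalises each variable, computes all pairwise Spearman
#' correlations among the phytochemical metrics and against the phylogenetic
#' variables, and flags outlier regions whose metric departs more than
#' `k` residual SD from its LOWESS trend on PD. Spearman correlations are
#' invariant under the (monotone) normalisation; the transformed scale
#' matters for the LOWESS outlier step, which is why normalisation happens
#' first. Metric columns that are entirely missing are dropped with a
#' warning.
#'
#' @param profiles Data frame from [compute_diversity_profiles()] (at least
#'   10 rows).
#' @param metrics Phytochemical metric columns to analyse.
#' @param targets Phylogenetic/effort columns to correlate against.
#' @param k Outlier threshold in residual SD units (default 2).
#' @param frac,iters LOWESS settings for the outlier fits.
#' @return List with `correlations` (long data frame), `outliers` (data
#'   frame), and `lambdas` (named vector of fitted Yeo-Johnson powers).
#' @export
associate_profiles <- function(profiles,
                               metrics = c("H", "Hbc", "G", "J", "FAD",
                                           "MFAD", "APWD"),
                               targets = c("PD", "SR", "PD_resid"),
                               k = 2, frac = 2/3, iters = 3L) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) < 10L)
    stop("need at least 10 profiles for the association analysis; got ",
         nrow(profiles))
  vars <- intersect(c(metrics, targets), names(profiles))
  all_null <- vapply(vars, function(v) all(!is.finite(profiles[[v]])),
                     logical(1))
  if (any(all_null)) {
    warning("dropping all-null column(s): ",
            paste(vars[all_null], collapse = ", "), call. = FALSE)
    vars <- vars[!all_null]
  }
  transformed <- profiles
  lambdas <- numeric(0)
  for (v in vars) {
    yj <- yeo_johnson(profiles[[v]])
    transformed[[v]] <- yj$y
    lambdas[v] <- yj$lambda
  }
  correlations <- correlation_matrix(transformed, variables = vars)
  out_metrics <- intersect(metrics, vars)
  outliers <- if ("PD" %in% vars) {
    do.call(rbind, lapply(out_metrics, function(mv)
      flag_outliers(transformed, y_var = mv, x_var = "PD", k = k,
                    frac = frac, iters = iters)))
  } else {
    data.frame(region = character(0), metric = character(0),
               residual = numeric(0), z = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  list(correlations = correlations, outliers = outliers, lambdas = lambdas)
}

#' Run the file-based pipeline end to end
#'
#' Reads the standard input files from `input_dir` (as written by
#' [simulate_study()]), computes the diversity table, runs the association
#' analysis, and writes `diversity.csv`, `correlations.csv`, `outliers.csv`
#' and a `run_metadata.json` echoing the resolved settings into
#' `output_dir`. A convenience wrapper: every number it writes is
#' reproducible by calling the underlying functions directly.
#'
#' @param input_dir Directory containing `occurrences.csv`,
#'   `fingerprints.csv` (optional) and `tree.nwk` (optional).
#' @param output_dir Output directory (created if missing).
#' @param min_size,rarefy_m,rarefy_reps,seed,include_root,lowess_frac,lowess_iters,k
#'   Settings as in [compute_diversity_profiles()] and
#'   [associate_profiles()].
#' @return Invisibly, a list with `profiles`, `correlations`, `outliers`.
#' @export
run_pipeline <- function(input_dir, output_dir, min_size = 7L,
                         rarefy_m = 7L, rarefy_reps = 1000L, seed = 1L,
                         include_root = FALSE, lowess_frac = 2/3,
                         lowess_iters = 3L, k = 2) {
  occ <- read_occurrence_table(file.path(input_dir, "occurrences.csv"))
  fp_path <- file.path(input_dir, "fingerprints.csv")
  fps <- if (file.exists(fp_path)) read_fingerprint_table(fp_path) else NULL
  tree_path <- file.path(input_dir, "tree.nwk")
  tree <- if (file.exists(tree_path)) parse_newick(tree_path) else NULL

  profiles <- compute_diversity_profiles(
    occ, fingerprints = fps, tree = tree, min_size = min_size,
    rarefy_m = rarefy_m, rarefy_reps = rarefy_reps, seed = seed,
    include_root = include_root, lowess_frac = lowess_frac,
    lowess_iters = lowess_iters)

  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_diversity_table(profiles, file.path(output_dir, "diversity.csv"))

  assoc <- NULL
  if (nrow(profiles) >= 10L) {
    assoc <- associate_profiles(profiles, k = k)
    write.csv(assoc$correlations, file.path(output_dir, "correlations.csv"),
              row.names = FALSE, na = "")
    write.csv(assoc$outliers, file.path(output_dir, "outliers.csv"),
              row.names = FALSE, na = "")
  } else {
    warning("fewer than 10 retained regions; association analysis skipped",
            call. = FALSE)
  }
  meta <- list(min_size = min_size, rarefy_m = rarefy_m,
               rarefy_reps = rarefy_reps, seed = seed,
               include_root = include_root, lowess_frac = lowess_frac,
               lowess_iters = lowess_iters, outlier_k = k,
               n_regions = nrow(profiles),
               pd_convention = if (include_root) "root" else "mrca")
  jsonlite::write_json(meta, file.path(output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(profiles = profiles,
                 correlations = if (is.null(assoc)) NULL else assoc$correlations,
                 outliers = if (is.null(assoc)) NULL else assoc$outliers))
}
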