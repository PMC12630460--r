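#' Configuration of a synthetic species-compound-region scenario
#'
#' Bundles the knobs of the generator with defaults chosen to resemble
#' compiled phytochemical occurrence data: a heavily right-skewed
#' compounds-per-species distribution (most species contribute 1-3 known
#' compounds, a few contribute over a hundred), seven biosynthetic pathways
#' with strongly uneven global frequencies, botanical regions of very uneven
#' size (large mainland floras and small island floras), and a Yule
#' (pure-birth) phylogeny over the species.
#'
#' @param n_species Number of species (default 500).
#' @param n_regions Number of WGSRPD Level-3 regions drawn from the bundled
#'   code list (default 30).
#' @param n_compounds Size of the global compound library species draw from
#'   (default 3000).
#' @param cps_dist Compounds-per-species distribution: `"logseries"`
#'   (default) or `"ztnb"` (zero-truncated negative binomial).
#' @param cps_theta Log-series shape in (0, 1) (default 0.93: about 61% of
#'   species carry three or fewer compounds, with a strong right skew).
#' @param cps_size,cps_mu Shape and mean of the zero-truncated negative
#'   binomial used when `cps_dist = "ztnb"`.
#' @param pathway_weights Named global pathway mixture (must cover the seven
#'   [npc_pathways()] labels and sum to 1). The default is skewed, with
#'   terpenoids and alkaloids dominating.
#' @param dirichlet_conc Concentration of the per-region Dirichlet draw
#'   around the global mixture; larger values give regions more even,
#'   mixture-like pathway profiles, small values give spiky single-pathway
#'   regions (default 8).
#' @param fp_bits,fp_per_compound Fingerprint bit-space size and bits set
#'   per compound (defaults 2048 and 64).
#' @param extra_region_rate Poisson rate of additional native regions per
#'   species beyond the first (default 0.6).
#' @param region_weight_sdlog Log-SD of the lognormal region weights that
#'   make some regions species-rich and others species-poor (default 1.2).
#' @param birth_rate Yule birth rate of the species tree (default 1).
#' @param seed Master seed; every stream the generator uses derives from it.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_species = 500L, n_regions = 30L,
                            n_compounds = 3000L,
                            cps_dist = c("logseries", "ztnb"),
                            cps_theta = 0.93,
                            cps_size = 0.35, cps_mu = 4,
                            pathway_weights = c(
                              "terpenoids" = 0.30,
                              "alkaloids" = 0.26,
                              "shikimates-phenylpropanoids" = 0.17,
                              "polyketides" = 0.10,
                              "fatty acids" = 0.07,
                              "amino acids/peptides" = 0.06,
                              "carbohydrates" = 0.04),
                            dirichlet_conc = 8,
                            fp_bits = 2048L, fp_per_compound = 64L,
                            extra_region_rate = 0.6,
                            region_weight_sdlog = 1.2,
                            birth_rate = 1,
                            seed = 1L) {
  cps_dist <- match.arg(cps_dist)
  stopifnot(n_species >= 2L, n_regions >= 1L, n_compounds >= 1L,
            cps_theta > 0, cps_theta < 1,
            cps_size > 0, cps_mu > 0, dirichlet_conc > 0,
            fp_bits >= 1L, fp_per_compound >= 1L,
            extra_region_rate >= 0, region_weight_sdlog >= 0,
            birth_rate > 0)
  if (!setequal(names(pathway_weights), npc_pathways()))
    stop("pathway_weights must be named by the seven npc_pathways() labels")
  if (any(pathway_weights < 0) || abs(sum(pathway_weights) - 1) > 1e-8)
    stop("pathway_weights must be non-negative and sum to 1")
  structure(as.list(environment()), class = "scenario_config")
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a global compound library
#'
#' Draws `n_compounds` synthetic compounds, each with a unique synthetic
#' structure identifier (`SYN-xxxxxx`; clearly not a chemical structure), a
#' pathway sampled from the global mixture, and a sparse random fingerprint.
#' Reproducible from the config seed.
#'
#' @param cfg A [scenario_config()].
#' @return List with `compounds` (data frame `structure`, `pathway`) and
#'   `fingerprints` (named list of [fingerprint()]).
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(region_seed(cfg$seed, "library"), {
    structures <- sprintf("SYN-%06d", seq_len(cfg$n_compounds))
    pathways <- sample(names(cfg$pathway_weights), cfg$n_compounds,
                       replace = TRUE, prob = cfg$pathway_weights)
    fingerprints <- lapply(structures, function(s)
      fingerprint(sample.int(cfg$fp_bits, cfg$fp_per_compound) - 1L,
                  n_bits = cfg$fp_bits))
    names(fingerprints) <- structures
    list(compounds = data.frame(structure = structures, pathway = pathways,
                                stringsAsFactors = FALSE),
         fingerprints = fingerprints)
  })
}

# Zero-truncated negative binomial compound counts per species.
r_ztnbinom <- function(n, size, mu) {
  k <- rnbinom(n, size = size, mu = mu)
  while (any(k == 0L)) k[k == 0L] <- rnbinom(sum(k == 0L), size = size, mu = mu)
  k
}

# Log-series counts (Fisher's log-series, support 1, 2, ...): the classic
# model for "most species contribute one to a few compounds, a handful
# contribute many". Sampled by inverse CDF over a truncated support carrying
# all but ~1e-12 of the mass.
r_logseries <- function(n, theta) {
  kmax <- 10L
  repeat {
    pmf <- -theta^(seq_len(kmax)) / (seq_len(kmax) * log(1 - theta))
    if (sum(pmf) > 1 - 1e-12 || kmax > 1e6) break
    kmax <- kmax * 4L
  }
  sample.int(kmax, n, replace = TRUE, prob = pmf)
}

# Compound count per species under the configured distribution.
r_compounds_per_species <- function(n, cfg) {
  if (cfg$cps_dist == "logseries") r_logseries(n, cfg$cps_theta)
  else r_ztnbinom(n, cfg$cps_size, cfg$cps_mu)
}

#' Simulate a complete species-compound-region study
#'
#' Generates every input the pipeline consumes: a compound-occurrence table,
#' a species-to-region distribution table, a fingerprint table for the
#' compounds in play, and a Yule tree over the species. Species are assigned
#' a primary region (probability proportional to lognormal region weights,
#' so region sizes are very uneven) plus a Poisson number of extra native
#' regions; each species' compounds are drawn by first sampling a pathway
#' from its primary region's Dirichlet mixture and then a library compound
#' of that pathway, so compound sharing between species arises naturally and
#' regions differ in pathway evenness.
#'
#' @param cfg A [scenario_config()].
#' @param dir Optional directory; when given, writes `occurrences.csv`,
#'   `distributions.csv`, `fingerprints.csv`, `tree.nwk` and
#'   `scenario.json` there.
#' @return (Invisibly when `dir` is given) a list with elements
#'   `occurrences` (a `"compound_occurrences"` data frame), `distributions`,
#'   `fingerprints` (named list, restricted to compounds that occur),
#'   `tree` (`"phylo"`), `region_mixtures` (matrix), and `config`.
#' @export
simulate_study <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  lib <- simulate_library(cfg)
  out <- with_seed(region_seed(cfg$seed, "study"), {
    species <- sprintf("Species_%04d", seq_len(cfg$n_species))
    tree <- ape::rphylo(cfg$n_species, birth = cfg$birth_rate, death = 0)
    tree$tip.label <- species

    regions <- sample(wgsrpd_codes(), cfg$n_regions)
    region_w <- rlnorm(cfg$n_regions, sdlog = cfg$region_weight_sdlog)
    mix <- t(vapply(seq_len(cfg$n_regions), function(i)
      rdirichlet1(cfg$dirichlet_conc * length(cfg$pathway_weights) *
                    cfg$pathway_weights),
      numeric(length(cfg$pathway_weights))))
    colnames(mix) <- names(cfg$pathway_weights)
    rownames(mix) <- regions

    primary <- sample.int(cfg$n_regions, cfg$n_species, replace = TRUE,
                          prob = region_w)
    native <- lapply(seq_len(cfg$n_species), function(i) {
      extra <- rpois(1L, cfg$extra_region_rate)
      extra <- min(extra, cfg$n_regions - 1L)
      others <- if (extra > 0L)
        sample(setdiff(seq_len(cfg$n_regions), primary[i]), extra,
               prob = region_w[setdiff(seq_len(cfg$n_regions), primary[i])])
      else integer(0)
      regions[c(primary[i], others)]
    })

    k <- r_compounds_per_species(cfg$n_species, cfg)
    by_pathway <- split(lib$compounds$structure, lib$compounds$pathway)
    rows <- vector("list", cfg$n_species)
    for (i in seq_len(cfg$n_species)) {
      pw_mix <- mix[primary[i], ]
      # only pathways actually present in the library are drawable
      avail <- names(by_pathway)[vapply(by_pathway, length, integer(1)) > 0]
      w <- pw_mix[avail]
      if (sum(w) == 0) w <- rep(1, length(avail))
      draws_pw <- sample(avail, k[i], replace = TRUE, prob = w)
      draws <- vapply(draws_pw, function(pw) {
        pool <- by_pathway[[pw]]
        pool[sample.int(length(pool), 1L)]
      }, character(1), USE.NAMES = FALSE)
      draws <- unique(draws)
      rows[[i]] <- data.frame(
        taxon = species[i],
        structure = draws,
        regions = paste(native[[i]], collapse = "|"),
        stringsAsFactors = FALSE)
    }
    occ <- do.call(rbind, rows)
    occ$pathway <- lib$compounds$pathway[match(occ$structure,
                                               lib$compounds$structure)]
    occ <- compound_occurrences(occ$taxon, occ$structure, occ$pathway,
                                occ$regions)
    dist_df <- data.frame(
      taxon = rep.int(species, lengths(native)),
      region_code = unlist(native, use.names = FALSE),
      stringsAsFactors = FALSE)
    used <- unique(occ$structure)
    list(occurrences = occ,
         distributions = dist_df,
         fingerprints = lib$fingerprints[used],
         tree = tree,
         region_mixtures = mix,
         config = cfg)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_occurrence_table(out$occurrences,
                           file.path(dir, "occurrences.csv"))
    write.csv(out$distributions, file.path(dir, "distributions.csv"),
              row.names = FALSE)
    write_fingerprint_table(out$fingerprints,
                            file.path(dir, "fingerprints.csv"))
    ape::write.tree(out$tree, file.path(dir, "tree.nwk"))
    cfg_json <- out$config
    class(cfg_json) <- NULL
    jsonlite::write_json(cfg_json, file.path(dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Write fingerprints as a plain-text table
#'
#' One row per structure: `structure,n_bits,bits`, with `bits` a
#' pipe-separated list of set bit indices.
#'
#' @param fingerprints Named list of [fingerprint()] objects.
#' @param path Output CSV path.
#' @export
write_fingerprint_table <- function(fingerprints, path) {
  df <- data.frame(
    structure = names(fingerprints),
    n_bits = vapply(fingerprints, `[[`, integer(1), "n_bits"),
    bits = vapply(fingerprints, function(f) paste(f$bits, collapse = "|"),
                  character(1)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint table written by [write_fingerprint_table()]
#'
#' @param path CSV path.
#' @return Named list of [fingerprint()] objects.
#' @export
read_fingerprint_table <- function(path) {
  df <- read.csv(path, colClasses = c("character", "integer", "character"))
  required <- c("structure", "n_bits", "bits")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("fingerprint table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    fingerprint(as.integer(strsplit(df$bits[i], "|", fixed = TRUE)[[1L]]),
                n_bits = df$n_bits[i]))
  names(out) <- df$structure
  out
}
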