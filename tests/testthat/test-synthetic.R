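test_that("scenario_config validates its inputs", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_species = 1), "n_species")
  expect_error(scenario_config(dirichlet_conc = 0), "dirichlet_conc")
  bad_w <- setNames(rep(1 / 6, 6), npc_pathways()[1:6])
  expect_error(scenario_config(pathway_weights = bad_w), "seven")
})

test_that("simulate_library is reproducible and honors the pathway mixture", {
  cfg <- scenario_config(n_compounds = 500, seed = 9)
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  expect_identical(lib1$compounds, lib2$compounds)
  expect_identical(lapply(lib1$fingerprints, `[[`, "bits"),
                   lapply(lib2$fingerprints, `[[`, "bits"))

  # degenerate mixture: everything lands in one pathway
  w <- setNames(rep(0, 7), npc_pathways()); w["alkaloids"] <- 1
  libd <- simulate_library(scenario_config(n_compounds = 200,
                                           pathway_weights = w, seed = 2))
  expect_true(all(libd$compounds$pathway == "alkaloids"))

  # multinomial check: empirical frequencies within 3 SE of the mixture
  cfg_big <- scenario_config(n_compounds = 10000, seed = 5)
  lib_big <- simulate_library(cfg_big)
  freq <- table(factor(lib_big$compounds$pathway,
                       levels = names(cfg_big$pathway_weights))) / 10000
  for (pw in names(cfg_big$pathway_weights)) {
    p <- cfg_big$pathway_weights[[pw]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(freq[[pw]] - p), 3.5 * se)
  }
})

test_that("compounds-per-species distribution has the heavy observed skew", {
  cfg <- scenario_config(seed = 3)
  set.seed(region_seed(cfg$seed, "cps"))
  k <- phytodiv:::r_compounds_per_species(20000, cfg)
  expect_gt(mean(k <= 3), 0.60)   # most species carry 1-3 compounds
  expect_gt(max(k), 30)           # with a long right tail
  expect_true(all(k >= 1))
  kz <- phytodiv:::r_ztnbinom(5000, size = 0.35, mu = 4)
  expect_true(all(kz >= 1))
})

test_that("simulate_study writes files the readers accept with zero warnings", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(n_species = 80, n_regions = 8, n_compounds = 400,
                         seed = 17)
  sim <- simulate_study(cfg, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("occurrences.csv", "distributions.csv", "fingerprints.csv",
           "tree.nwk", "scenario.json")))))
  expect_no_warning(occ <- read_occurrence_table(
    file.path(dir, "occurrences.csv")))
  expect_no_warning(fps <- read_fingerprint_table(
    file.path(dir, "fingerprints.csv")))
  expect_no_warning(tree <- parse_newick(file.path(dir, "tree.nwk")))
  expect_no_warning(dist_df <- read_distribution_table(
    file.path(dir, "distributions.csv")))
  expect_equal(as.data.frame(occ), as.data.frame(sim$occurrences))
  expect_setequal(names(fps), unique(occ$structure))
  expect_equal(sort(tree$tip.label), sort(unique(dist_df$taxon)))
  expect_no_warning(build_region_groups(occ, fingerprints = fps))
})

test_that("simulate_study is deterministic for a fixed seed", {
  cfg <- scenario_config(n_species = 60, n_regions = 6, n_compounds = 300,
                         seed = 23)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(as.data.frame(s1$occurrences),
                   as.data.frame(s2$occurrences))
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  s3 <- simulate_study(scenario_config(n_species = 60, n_regions = 6,
                                       n_compounds = 300, seed = 24))
  expect_false(identical(as.data.frame(s1$occurrences),
                         as.data.frame(s3$occurrences)))
})

test_that("higher Dirichlet concentration gives more even regions (higher J)", {
  # levels spread where the expected evenness gaps are resolvable by the
  # Monte-Carlo replication below (J plateaus near the global-mixture value
  # for very large concentrations)
  levels <- c(0.02, 0.1, 0.5, 2.5, 12)
  mean_j <- vapply(seq_along(levels), function(i) {
    js <- unlist(lapply(1:10, function(rep) {
      cfg <- scenario_config(n_species = 120, n_regions = 20,
                             n_compounds = 600,
                             dirichlet_conc = levels[i],
                             seed = 100 * i + rep)
      sim <- simulate_study(cfg)
      groups <- filter_groups(
        suppressWarnings(build_region_groups(
          sim$occurrences, fingerprints = sim$fingerprints)), 7)
      vapply(groups, function(g) {
        j <- pielou(g$pathways)
        if (is.na(j)) 0 else j
      }, numeric(1))
    }))
    mean(js)
  }, numeric(1))
  expect_equal(cor(seq_along(levels), mean_j, method = "spearman"), 1)
})
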