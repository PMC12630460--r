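test_that("standardize_structure keeps the largest fragment and is idempotent", {
  expect_equal(standardize_structure("CCO.Cl"), "CCO")
  expect_equal(standardize_structure("CCO"), "CCO")
  # heavy-atom oracle: acetate has 4 heavy atoms, sodium 1
  expect_equal(standardize_structure("[Na+].CC(=O)[O-]"), "CC(=O)[O-]")

  # idempotence on random multi-fragment strings
  set.seed(11)
  alphabet <- c("C", "N", "O", "c", "n", "Cl", "Br", "(", ")", "=", "1")
  for (i in 1:100) {
    frags <- replicate(sample(2:4, 1), paste(
      sample(alphabet, sample(3:8, 1), replace = TRUE), collapse = ""))
    raw <- paste(frags, collapse = ".")
    once <- standardize_structure(raw)
    expect_identical(standardize_structure(once), once)
  }
})

test_that("unparseable structures are rejected with a warning, not an error", {
  expect_warning(out <- standardize_structure(c("CCO", "", NA)),
                 "could not be standardized")
  expect_identical(out, c("CCO", NA, NA))
})

test_that("heavy_atom_count ignores hydrogens and counts two-letter symbols once", {
  expect_equal(heavy_atom_count("CCO"), 3)
  expect_equal(heavy_atom_count("[Na+]"), 1)
  expect_equal(heavy_atom_count("[2H]O[H]"), 1)   # water: one heavy atom
  expect_equal(heavy_atom_count("ClCCl"), 3)      # Cl not counted as C + l
  expect_equal(heavy_atom_count("c1ccccc1"), 6)   # aromatic carbons
})

test_that("heavy-atom ties break to the lexicographically smallest fragment", {
  expect_equal(standardize_structure("OCC.CCN"), "CCN")
})

test_that("build_region_groups deduplicates by structure and fans out regions", {
  # two species in FIJ sharing one compound -> 1 compound, 2 species
  occ <- compound_occurrences(
    taxon = c("Sp A", "Sp B"),
    structure = c("CCO", "CCO"),
    pathway = c("terpenoids", "terpenoids"),
    regions = c("FIJ", "FIJ"))
  g <- build_region_groups(occ)
  expect_length(g, 1L)
  expect_equal(length(g$FIJ$structures), 1L)
  expect_setequal(g$FIJ$species, c("Sp A", "Sp B"))

  # one species native to 2 regions with 3 compounds -> both groups hold 3
  occ2 <- compound_occurrences(
    taxon = "Sp A",
    structure = c("CCO", "CCN", "CCC"),
    pathway = rep("alkaloids", 3),
    regions = rep("FIJ|NWG", 3))
  g2 <- build_region_groups(occ2)
  expect_setequal(names(g2), c("FIJ", "NWG"))
  expect_equal(length(g2$FIJ$structures), 3L)
  expect_equal(length(g2$NWG$structures), 3L)

  # 5 records, 2 duplicated structures in one region -> group size 3
  occ3 <- compound_occurrences(
    taxon = c("A", "A", "B", "B", "C"),
    structure = c("CCO", "CCN", "CCO", "CCC", "CCN"),
    pathway = rep("terpenoids", 5),
    regions = rep("FIJ", 5))
  g3 <- build_region_groups(occ3)
  expect_equal(length(g3$FIJ$structures),
               length(unique(occ3$structure)))  # brute-force set size
})

test_that("pathway conflicts keep the first label and warn", {
  occ <- compound_occurrences(
    taxon = c("A", "B"),
    structure = c("CCO", "CCO"),
    pathway = c("terpenoids", "alkaloids"),
    regions = c("FIJ", "FIJ"))
  expect_warning(g <- build_region_groups(occ), "conflicting pathway")
  expect_equal(g$FIJ$pathways, "terpenoids")
})

test_that("unknown region codes warn but pass through", {
  occ <- compound_occurrences("A", "CCO", "terpenoids", "ZZZ")
  expect_warning(g <- build_region_groups(occ), "WGSRPD")
  expect_named(g, "ZZZ")
})

test_that("species totals across groups cover every distinct input species", {
  set.seed(21)
  n <- 40
  structure_ids <- sample(25, n, replace = TRUE)
  pathway_of <- sample(npc_pathways(), 25, replace = TRUE)  # consistent labels
  occ <- compound_occurrences(
    taxon = sprintf("Sp%02d", sample(12, n, replace = TRUE)),
    structure = sprintf("CMP-%02d", structure_ids),
    pathway = pathway_of[structure_ids],
    regions = sample(c("FIJ", "NWG", "FIJ|NWG", "SAM"), n, replace = TRUE))
  g <- build_region_groups(occ)
  total_species <- sum(vapply(g, function(x) length(x$species), integer(1)))
  expect_gte(total_species, length(unique(occ$taxon)))
})

test_that("filter_groups keeps groups at or above the size floor, order preserved", {
  groups <- lapply(c(3, 7, 20), function(n) {
    set.seed(n); random_group(n, region = paste0("R", n))
  })
  names(groups) <- c("R3", "R7", "R20")
  kept <- filter_groups(groups, 7)
  expect_named(kept, c("R7", "R20"))
  expect_identical(filter_groups(groups, 1), groups)
  # composing filters: the stricter floor wins
  expect_identical(filter_groups(filter_groups(groups, 3), 7),
                   filter_groups(groups, 7))
  small <- groups["R3"]
  expect_warning(out <- filter_groups(small, 7), "no region group")
  expect_length(out, 0L)
})

test_that("occurrence tables round-trip through CSV and drop uncategorised rows", {
  occ <- compound_occurrences(
    taxon = c("Sp A", "Sp B", "Sp C"),
    structure = c("CCO", "CCN", "CCC"),
    pathway = c("terpenoids", "alkaloids", "carbohydrates"),
    regions = c("FIJ", "FIJ|NWG", "SAM"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence_table(occ, path)
  back <- read_occurrence_table(path)
  expect_equal(as.data.frame(back), as.data.frame(occ))

  # a row with an empty pathway cell is dropped with a message
  raw <- read.csv(path, colClasses = "character")
  raw$pathway[2] <- ""
  write.csv(raw, path, row.names = FALSE)
  expect_message(dropped <- read_occurrence_table(path), "no pathway")
  expect_equal(nrow(dropped), 2L)

  # a missing required column is a hard error naming the column
  write.csv(raw[, c("taxon", "structure", "pathway")], path,
            row.names = FALSE)
  expect_error(read_occurrence_table(path), "regions")
})

test_that("diversity tables serialize NA as empty cells and read back", {
  profiles <- data.frame(region = c("FIJ", "NWG"), N = c(10, 8),
                         J = c(0.5, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diversity_table(profiles, path)
  txt <- readLines(path)
  expect_match(txt[3], ",$")  # trailing empty cell for the null J
  back <- read_diversity_table(path)
  expect_identical(back$J, c(0.5, NA))
})
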