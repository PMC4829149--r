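make_profile_fixture <- function() {
  tree <- toy_tree()
  maps <- annotation_maps(
    peptide_to_taxa = list(AAAK = "spA1", VVVK = "spA2",
                           CCCR = c("spA1", "spB1"), DDDK = "hsap"),
    peptide_to_kos = list(AAAK = "K00260", VVVK = "K00260",
                          CCCR = c("K00001", "K00002"), DDDK = "K10001"),
    peptide_to_cogs = list(AAAK = "C0001", VVVK = "C0002",
                           CCCR = "C0003"),
    cog_families = c(C0001 = "G", C0002 = "G", C0003 = "GE"),
    ko_domain = c(K00260 = "bacterial", K00001 = "bacterial",
                  K00002 = "bacterial", K10001 = "human"))
  obs <- data.frame(
    sample_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    peptide = c("AAAK", "VVVK", "CCCR", "EEEK", "AAAK", "DDDK"),
    spectral_count = c(2L, 3L, 4L, 6L, 1L, 5L),
    stringsAsFactors = FALSE)
  asg <- assign_lca(obs$peptide, maps, tree)
  list(tree = tree, maps = maps, obs = obs, asg = asg)
}

test_that("KO aggregation sums spectra per class", {
  fx <- make_profile_fixture()
  m <- aggregate_profile(fx$obs, "ko", maps = fx$maps)
  ## two peptides (2, 3) both -> K00260
  expect_equal(unclass(m)["K00260", "s1"], 5)
  ## multi-KO peptide contributes its full count to each KO
  expect_equal(unclass(m)["K00001", "s1"], 4)
  expect_equal(unclass(m)["K00002", "s1"], 4)
  ## unmapped peptide lands in the explicit unassigned row
  expect_equal(unclass(m)["unassigned", "s1"], 6)
  ## fractional sharing splits the count and conserves mass
  mf <- aggregate_profile(fx$obs, "ko", maps = fx$maps,
                          share = "fractional")
  expect_equal(unclass(mf)["K00001", "s1"], 2)
  totals <- tapply(fx$obs$spectral_count, fx$obs$sample_id, sum)
  expect_equal(colSums(mf), as.numeric(totals[colnames(mf)]),
               ignore_attr = TRUE)
})

test_that("taxon-rank aggregation respects LCA depth and nests", {
  fx <- make_profile_fixture()
  ## CCCR's LCA is the Bacteria domain -> excluded at phylum rank
  mp <- aggregate_profile(fx$obs, "taxon", assignments = fx$asg,
                          tree = fx$tree, rank = "phylum")
  expect_equal(unclass(mp)["Firmicutes", "s1"], 5)  # AAAK + VVVK
  expect_false("Bacteroidetes" %in% setdiff(rownames(mp), "unassigned") &&
                 unclass(mp)["Bacteroidetes", "s1"] > 0)
  expect_equal(unclass(mp)["unassigned", "s1"], 10)  # CCCR + EEEK
  ## genus totals within a phylum never exceed the phylum total
  mg <- aggregate_profile(fx$obs, "taxon", assignments = fx$asg,
                          tree = fx$tree, rank = "genus")
  expect_lte(unclass(mg)["GenusA", "s1"], unclass(mp)["Firmicutes", "s1"])
  ## mass conservation at taxon level
  totals <- tapply(fx$obs$spectral_count, fx$obs$sample_id, sum)
  expect_equal(colSums(mp), as.numeric(totals[colnames(mp)]),
               ignore_attr = TRUE)
})

test_that("taxon-restricted profiles keep only the clade's peptides", {
  fx <- make_profile_fixture()
  m <- aggregate_profile(fx$obs, "ko", maps = fx$maps,
                         assignments = fx$asg, tree = fx$tree,
                         restrict_taxon = "GenusA")
  ## only AAAK and VVVK have LCA at/below GenusA
  expect_equal(sort(setdiff(rownames(m), "unassigned")), "K00260")
  expect_equal(unclass(m)["K00260", "s1"], 5)
  ## restriction by name or id agree
  m2 <- aggregate_profile(fx$obs, "ko", maps = fx$maps,
                          assignments = fx$asg, tree = fx$tree,
                          restrict_taxon = "gA")
  expect_equal(unclass(m2), unclass(m))
})

test_that("abundance_filter keeps features reaching the max-count bar", {
  m <- abundance_matrix(
    matrix(c(4, 0, 1, 4, 0, 1, 4, 5, 1), 3, 3,
           dimnames = list(c("f_low", "f_peak", "f_one"),
                           c("s1", "s2", "s3"))), "counts")
  f5 <- abundance_filter(m, 5)
  expect_equal(rownames(f5), "f_peak")     # (0,0,5) kept; (4,4,4) dropped
  expect_equal(unclass(abundance_filter(m, 1)), unclass(m))  # identity
  ## retained set non-increasing in the threshold
  expect_true(all(rownames(abundance_filter(m, 4)) %in%
                    rownames(abundance_filter(m, 2))))
  expect_error(abundance_filter(m, 0), ">= 1")
})

test_that("to_percent normalises columns to 100", {
  m <- abundance_matrix(matrix(c(5, 15, 1, 1, 2, 0), 3, 2,
                               dimnames = list(c("a", "b", "c"),
                                               c("s1", "s2"))),
                        "counts")
  p <- to_percent(m)
  expect_equal(unname(unclass(p)[, "s1"]), 100 * c(5, 15, 1) / 21)
  expect_equal(unname(unclass(p)[, "s2"]), 100 * c(1, 2, 0) / 3)
  ## counts (5,15) -> (25,75); a single feature -> 100
  m2 <- abundance_matrix(matrix(c(5, 15), 2, 1,
                                dimnames = list(c("a", "b"), "s")),
                         "counts")
  expect_equal(unname(unclass(to_percent(m2))[, 1]), c(25, 75))
  m1 <- abundance_matrix(matrix(7, 1, 1, dimnames = list("a", "s")),
                         "counts")
  expect_equal(unname(unclass(to_percent(m1))[1, 1]), 100)
  expect_equal(unname(colSums(p)), c(100, 100), tolerance = 1e-12)
  bad <- abundance_matrix(matrix(0, 1, 1, dimnames = list("a", "sz")),
                          "counts")
  expect_error(to_percent(bad), "sz")
})

test_that("COG family profile routes multi-family and unannotated peptides", {
  fx <- make_profile_fixture()
  p <- cog_family_profile(fx$obs, fx$maps)
  ## s1: AAAK+VVVK -> G (5), CCCR -> ambiguous (4), EEEK -> unassigned (6)
  expect_equal(unclass(p)["G", "s1"], 100 * 5 / 15)
  expect_equal(unclass(p)["ambiguous", "s1"], 100 * 4 / 15)
  expect_equal(unclass(p)["unassigned", "s1"], 100 * 6 / 15)
  expect_equal(unname(colSums(p)), c(100, 100), tolerance = 1e-9)
})
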