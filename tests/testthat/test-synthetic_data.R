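test_that("generator_config validates its stated world", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(common_core_kos = 290,
                                individual_core_kos = 40),
               "exceed")
  expect_error(generator_config(eukaryotic_fraction = 0.9,
                                untaxon_fraction = 0.2), "sum")
  expect_error(generator_config(n_subjects = 15L), "even")
})

test_that("same seed reproduces the bundle, different seeds differ", {
  cfg <- generator_config(n_subjects = 4L, spectra_per_sample = 500L,
                          n_bacterial_kos = 50L, n_human_kos = 20L,
                          common_core_kos = 20L, individual_core_kos = 10L,
                          n_16s_samples = 10L, seed = 7L)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$observations, b2$observations)
  expect_identical(unclass(b1$sixteen_s_phylum),
                   unclass(b2$sixteen_s_phylum))
  cfg2 <- generator_config(n_subjects = 4L, spectra_per_sample = 500L,
                           n_bacterial_kos = 50L, n_human_kos = 20L,
                           common_core_kos = 20L,
                           individual_core_kos = 10L,
                           n_16s_samples = 10L, seed = 8L)
  b3 <- generate_cohort(cfg2)
  expect_false(identical(b1$observations, b3$observations))
})

test_that("per-sample spectral totals equal the configured value exactly", {
  b <- default_cohort()
  totals <- tapply(b$observations$spectral_count,
                   b$observations$sample_id, sum)
  expect_true(all(totals == b$truth$config$spectra_per_sample))
  expect_equal(length(totals), nrow(b$meta))
})

test_that("generated taxonomy and module file pass the parsers", {
  b <- default_cohort()
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  tree <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(tree$nodes, b$tree$nodes)
  mods <- read_module_definitions(file.path(dir, "modules.gmm"))
  expect_equal(length(mods), length(b$modules))
  expect_equal(mods[[5]]$pathways, b$modules[[5]]$pathways)
  meta <- read_sample_meta(file.path(dir, "meta.tsv"))
  expect_identical(meta, b$meta)
  suppressWarnings(obs <- read_peptide_table(file.path(dir, "peptides.tsv")))
  expect_equal(nrow(obs), nrow(b$observations))
})

test_that("true LCAs agree with assign_lca on the generated maps", {
  b <- default_cohort()
  tr <- truth_record(b)
  asg <- default_assignments()
  got <- setNames(asg$lca_taxon, asg$peptide)
  ## truth peptides are stored in normalised (I-free) form already
  seen <- tr$peptide_lca[tr$peptide_lca$peptide %in% names(got), ]
  expect_gt(nrow(seen), 1000)
  expect_identical(unname(got[seen$peptide]), seen$true_lca)
})

test_that("domain classes of generated peptides match their category", {
  b <- default_cohort()
  tr <- truth_record(b)
  asg <- default_assignments()
  cls <- setNames(asg$domain_class, asg$peptide)
  cat <- setNames(tr$peptide_lca$category, tr$peptide_lca$peptide)
  seen <- intersect(names(cls), names(cat))
  map <- c(bacterial = "bacterial", eukaryotic = "eukaryotic",
           archaeal = "archaeal", ambiguous = "ambiguous",
           untaxon = "unassigned")
  expect_identical(unname(cls[seen]), unname(map[cat[seen]]))
})

test_that("a module built from omnipresent KOs is detected everywhere", {
  b <- default_cohort()
  ko <- aggregate_profile(b$observations, "ko", maps = b$maps,
                          include_unassigned = FALSE)
  res <- score_gmm(b$modules[1], ko)
  ## module 1 is built from top common-core KOs
  expect_true(all(res$detected))
})

test_that("null probiotic effect leaves groups exchangeable", {
  b <- default_cohort()
  ko <- aggregate_profile(b$observations, "ko", maps = b$maps,
                          include_unassigned = FALSE)
  kod <- b$maps$ko_domain
  bko <- ko[intersect(rownames(ko),
                      names(kod)[kod == "bacterial"]), ]
  subj <- b$meta$subject_id[match(colnames(bko), b$meta$sample_id)]
  subjects <- unique(subj)
  subj_grp <- b$meta$group[match(subjects, b$meta$subject_id)]
  ## permutation test at the subject level (group is a subject-level
  ## label): between-group squared difference of mean percentages
  pct <- unclass(to_percent(bko))
  stat <- function(sg) {
    g <- sg[match(subj, subjects)]
    sum((rowMeans(pct[, g == "probiotic"]) -
           rowMeans(pct[, g == "placebo"]))^2)
  }
  obs <- stat(subj_grp)
  set.seed(13)
  null <- replicate(500, stat(sample(subj_grp)))
  p <- mean(null >= obs)
  expect_gt(p, 0.05)
})

test_that("a nonzero probiotic effect is detectable", {
  cfg <- generator_config(probiotic_effect = 4, seed = 11L,
                          n_subjects = 8L, spectra_per_sample = 2000L,
                          n_bacterial_kos = 100L, common_core_kos = 40L,
                          individual_core_kos = 20L, n_16s_samples = 24L)
  b <- generate_cohort(cfg)
  ko <- aggregate_profile(b$observations, "ko", maps = b$maps,
                          include_unassigned = FALSE)
  pct <- unclass(to_percent(ko))[b$truth$effect_kos, ]
  m <- b$meta[match(colnames(pct), b$meta$sample_id), ]
  tp2_prob <- colSums(pct[, m$group == "probiotic" & m$time_point == 2])
  tp2_plac <- colSums(pct[, m$group == "placebo" & m$time_point == 2])
  expect_gt(mean(tp2_prob), 2 * mean(tp2_plac))
})

test_that("planted human-bacterial pairs are recovered", {
  b <- default_cohort()
  tr <- truth_record(b)
  ko <- aggregate_profile(b$observations, "ko", maps = b$maps,
                          include_unassigned = FALSE)
  kod <- b$maps$ko_domain
  hko <- abundance_filter(
    ko[intersect(rownames(ko), names(kod)[kod == "human"]), ], 2)
  bko <- abundance_filter(
    ko[intersect(rownames(ko), names(kod)[kod == "bacterial"]), ], 5)
  res <- correlate_human_bacterial(hko, bko)
  hits <- paste(res$records$human_ko, res$records$bacterial_ko)
  planted <- paste(tr$planted_pairs$human_ko,
                   tr$planted_pairs$bacterial_ko)
  expect_gte(sum(planted %in% hits), 4)
})
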