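test_that("Jaccard distances follow set arithmetic", {
  sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"),
               s3 = c("A", "B", "C"), s4 = c("X", "Y"))
  d <- as.matrix(jaccard_distance(sets))
  expect_equal(d["s1", "s2"], 1 - 2 / 4)
  expect_equal(d["s1", "s3"], 0)        # identical sets
  expect_equal(d["s1", "s4"], 1)        # disjoint sets
  expect_equal(d, t(d))                 # symmetry
  expect_error(jaccard_distance(list(s1 = "A", s2 = character(0))),
               "s2")
})

test_that("Jaccard distance satisfies the triangle inequality", {
  set.seed(31)
  for (rep in 1:100) {
    universe <- LETTERS[1:12]
    sets <- lapply(1:3, function(i)
      sample(universe, sample(1:12, 1)))
    names(sets) <- c("a", "b", "c")
    d <- as.matrix(jaccard_distance(sets))
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
  }
})

test_that("complete-linkage merge heights are non-decreasing", {
  set.seed(77)
  sets <- lapply(1:8, function(i) sample(LETTERS, sample(3:10, 1)))
  names(sets) <- paste0("s", 1:8)
  h <- jaccard_cluster(sets)
  expect_true(all(diff(h$height) >= -1e-12))
})

test_that("correlation clustering uses 1 - Pearson r", {
  m <- abundance_matrix(
    matrix(c(10, 20, 70, 5, 10, 85, 70, 20, 10), 3, 3,
           dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3"))),
    "percent")
  h <- correlation_cluster(m)
  x <- unclass(m)
  d <- as.matrix(stats::cophenetic(h))
  ## direct pairwise distances bound the cophenetic ones from below
  expect_equal(min(d[d > 0]), 1 - cor(x[, "s1"], x[, "s2"]),
               tolerance = 1e-12)
  ## proportional columns -> distance 0; anti-correlated -> 2
  expect_equal(1 - cor(c(1, 2, 3), c(2, 4, 6)), 0)
  m2 <- abundance_matrix(
    matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
           dimnames = list(letters[1:3], c("u", "v"))), "counts")
  h2 <- correlation_cluster(m2)
  expect_equal(max(h2$height), 2, tolerance = 1e-12)
  bad <- abundance_matrix(matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
                                 dimnames = list(letters[1:3],
                                                 c("flat", "ok"))),
                          "counts")
  expect_error(correlation_cluster(bad), "flat")
})

test_that("dendrograms serialise to Newick", {
  sets <- list(s1 = c("A", "B"), s2 = c("A", "B", "C"), s3 = "Z")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(jaccard_cluster(sets), f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, names(sets))
})

test_that("Spearman screen recovers monotone relations exactly", {
  x <- matrix(1:12, 1, 12, dimnames = list("h1", paste0("s", 1:12)))
  up <- (1:12)^2          # strictly increasing transform
  down <- 13 - (1:12)     # strictly decreasing
  b <- rbind(up, down)
  dimnames(b) <- list(c("b_up", "b_down"), colnames(x))
  res <- correlate_human_bacterial(
    abundance_matrix(x, "counts"), abundance_matrix(b, "counts"),
    alpha = 0.05)
  rho <- setNames(res$all$rho, res$all$bacterial_ko)
  expect_equal(unname(rho["b_up"]), 1)
  expect_equal(unname(rho["b_down"]), -1)
  expect_equal(res$all$p_value[res$all$bacterial_ko == "b_up"], 0)
})

test_that("small-n Spearman p-values match cor.test's exact method", {
  set.seed(5)
  for (n in c(5, 6, 7)) {
    x <- matrix(exp(rnorm(n)), 1, n,
                dimnames = list("h", paste0("s", 1:n)))
    y <- matrix(exp(rnorm(n)), 1, n, dimnames = list("b", colnames(x)))
    res <- correlate_human_bacterial(abundance_matrix(x, "counts"),
                                     abundance_matrix(y, "counts"))
    ct <- cor.test(x[1, ], y[1, ], method = "spearman", exact = TRUE)
    expect_equal(res$all$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$all$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher exact matches enumeration and known values", {
  ## [[8,0],[0,8]] -> 2 / choose(16, 8)
  expect_equal(fisher_exact_2x2(matrix(c(8, 0, 0, 8), 2, 2)),
               2 / choose(16, 8), tolerance = 1e-12)
  ## identical rows -> p = 1
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 5, 5), 2, 2)), 1)
  set.seed(12)
  for (rep in 1:200) {
    tab <- matrix(sample(0:6, 4, TRUE), 2, 2)
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(rep(1, 4)), log(4))
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  ## 0 <= H <= ln(k), maximised by the uniform vector
  set.seed(4)
  for (rep in 1:50) {
    p <- runif(6)
    h <- shannon_index(p)
    expect_gte(h, 0)
    expect_lte(h, log(sum(p > 0)) + 1e-12)
  }
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("ratio_group_test produces ratios, clusters and both tests", {
  b <- default_cohort()
  asg <- default_assignments()
  rg <- ratio_group_test(asg, b$observations, b$meta)
  expect_equal(nrow(rg$ratios), nrow(b$meta))
  expect_true(all(rg$ratios$ratio > 0))
  expect_equal(sum(rg$contingency), 16)
  expect_true(rg$fisher_p >= 0 && rg$fisher_p <= 1)
  ## null cohort: no significant group clustering or paired shift
  expect_gt(rg$fisher_p, 0.05)
  expect_gt(rg$wilcoxon_p, 0.05)
})

test_that("phylum concordance is exact on identical matrices", {
  m <- abundance_matrix(
    matrix(c(60, 30, 10, 50, 40, 10, 70, 20, 10, 55, 30, 15), 3, 4,
           dimnames = list(c("Firmicutes", "Bacteroidetes", "Actino"),
                           paste0("s", 1:4))), "percent")
  res <- phylum_concordance(m, m)
  expect_true(all(abs(res$correlations$r - 1) < 1e-12))
  expect_equal(nrow(res$summary), 6)
  ## a phylum on one platform only is excluded with a warning
  m2 <- abundance_matrix(unclass(m)[1:2, ] * 100 /
                           rep(colSums(unclass(m)[1:2, ]), each = 2),
                         "percent")
  expect_warning(res2 <- phylum_concordance(m, m2), "Actino")
  expect_equal(nrow(res2$correlations), 2)
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  set.seed(88)
  a <- sample(1:4, 200, TRUE); bl <- sample(1:4, 200, TRUE)
  expect_lt(abs(adjusted_rand_index(a, bl)), 0.1)
})
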