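## Shared fixtures and independent oracles, built in code.

## Small fixed taxonomy: two bacterial phyla, archaea, and a Chordata
## lineage.
toy_tree <- function() {
  taxonomy_tree(data.frame(
    taxon_id = c("root", "bact", "arch", "euk",
                 "firm", "bctr", "gA", "gB", "spA1", "spA2", "spB1",
                 "eury", "msm",
                 "chord", "mamm", "homo", "hsap", "bos", "btau"),
    parent_id = c("root", "root", "root", "root",
                  "bact", "bact", "firm", "bctr", "gA", "gA", "gB",
                  "arch", "eury",
                  "euk", "chord", "mamm", "homo", "mamm", "bos"),
    rank = c("root", "domain", "domain", "domain",
             "phylum", "phylum", "genus", "genus", "species", "species",
             "species", "phylum", "species",
             "phylum", "class", "genus", "species", "genus", "species"),
    name = c("root", "Bacteria", "Archaea", "Eukaryota",
             "Firmicutes", "Bacteroidetes", "GenusA", "GenusB",
             "SpeciesA1", "SpeciesA2", "SpeciesB1",
             "Euryarchaeota", "Methanobrevibacter smithii",
             "Chordata", "Mammalia", "Homo", "Homo sapiens",
             "Bos", "Bos taurus"),
    stringsAsFactors = FALSE))
}

## Independent LCA oracle: intersect root-paths and take the last
## common element.
lca_oracle <- function(tree, ids) {
  path_from_root <- function(id) rev(ancestors(tree, id))
  paths <- lapply(unique(ids), path_from_root)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

## Random valid taxonomy: root, domain children of root, no_rank below.
random_tree <- function(n_nodes) {
  n_dom <- sample(2:3, 1L)
  ids <- c("root", paste0("d", seq_len(n_dom)))
  parent <- c("root", rep("root", n_dom))
  rank <- c("root", rep("domain", n_dom))
  while (length(ids) < n_nodes) {
    i <- length(ids) + 1L
    parent <- c(parent, sample(ids[-1], 1L))  # attach below a domain
    ids <- c(ids, paste0("t", i))
    rank <- c(rank, "no_rank")
  }
  taxonomy_tree(data.frame(taxon_id = ids, parent_id = parent,
                           rank = rank, name = ids,
                           stringsAsFactors = FALSE))
}

## Independent GMM oracle: enumerate every pathway, recompute coverage
## and median abundance from scratch, apply the strict > 2/3 rule.
gmm_oracle <- function(module, counts) {
  best_cov <- -1; best_med <- -1; best_idx <- NA_integer_
  for (j in seq_along(module$pathways)) {
    abund <- c()
    for (st in module$pathways[[j]]) {
      vals <- 0
      for (ko in st) if (!is.na(counts[ko])) vals <- c(vals, counts[[ko]])
      abund <- c(abund, max(vals))
    }
    cov <- sum(abund > 0) / length(abund)
    med <- median(abund)
    if (cov > best_cov || (cov == best_cov && med > best_med)) {
      best_cov <- cov; best_med <- med; best_idx <- j
    }
  }
  det <- best_cov > 2 / 3
  list(coverage = best_cov, detected = det,
       abundance = if (det) best_med else 0,
       best_pathway_index = best_idx)
}

## Independent Fisher oracle: choose()-based hypergeometric
## enumeration over the support.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- r1 + r2
  if (N == 0) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

random_module <- function(kos, max_pathways = 4L, max_steps = 6L) {
  pathways <- lapply(seq_len(sample(max_pathways, 1L)), function(p)
    lapply(seq_len(sample(max_steps, 1L)), function(s)
      sample(kos, sample(1:3, 1L))))
  module_definition("MTEST", "random module", pathways)
}

## The default synthetic cohort (seed 42), generated once per test run.
default_cohort <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle)) bundle <<- generate_cohort(generator_config(seed = 42))
    bundle
  }
})

default_assignments <- local({
  asg <- NULL
  function() {
    if (is.null(asg)) {
      b <- default_cohort()
      asg <<- assign_lca(unique(b$observations$peptide), b$maps, b$tree)
    }
    asg
  }
})

toy_observations <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    peptide = c("AAAK", "CCCR", "DDDK", "AAAK", "EEEK"),
    spectral_count = c(2L, 3L, 1L, 4L, 5L),
    stringsAsFactors = FALSE)
}
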