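#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a 16-subject, three-time-point
#' placebo/probiotic crossover metaproteome at desk scale: a common
#' functional core shared by all subjects, individual cores stable
#' across time points, roughly 14% eukaryotic (host) spectra, well
#' under 1% archaeal spectra, and a null probiotic effect.
#'
#' @param n_subjects number of subjects (split evenly into placebo and
#'   probiotic groups)
#' @param time_points samples per subject
#' @param n_bacterial_kos,n_human_kos,n_archaeal_kos catalogue sizes
#'   (the real study's 967 bacterial KOs scaled down to 300; 73 human
#'   KOs as reported)
#' @param common_core_kos bacterial KOs shared by every subject
#' @param individual_core_kos extra KOs boosted per subject
#' @param spectra_per_sample total spectral count per sample (exact)
#' @param eukaryotic_fraction,archaeal_fraction,ambiguous_fraction
#'   expected fractions of taxonomically assigned spectra per class
#' @param untaxon_fraction fraction of spectra from peptides with no
#'   taxonomic match at all
#' @param dirichlet_concentration concentration of the per-subject
#'   Dirichlet draw around the base KO profile (lower = more
#'   personalised)
#' @param temporal_sd standard deviation of the multiplicative
#'   log-normal noise between a subject's time points
#' @param probiotic_effect multiplicative KO perturbation applied at
#'   time point 2 in the probiotic group (0 = null, the default)
#' @param peptides_per_ko peptides in the universe per KO
#' @param peptide_retention probability a subject expresses any given
#'   peptide of a KO (drives subject-specific peptide repertoires)
#' @param degenerate_fraction fraction of bacterial peptides shared
#'   across several taxa (exercising non-trivial LCAs)
#' @param missed_cleavage_fraction fraction of peptides emitted as a
#'   two-fragment missed-cleavage form
#' @param no_cog_fraction fraction of KOs lacking a COG annotation
#' @param multi_family_fraction fraction of COGs spanning two family
#'   letters (ambiguous)
#' @param n_modules synthetic gut metabolic modules to emit
#' @param n_16s_samples samples with a matched 16S profile
#' @param cross_platform_cor planted log-scale correlation between
#'   proteome and 16S phylum abundances
#' @param n_planted_pairs human-bacterial KO pairs with coupled
#'   abundances
#' @param seed integer RNG seed; the same seed reproduces the bundle
#'   bit for bit
#' @return a validated `generator_config` list
#' @export
generator_config <- function(n_subjects = 16L, time_points = 3L,
                             n_bacterial_kos = 300L, n_human_kos = 73L,
                             n_archaeal_kos = 5L,
                             common_core_kos = 100L,
                             individual_core_kos = 40L,
                             spectra_per_sample = 4000L,
                             eukaryotic_fraction = 0.14,
                             archaeal_fraction = 0.005,
                             ambiguous_fraction = 0.01,
                             untaxon_fraction = 0.05,
                             dirichlet_concentration = 200,
                             temporal_sd = 0.3,
                             probiotic_effect = 0,
                             peptides_per_ko = 8L,
                             peptide_retention = 0.6,
                             degenerate_fraction = 0.25,
                             missed_cleavage_fraction = 0.1,
                             no_cog_fraction = 0.15,
                             multi_family_fraction = 0.05,
                             n_modules = 20L,
                             n_16s_samples = 44L,
                             cross_platform_cor = 0.7,
                             n_planted_pairs = 5L,
                             seed = 42L) {
  cfg <- as.list(environment())
  fr <- c(cfg$eukaryotic_fraction, cfg$archaeal_fraction,
          cfg$ambiguous_fraction, cfg$untaxon_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1)
    stop("spectral fractions must lie in [0,1] and sum to < 1")
  if (cfg$common_core_kos + cfg$individual_core_kos > cfg$n_bacterial_kos)
    stop("core sizes exceed the bacterial KO catalogue")
  if (cfg$n_subjects %% 2L != 0L)
    stop("n_subjects must be even (equal group split)")
  if (cfg$n_16s_samples > cfg$n_subjects * cfg$time_points)
    stop("n_16s_samples exceeds the number of samples")
  sizes <- c(cfg$n_subjects, cfg$time_points, cfg$n_bacterial_kos,
             cfg$n_human_kos, cfg$spectra_per_sample,
             cfg$peptides_per_ko, cfg$n_modules)
  if (any(sizes < 1)) stop("all sizes must be positive")
  structure(cfg, class = "generator_config")
}

## Random tryptic "words": interior residues avoid K/R (no internal
## cleavage site), I (normalised away) and a leading P (which would
## suppress cleavage on concatenation); the final residue is K or R.
random_tryptic_words <- function(n, min_len = 8L, max_len = 14L) {
  interior <- setdiff(AA_ALPHABET, c("K", "R", "I", "P"))
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(min_len:max_len, need, replace = TRUE)
    words <- vapply(lens, function(l)
      paste0(paste(sample(interior, l - 1L, replace = TRUE),
                   collapse = ""),
             sample(c("K", "R"), 1L)), "")
    out <- unique(c(out, words))
  }
  out[seq_len(n)]
}

build_synthetic_taxonomy <- function() {
  rows <- list()
  add <- function(id, parent, rank, name)
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = id, parent_id = parent, rank = rank, name = name,
      stringsAsFactors = FALSE)
  add("root", "root", "root", "root")
  add("d_bact", "root", "domain", "Bacteria")
  add("d_arch", "root", "domain", "Archaea")
  add("d_euk", "root", "domain", "Eukaryota")
  phyla <- c(p_firm = "Firmicutes", p_bact = "Bacteroidetes",
             p_actino = "Actinobacteria", p_proteo = "Proteobacteria")
  genus_seed_names <- list(
    p_firm = c("Faecalibacterium", "Ruminococcus", "Roseburia"),
    p_bact = c("Bacteroides", "Prevotella", "Alistipes"),
    p_actino = c("Bifidobacterium", "Collinsella", "Eggerthella"),
    p_proteo = c("Escherichia", "Bilophila", "Desulfovibrio"))
  species <- character(0); phylum_of <- character(0)
  genus_of <- character(0)
  for (pid in names(phyla)) {
    add(pid, "d_bact", "phylum", phyla[[pid]])
    n_gen <- sample(2:3, 1L)
    for (g in seq_len(n_gen)) {
      gid <- paste0("g_", pid, "_", g)
      add(gid, pid, "genus", genus_seed_names[[pid]][g])
      n_sp <- sample(2:3, 1L)
      for (s in seq_len(n_sp)) {
        sid <- paste0("s_", pid, "_", g, "_", s)
        add(sid, gid, "species",
            paste(genus_seed_names[[pid]][g], paste0("sp", s)))
        species <- c(species, sid)
        phylum_of[sid] <- pid
        genus_of[sid] <- gid
      }
    }
  }
  add("p_eury", "d_arch", "phylum", "Euryarchaeota")
  add("g_methano", "p_eury", "genus", "Methanobrevibacter")
  add("s_msmithii", "g_methano", "species", "Methanobrevibacter smithii")
  add("p_chordata", "d_euk", "phylum", "Chordata")
  add("c_mammalia", "p_chordata", "class", "Mammalia")
  add("g_homo", "c_mammalia", "genus", "Homo")
  add("s_hsapiens", "g_homo", "species", "Homo sapiens")
  add("g_bos", "c_mammalia", "genus", "Bos")
  add("s_btaurus", "g_bos", "species", "Bos taurus")
  list(tree = taxonomy_tree(do.call(rbind, rows)),
       bacterial_species = species, phylum_of = phylum_of,
       genus_of = genus_of)
}

#' Generate a synthetic metaproteome cohort
#'
#' Produces every input the analysis pipeline needs — taxonomy, KO and
#' gut-metabolic-module catalogues, a peptide universe with taxonomic
#' and functional annotation maps, per-sample peptide spectral-count
#' tables, sample metadata, and a matched 16S phylum/genus table —
#' with subject-specific structure: a common functional core, stable
#' individual cores, subject-specific peptide repertoires, degenerate
#' and missed-cleavage peptides to exercise LCA assignment, and (by
#' default) no probiotic-group effect. Per-sample spectral totals equal
#' `spectra_per_sample` exactly. Byte-reproducible given a seed.
#'
#' @param config a [generator_config()]
#' @return a list (`cohort_bundle`) with `meta`, `observations`,
#'   `tree`, `maps`, `modules`, `sixteen_s_phylum`, `sixteen_s_genus`
#'   and a `truth` record of the planted structure (see
#'   [truth_record()])
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## --- samples ------------------------------------------------------
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  group <- rep(c("placebo", "probiotic"), each = cfg$n_subjects / 2L)
  meta <- do.call(rbind, lapply(seq_along(subjects), function(i)
    data.frame(sample_id = sprintf("%s_T%d", subjects[i],
                                   seq_len(cfg$time_points)),
               subject_id = subjects[i],
               time_point = seq_len(cfg$time_points),
               group = group[i], stringsAsFactors = FALSE)))
  samples <- meta$sample_id

  ## --- taxonomy -----------------------------------------------------
  taxo <- build_synthetic_taxonomy()
  tree <- taxo$tree
  spp <- taxo$bacterial_species

  ## --- KO catalogues ------------------------------------------------
  ko_b <- sprintf("K0%04d", seq_len(cfg$n_bacterial_kos))
  ko_h <- sprintf("K1%04d", seq_len(cfg$n_human_kos))
  ko_a <- sprintf("K2%04d", seq_len(cfg$n_archaeal_kos))
  ko_domain <- c(setNames(rep("bacterial", length(ko_b) + length(ko_a)),
                          c(ko_b, ko_a)),
                 setNames(rep("human", length(ko_h)), ko_h))

  ## COG annotation per KO: a fraction of KOs carry no COG; a fraction
  ## of COGs span two family letters (ambiguous).
  ko_fn <- c(ko_b, ko_h)
  has_cog <- runif(length(ko_fn)) >= cfg$no_cog_fraction
  cog_id <- setNames(rep(NA_character_, length(ko_fn)), ko_fn)
  cog_id[has_cog] <- sprintf("C%04d", seq_len(sum(has_cog)))
  fam <- vapply(seq_len(sum(has_cog)), function(i) {
    if (runif(1) < cfg$multi_family_fraction)
      paste(sample(COG_FAMILY_ALPHABET, 2L), collapse = "")
    else sample(COG_FAMILY_ALPHABET, 1L)
  }, "")
  cog_families <- setNames(fam, cog_id[has_cog])

  ## --- peptide universe --------------------------------------------
  ## One row per *observed* peptide (the string that appears in sample
  ## tables); missed-cleavage peptides are the concatenation of two
  ## tryptic words whose fragment-level taxa intersect to the intended
  ## set.
  n_amb <- 30L; n_untax <- 60L
  n_b_pep <- cfg$n_bacterial_kos * cfg$peptides_per_ko
  n_h_pep <- cfg$n_human_kos * cfg$peptides_per_ko
  n_a_pep <- cfg$n_archaeal_kos * cfg$peptides_per_ko
  n_mc_extra <- n_b_pep  # generous pool of extra words for fragments
  words <- random_tryptic_words(n_b_pep + n_h_pep + n_a_pep +
                                  n_amb + n_untax + n_mc_extra)
  wi <- 0L
  next_word <- function() { wi <<- wi + 1L; words[wi] }

  p2t <- list()       # fragment -> taxa
  p2k <- list()       # observed peptide -> KO(s)
  p2c <- list()       # observed peptide -> COG(s)
  info <- list()      # per observed peptide: category, ko, taxa
  register <- function(pep, category, ko, taxa) {
    info[[length(info) + 1L]] <<- list(peptide = pep, category = category,
                                       ko = ko, taxa = list(taxa))
    if (!is.na(ko)) {
      p2k[[pep]] <<- ko
      if (!is.na(cog_id[ko])) p2c[[pep]] <<- unname(cog_id[ko])
    }
  }

  host_species <- sample(spp, cfg$n_bacterial_kos, replace = TRUE)
  ko_peptides <- vector("list", length(ko_fn))
  names(ko_peptides) <- ko_fn

  for (ki in seq_along(ko_b)) {
    ko <- ko_b[ki]
    peps <- character(cfg$peptides_per_ko)
    for (j in seq_len(cfg$peptides_per_ko)) {
      base_sp <- host_species[ki]
      taxa <- base_sp
      if (runif(1) < cfg$degenerate_fraction) {
        if (runif(1) < 0.6) {
          ## same-phylum degeneracy -> LCA at genus or phylum level
          pool <- setdiff(spp[taxo$phylum_of[spp] ==
                                taxo$phylum_of[base_sp]], base_sp)
        } else {
          pool <- setdiff(spp, base_sp)
        }
        if (length(pool))
          taxa <- c(base_sp, sample(pool, min(length(pool),
                                              sample(1:2, 1L))))
      }
      if (runif(1) < cfg$missed_cleavage_fraction) {
        w1 <- next_word(); w2 <- next_word()
        extra <- sample(setdiff(spp, taxa), 1L)
        p2t[[w1]] <- unique(c(taxa, extra))  # superset
        p2t[[w2]] <- taxa                    # intersection = taxa
        pep <- paste0(w1, w2)
      } else {
        pep <- next_word()
        p2t[[pep]] <- taxa
      }
      register(pep, "bacterial", ko, taxa)
      peps[j] <- pep
    }
    ko_peptides[[ko]] <- peps
  }

  for (ki in seq_along(ko_h)) {
    ko <- ko_h[ki]
    peps <- character(cfg$peptides_per_ko)
    for (j in seq_len(cfg$peptides_per_ko)) {
      taxa <- if (runif(1) < 0.6) "s_hsapiens"
              else c("s_hsapiens", "s_btaurus")
      pep <- next_word()
      p2t[[pep]] <- taxa
      register(pep, "eukaryotic", ko, taxa)
      peps[j] <- pep
    }
    ko_peptides[[ko]] <- peps
  }

  arch_peptides <- character(n_a_pep)
  for (j in seq_len(n_a_pep)) {
    pep <- next_word()
    p2t[[pep]] <- "s_msmithii"
    ko <- ko_a[((j - 1L) %% length(ko_a)) + 1L]
    register(pep, "archaeal", ko, "s_msmithii")
    arch_peptides[j] <- pep
  }

  amb_peptides <- character(n_amb)
  for (j in seq_len(n_amb)) {
    pep <- next_word()
    taxa <- c(sample(spp, 1L), "s_hsapiens")
    p2t[[pep]] <- taxa
    register(pep, "ambiguous", NA_character_, taxa)
    amb_peptides[j] <- pep
  }

  untax_peptides <- character(n_untax)
  for (j in seq_len(n_untax)) {
    pep <- next_word()
    ko <- if (j %% 2L == 0L) sample(ko_b, 1L) else NA_character_
    register(pep, "untaxon", ko, character(0))
    untax_peptides[j] <- pep
  }

  maps <- annotation_maps(p2t, p2k, p2c, cog_families, ko_domain)
  validate_annotation_taxa(maps, tree)

  pep_df <- data.frame(
    peptide = vapply(info, `[[`, "", "peptide"),
    category = vapply(info, `[[`, "", "category"),
    ko = vapply(info, `[[`, "", "ko"),
    stringsAsFactors = FALSE)
  pep_taxa <- lapply(info, function(x) x$taxa[[1]])
  names(pep_taxa) <- pep_df$peptide

  ## --- subject KO profiles (Dirichlet-multinomial hierarchy) --------
  core <- ko_b[seq_len(cfg$common_core_kos)]
  noncore <- setdiff(ko_b, core)
  subj_core <- lapply(subjects, function(s)
    sample(noncore, cfg$individual_core_kos))
  names(subj_core) <- subjects

  base_alpha <- setNames(rep(0.3, length(ko_b)), ko_b)
  base_alpha[core] <- 6
  subj_profiles <- vapply(subjects, function(s) {
    a <- base_alpha
    a[subj_core[[s]]] <- 3
    prior <- a / sum(a)
    w <- rgamma(length(ko_b), shape = cfg$dirichlet_concentration * prior)
    w / sum(w)
  }, numeric(length(ko_b)))
  rownames(subj_profiles) <- ko_b

  ## probiotic effect (default 0 = null): perturb a fixed KO set at
  ## time point 2 in the probiotic group
  effect_kos <- sample(core, 10L)
  sample_profiles <- vapply(seq_len(nrow(meta)), function(r) {
    w <- subj_profiles[, meta$subject_id[r]] *
      exp(rnorm(length(ko_b), sd = cfg$temporal_sd))
    if (cfg$probiotic_effect > 0 && meta$group[r] == "probiotic" &&
        meta$time_point[r] == 2L)
      w[effect_kos] <- w[effect_kos] * (1 + cfg$probiotic_effect)
    w / sum(w)
  }, numeric(length(ko_b)))
  dimnames(sample_profiles) <- list(ko_b, samples)

  ## --- human KO profiles with planted human-bacterial coupling ------
  alpha_h <- setNames(c(rep(4, min(15L, cfg$n_human_kos)),
                        rep(0.5, max(0L, cfg$n_human_kos - 15L))), ko_h)
  human_profiles <- vapply(subjects, function(s) {
    w <- rgamma(length(ko_h), shape = 100 * alpha_h / sum(alpha_h))
    w / sum(w)
  }, numeric(length(ko_h)))
  rownames(human_profiles) <- ko_h
  human_sample <- vapply(seq_len(nrow(meta)), function(r) {
    w <- human_profiles[, meta$subject_id[r]] *
      exp(rnorm(length(ko_h), sd = cfg$temporal_sd))
    w / sum(w)
  }, numeric(length(ko_h)))
  dimnames(human_sample) <- list(ko_h, samples)

  planted_pairs <- data.frame(human_ko = character(0),
                              bacterial_ko = character(0))
  if (cfg$n_planted_pairs > 0L) {
    hk <- sample(ko_h[-seq_len(min(15L, cfg$n_human_kos))],
                 cfg$n_planted_pairs)
    bk <- sample(core, cfg$n_planted_pairs)
    planted_pairs <- data.frame(human_ko = hk, bacterial_ko = bk,
                                stringsAsFactors = FALSE)
    for (i in seq_len(cfg$n_planted_pairs)) {
      b <- sample_profiles[bk[i], ]
      human_sample[hk[i], ] <- mean(human_sample[hk[i], ]) *
        b / mean(b)
    }
    human_sample <- sweep(human_sample, 2L, colSums(human_sample), "/")
  }

  ## --- subject-specific peptide repertoires -------------------------
  retain <- lapply(subjects, function(s) {
    r <- lapply(ko_peptides, function(p) {
      keep <- p[runif(length(p)) < cfg$peptide_retention]
      if (length(keep) == 0L) keep <- p[sample.int(length(p), 1L)]
      keep
    })
    r$ambiguous <- amb_peptides[runif(n_amb) < 0.5]
    if (!length(r$ambiguous)) r$ambiguous <- amb_peptides[1]
    r$untaxon <- untax_peptides[runif(n_untax) < 0.5]
    if (!length(r$untaxon)) r$untaxon <- untax_peptides[1]
    r
  })
  names(retain) <- subjects

  ## --- spectral counts ----------------------------------------------
  p_assigned <- 1 - cfg$untaxon_fraction
  p_bact <- 1 - cfg$eukaryotic_fraction - cfg$archaeal_fraction -
    cfg$ambiguous_fraction
  cat_probs <- c(bacterial = p_bact * p_assigned,
                 eukaryotic = cfg$eukaryotic_fraction * p_assigned,
                 archaeal = cfg$archaeal_fraction * p_assigned,
                 ambiguous = cfg$ambiguous_fraction * p_assigned,
                 untaxon = cfg$untaxon_fraction)

  draw_over_peptides <- function(total, kos, weights, subject_ret) {
    if (total == 0L) return(integer(0))
    ko_counts <- as.integer(rmultinom(1L, total, weights))
    names(ko_counts) <- kos
    out <- integer(0)
    for (ko in kos[ko_counts > 0L]) {
      peps <- subject_ret[[ko]]
      cnt <- rmultinom(1L, ko_counts[[ko]],
                       rep(1 / length(peps), length(peps)))[, 1]
      names(cnt) <- peps
      out <- c(out, cnt[cnt > 0L])
    }
    out
  }

  obs_list <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    sid <- meta$sample_id[r]; sub <- meta$subject_id[r]
    nc <- as.integer(rmultinom(1L, cfg$spectra_per_sample, cat_probs))
    names(nc) <- names(cat_probs)
    counts <- c(
      draw_over_peptides(nc[["bacterial"]], ko_b,
                         sample_profiles[, sid], retain[[sub]]),
      draw_over_peptides(nc[["eukaryotic"]], ko_h,
                         human_sample[, sid], retain[[sub]]))
    ## archaeal: uniform over the subject's archaeal repertoire
    arch_ret <- arch_peptides
    if (nc[["archaeal"]] > 0L) {
      cnt <- rmultinom(1L, nc[["archaeal"]],
                       rep(1 / length(arch_ret), length(arch_ret)))[, 1]
      names(cnt) <- arch_ret
      counts <- c(counts, cnt[cnt > 0L])
    }
    for (cat in c("ambiguous", "untaxon")) {
      if (nc[[cat]] > 0L) {
        peps <- retain[[sub]][[cat]]
        cnt <- rmultinom(1L, nc[[cat]],
                         rep(1 / length(peps), length(peps)))[, 1]
        names(cnt) <- peps
        counts <- c(counts, cnt[cnt > 0L])
      }
    }
    obs_list[[r]] <- data.frame(sample_id = sid,
                                peptide = names(counts),
                                spectral_count = as.integer(counts),
                                stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs_list)

  ## Display form: some leucines are written as isoleucine so the
  ## tables exercise I/L normalisation (fixed peptide -> display map).
  all_peps <- unique(observations$peptide)
  display <- setNames(all_peps, all_peps)
  flip <- runif(length(all_peps)) < 0.3
  display[flip] <- vapply(all_peps[flip], function(p) {
    pos <- gregexpr("L", p, fixed = TRUE)[[1]]
    if (pos[1] == -1L) return(p)
    i <- pos[sample.int(length(pos), 1L)]
    substr(p, i, i) <- "I"
    p
  }, "")
  observations$peptide <- unname(display[observations$peptide])
  observations <- observations[order(observations$sample_id,
                                     observations$peptide), ]
  rownames(observations) <- NULL

  ## --- gut metabolic module catalogue -------------------------------
  ## Module 1 is built from the three core KOs least likely to drop
  ## out of any sample (highest minimum relative abundance), so it is
  ## detected everywhere by construction.
  min_w <- apply(sample_profiles[core, , drop = FALSE], 1L, min)
  omnipresent <- names(sort(min_w, decreasing = TRUE))[1:3]
  modules <- vector("list", cfg$n_modules)
  modules[[1]] <- module_definition(
    "MS0001", "synthetic core module",
    list(lapply(omnipresent, identity)))
  for (mi in 2:cfg$n_modules) {
    n_pw <- sample(1:3, 1L)
    pathways <- lapply(seq_len(n_pw), function(p) {
      n_steps <- sample(3:6, 1L)
      lapply(seq_len(n_steps), function(s) {
        pool <- if (runif(1) < 0.5) core else ko_b
        sample(pool, sample(1:2, 1L))
      })
    })
    modules[[mi]] <- module_definition(
      sprintf("MS%04d", mi), sprintf("synthetic module %d", mi), pathways)
  }

  ## --- true taxon composition and matched 16S -----------------------
  rank_matrix <- function(rank_of) {
    pep_rank <- vapply(pep_taxa, function(tx) {
      if (length(tx) == 0L) return(NA_character_)
      u <- unique(rank_of[tx])
      if (length(u) == 1L && !is.na(u)) u else NA_character_
    }, "")
    feat <- pep_rank[observations$peptide |> normalize_peptide()]
    keep <- !is.na(feat)
    counts_matrix(feat[keep], observations$sample_id[keep],
                  observations$spectral_count[keep], samples)
  }
  phylum_of_all <- c(taxo$phylum_of,
                     setNames(rep("p_eury", 1L), "s_msmithii"))
  phylum_names <- c(setNames(tree$name[unique(taxo$phylum_of)],
                             unique(taxo$phylum_of)),
                    p_eury = "Euryarchaeota")
  phy_counts <- rank_matrix(setNames(phylum_names[phylum_of_all],
                                     names(phylum_of_all)))
  gen_counts <- rank_matrix(setNames(tree$name[taxo$genus_of],
                                     names(taxo$genus_of)))
  proteome_phyla <- to_percent(phy_counts)

  s16 <- sort(sample(samples, cfg$n_16s_samples))
  make_16s <- function(pct) {
    m <- unclass(pct)[, s16, drop = FALSE]
    out <- m
    for (f in rownames(m)) {
      x <- log(m[f, ] + 0.1)
      if (sd(x) == 0) x <- x + rnorm(length(x), sd = 1e-6)
      z <- (x - mean(x)) / sd(x)
      y <- cfg$cross_platform_cor * z +
        sqrt(1 - cfg$cross_platform_cor^2) * rnorm(length(z))
      out[f, ] <- pmax(exp(mean(x) + sd(x) * y) - 0.1, 1e-6)
    }
    abundance_matrix(sweep(out, 2L, colSums(out), "/") * 100, "percent")
  }
  sixteen_s_phylum <- make_16s(proteome_phyla)
  sixteen_s_genus <- make_16s(to_percent(gen_counts))

  truth <- list(config = cfg,
                subject_profiles = subj_profiles,
                sample_profiles = sample_profiles,
                human_sample_profiles = human_sample,
                subject_core_kos = subj_core,
                common_core_kos = core,
                peptide_info = pep_df,
                peptide_taxa = pep_taxa,
                planted_pairs = planted_pairs,
                proteome_phyla = proteome_phyla,
                planted_16s_cor = cfg$cross_platform_cor,
                effect_kos = effect_kos)

  structure(list(meta = meta, observations = observations, tree = tree,
                 maps = maps, modules = modules,
                 sixteen_s_phylum = sixteen_s_phylum,
                 sixteen_s_genus = sixteen_s_genus,
                 truth = truth),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$meta), "samples,",
      length(unique(x$meta$subject_id)), "subjects,",
      nrow(x$observations), "peptide observations\n")
  invisible(x)
}

#' Ground-truth tables of a synthetic cohort
#'
#' Extracts the planted structure of a generated bundle for use as a
#' test oracle: true per-subject and per-sample KO profiles, the true
#' taxon set (and LCA, computed on the stated taxa) of every generated
#' peptide, the module catalogue, and the planted human-bacterial and
#' cross-platform correlations.
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()]
#' @return list of ground-truth tables; `peptide_lca` gives, per
#'   generated peptide, its intended taxon set's LCA
#' @export
truth_record <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  tr <- bundle$truth
  lca <- vapply(tr$peptide_taxa, function(tx)
    if (length(tx) == 0L) "unassigned" else lca_taxa(bundle$tree, tx), "")
  tr$peptide_lca <- data.frame(peptide = names(tr$peptide_taxa),
                               true_lca = unname(lca),
                               category = tr$peptide_info$category,
                               stringsAsFactors = FALSE)
  tr
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Emits `meta.tsv`, `peptides.tsv`, `taxonomy.tsv`, the annotation
#' maps, `modules.gmm`, the matched 16S tables and the truth record.
#'
#' @param bundle a `cohort_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sample_meta(bundle$meta, file.path(dir, "meta.tsv"))
  write_peptide_table(bundle$observations, file.path(dir, "peptides.tsv"))
  write_taxonomy(bundle$tree, file.path(dir, "taxonomy.tsv"))
  write_annotation_maps(bundle$maps, file.path(dir, "maps"))
  write_module_definitions(bundle$modules, file.path(dir, "modules.gmm"))
  write_abundance_matrix(bundle$sixteen_s_phylum,
                         file.path(dir, "sixteen_s_phylum.tsv"))
  write_abundance_matrix(bundle$sixteen_s_genus,
                         file.path(dir, "sixteen_s_genus.tsv"))
  tr <- truth_record(bundle)
  tdir <- file.path(dir, "truth")
  if (!dir.exists(tdir)) dir.create(tdir)
  write_tsv(tr$peptide_lca, file.path(tdir, "peptide_lca.tsv"))
  write_tsv(tr$planted_pairs, file.path(tdir, "planted_pairs.tsv"))
  write_abundance_matrix(
    abundance_matrix(tr$sample_profiles * 100, "percent"),
    file.path(tdir, "sample_profiles.tsv"))
  invisible(dir)
}

#' Simulate independent human and bacterial KO matrices
#'
#' A null-model generator for validating false-discovery-rate control
#' and power of [correlate_human_bacterial()]: all features are
#' independent log-normal abundances except `n_planted` pairs coupled
#' through a Gaussian copula at Spearman correlation `rho`.
#'
#' @param n_human,n_bacterial,n_samples matrix dimensions
#' @param n_planted number of correlated (human, bacterial) pairs
#' @param rho target Spearman correlation of planted pairs
#' @param seed RNG seed
#' @return list with `human` and `bacterial` abundance matrices and
#'   the `planted` pair table
#' @export
simulate_ko_pair_matrices <- function(n_human, n_bacterial, n_samples,
                                      n_planted = 0L, rho = 0.8,
                                      seed = 1L) {
  set.seed(seed)
  samples <- sprintf("smp%02d", seq_len(n_samples))
  hk <- sprintf("K9%04d", seq_len(n_human))
  bk <- sprintf("K8%04d", seq_len(n_bacterial))
  H <- matrix(exp(rnorm(n_human * n_samples)), n_human, n_samples,
              dimnames = list(hk, samples))
  B <- matrix(exp(rnorm(n_bacterial * n_samples)), n_bacterial,
              n_samples, dimnames = list(bk, samples))
  planted <- data.frame(human_ko = character(0),
                        bacterial_ko = character(0))
  if (n_planted > 0L) {
    ## Pearson correlation of the Gaussian copula giving Spearman rho
    r_pearson <- 2 * sin(pi * rho / 6)
    ih <- seq_len(n_planted)
    for (i in ih) {
      z <- log(B[i, ])
      z <- (z - mean(z)) / sd(z)
      H[i, ] <- exp(r_pearson * z +
                      sqrt(1 - r_pearson^2) * rnorm(n_samples))
    }
    planted <- data.frame(human_ko = hk[ih], bacterial_ko = bk[ih],
                          stringsAsFactors = FALSE)
  }
  list(human = abundance_matrix(H, "counts"),
       bacterial = abundance_matrix(B, "counts"),
       planted = planted)
}
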