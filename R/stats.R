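## Comparative statistics: presence/absence Jaccard clustering,
## correlation clustering, FDR-screened Spearman correlation,
## Fisher exact group tests, Shannon diversity, platform concordance.

#' Jaccard distance matrix between peptide presence sets
#'
#' d(A, B) = 1 - |A intersect B| / |A union B|.
#'
#' @param sets named list: sample id -> character vector of peptides
#' @return a `dist` object over samples (lexicographic order)
#' @export
jaccard_distance <- function(sets) {
  if (length(sets) < 2L) stop("need at least two samples")
  sizes <- lengths(lapply(sets, unique))
  if (any(sizes == 0L))
    stop("empty peptide set for sample ", names(sets)[sizes == 0L][1])
  sets <- sets[order(names(sets))]
  items <- sort(unique(unlist(sets, use.names = FALSE)))
  m <- vapply(sets, function(s) items %in% s, logical(length(items)))
  inter <- crossprod(m * 1)
  sz <- colSums(m)
  uni <- outer(sz, sz, "+") - inter
  as.dist(1 - inter / uni)
}

#' Complete-linkage clustering of samples by peptide Jaccard distance
#'
#' Hierarchical clustering (complete linkage) of per-sample peptide
#' presence/absence using the Jaccard distance. Samples are ordered
#' lexicographically before clustering so ties break deterministically.
#'
#' @inheritParams jaccard_distance
#' @return an `hclust` object
#' @seealso [write_newick()], [correlation_cluster()]
#' @export
jaccard_cluster <- function(sets) {
  hclust(jaccard_distance(sets), method = "complete")
}

#' Complete-linkage clustering of samples by 1 - Pearson correlation
#'
#' Used both for 16S oligonucleotide profiles and for KO abundance
#' profiles; the distance between two sample columns is one minus
#' their Pearson correlation coefficient.
#'
#' @param m an [abundance_matrix()] (features x samples)
#' @return an `hclust` object
#' @export
correlation_cluster <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (ncol(m) < 2L) stop("need at least two samples")
  v <- apply(unclass(m), 2L, sd)
  if (any(v == 0))
    stop("zero-variance column: sample ", colnames(m)[v == 0][1])
  x <- unclass(m)[, order(colnames(m)), drop = FALSE]
  hclust(as.dist(1 - cor(x)), method = "complete")
}

#' Write a dendrogram in Newick format
#'
#' @param h an `hclust` object
#' @param path output file
#' @export
write_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' False-discovery-rate adjusted p-values (q-values)
#'
#' `method = "bh"` (default) is the Benjamini-Hochberg step-up
#' adjustment (pi0 = 1, conservative). `method = "storey"` rescales by
#' a smoothed estimate of the null proportion pi0, obtained by fitting
#' a smoothing spline to pi0(lambda) over a lambda grid and evaluating
#' at the largest lambda.
#'
#' @param p vector of p-values
#' @param method `"bh"` or `"storey"`
#' @return vector of q-values
#' @export
qvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  bh <- p.adjust(p, method = "BH")
  if (method == "bh") return(bh)
  lambda <- seq(0.05, 0.9, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l, na.rm = TRUE) / (1 - l), 0)
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- min(1, max(predict(fit, x = max(lambda))$y, 0))
  pmin(1, pi0 * bh)
}

## All permutations of 1..n as an n! x n matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## Two-sided Spearman p-values: t approximation for n >= 10, exact
## permutation enumeration for smaller n (mid-ranks throughout).
spearman_p <- function(rho, n, rx = NULL, ry = NULL) {
  if (n >= 10) {
    tt <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
    p[abs(rho) >= 1] <- 0
    return(pmin(p, 1))
  }
  perms <- all_permutations(n)
  ryc <- ry - mean(ry)
  rxc <- rx - mean(rx)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  rho_null <- as.vector((matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom)
  mean(abs(rho_null) >= abs(rho) - 1e-12)
}

#' Spearman correlation screen between human and bacterial functions
#'
#' Computes the Spearman correlation (mid-rank ties) between every
#' human KO and every bacterial KO across the shared samples, with
#' two-sided p-values (t approximation for n >= 10, exact permutation
#' for smaller n) and q-values over the full pair family. Records with
#' p < 0.05 and q < `alpha` form the reported hit list; the full table
#' is also returned.
#'
#' @param human_ko,bacterial_ko [abundance_matrix()] objects sharing
#'   sample columns (at least 4 in common)
#' @param alpha q-value threshold for the hit list (default 0.05)
#' @param method q-value method, see [qvalues()]
#' @return list with data.frames `records` (filtered) and `all`
#'   (every pair: `human_ko`, `bacterial_ko`, `rho`, `p_value`,
#'   `q_value`)
#' @export
correlate_human_bacterial <- function(human_ko, bacterial_ko,
                                      alpha = 0.05,
                                      method = c("bh", "storey")) {
  method <- match.arg(method)
  stopifnot(inherits(human_ko, "abundance_matrix"),
            inherits(bacterial_ko, "abundance_matrix"))
  samples <- intersect(colnames(human_ko), colnames(bacterial_ko))
  n <- length(samples)
  if (n < 4L)
    stop("need at least 4 common samples (got ", n, ")")
  H <- unclass(human_ko)[, samples, drop = FALSE]
  B <- unclass(bacterial_ko)[, samples, drop = FALSE]
  drop0 <- function(m, lab) {
    v <- apply(m, 1L, sd)
    if (any(v == 0))
      warning(sum(v == 0), " zero-variance ", lab,
              " feature(s) dropped", call. = FALSE)
    m[v > 0, , drop = FALSE]
  }
  H <- drop0(H, "human"); B <- drop0(B, "bacterial")
  RH <- t(apply(H, 1L, rank)); RB <- t(apply(B, 1L, rank))
  rho <- cor(t(RH), t(RB))
  pairs <- expand.grid(human_ko = rownames(H), bacterial_ko = rownames(B),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- rho[cbind(pairs$human_ko, pairs$bacterial_ko)]
  if (n >= 10) {
    p <- spearman_p(r, n)
  } else {
    p <- mapply(function(h, b, rr)
      spearman_p(rr, n, RH[h, ], RB[b, ]),
      pairs$human_ko, pairs$bacterial_ko, r)
  }
  q <- qvalues(p, method)
  all <- data.frame(pairs, rho = r, p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  records <- all[all$p_value < 0.05 & all$q_value < alpha, , drop = FALSE]
  records <- records[order(records$q_value, records$p_value), ]
  rownames(records) <- NULL
  list(records = records, all = all)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric computation: with margins fixed, the p-value
#' sums the probabilities of all tables no more probable than the
#' observed one (relative tolerance 1e-7 for ties, as is conventional).
#'
#' @param tab a 2x2 matrix of non-negative integer counts
#' @return the two-sided p-value
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m + n == 0L) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bacterial/eukaryotic ratio per sample and probiotic group test
#'
#' Computes the per-sample ratio of bacterial to eukaryotic spectral
#' counts, correlates the per-subject time-course ratio trajectories
#' (Pearson), cuts the complete-linkage tree of 1 - r into two
#' clusters, and tests the 2x2 table of cluster membership against
#' intervention group with a two-sided Fisher exact test. Additionally
#' runs a paired two-sided Wilcoxon signed-rank test of time point 1
#' versus time point 2 ratios within the probiotic group.
#'
#' @param assignments output of [assign_lca()]
#' @param observations peptide observations
#' @param meta sample metadata
#' @param pseudocount added to both domain counts (default 0; a sample
#'   with zero eukaryotic spectra raises an error advising a
#'   pseudocount)
#' @return list with the per-sample `ratios` table, per-subject
#'   `clusters`, the `contingency` table, `fisher_p`, `wilcoxon_p` and
#'   the subject `dendrogram`
#' @export
ratio_group_test <- function(assignments, observations, meta,
                             pseudocount = 0) {
  obs <- normalize_observations(observations)
  cls <- setNames(assignments$domain_class, assignments$peptide)
  obs$class <- cls[obs$peptide]
  bact <- tapply(obs$spectral_count[obs$class == "bacterial"],
                 obs$sample_id[obs$class == "bacterial"], sum)
  euk <- tapply(obs$spectral_count[obs$class == "eukaryotic"],
                obs$sample_id[obs$class == "eukaryotic"], sum)
  meta <- meta[order(meta$subject_id, meta$time_point), ]
  b <- bact[meta$sample_id]; e <- euk[meta$sample_id]
  b[is.na(b)] <- 0; e[is.na(e)] <- 0
  b <- b + pseudocount; e <- e + pseudocount
  if (any(e == 0))
    stop("sample ", meta$sample_id[which(e == 0)[1]],
         " has no eukaryotic spectra; use a pseudocount > 0")
  ratios <- data.frame(meta, bacterial = as.numeric(b),
                       eukaryotic = as.numeric(e),
                       ratio = as.numeric(b / e),
                       stringsAsFactors = FALSE)
  subjects <- sort(unique(meta$subject_id))
  tps <- sort(unique(meta$time_point))
  traj <- t(vapply(subjects, function(s) {
    r <- ratios$ratio[ratios$subject_id == s][order(
      ratios$time_point[ratios$subject_id == s])]
    if (length(r) != length(tps))
      stop("subject ", s, " lacks samples at some time points")
    r
  }, numeric(length(tps))))
  rownames(traj) <- subjects
  v <- apply(traj, 1L, sd)
  if (any(v == 0))
    stop("subject ", subjects[v == 0][1],
         " has a constant ratio trajectory; Pearson undefined")
  h <- hclust(as.dist(1 - cor(t(traj))), method = "complete")
  clusters <- cutree(h, k = 2)
  grp <- vapply(subjects, function(s)
    meta$group[meta$subject_id == s][1], "")
  tab <- table(factor(clusters, levels = 1:2),
               factor(grp, levels = c("placebo", "probiotic")))
  fisher_p <- fisher_exact_2x2(as.matrix(tab))
  prob <- subjects[grp == "probiotic"]
  wilcoxon_p <- if (length(prob) >= 2 && all(c(1, 2) %in% tps)) {
    suppressWarnings(wilcox.test(
      traj[prob, which(tps == 1)], traj[prob, which(tps == 2)],
      paired = TRUE, alternative = "two.sided")$p.value)
  } else NA_real_
  list(ratios = ratios, clusters = clusters,
       contingency = as.matrix(tab), fisher_p = fisher_p,
       wilcoxon_p = wilcoxon_p, dendrogram = h)
}

#' Shannon diversity index
#'
#' H = -sum p_i ln p_i over renormalised proportions; zero entries are
#' dropped.
#'
#' @param abundances non-negative vector of (relative) abundances for
#'   one sample
#' @return the Shannon index (natural log)
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  s <- sum(abundances)
  if (s <= 0) stop("all-zero abundance vector")
  p <- abundances / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Proteome versus 16S phylum concordance
#'
#' For each phylum present on both platforms, the Pearson correlation
#' across shared samples between spectral-count and 16S relative
#' abundances, with two-sided p-values and Benjamini-Hochberg q-values
#' across phyla. Also emits a paired summary table (median and
#' 0.25/0.75 quantiles per phylum per platform) for split-violin
#' display.
#'
#' @param proteome_phyla,sixteen_s_phyla [abundance_matrix()] objects
#'   on the percent scale with phyla in rows
#' @return list with data.frames `correlations` (`phylum`, `r`,
#'   `p_value`, `q_value`, `n`) and `summary`
#' @export
phylum_concordance <- function(proteome_phyla, sixteen_s_phyla) {
  stopifnot(inherits(proteome_phyla, "abundance_matrix"),
            inherits(sixteen_s_phyla, "abundance_matrix"))
  phyla <- intersect(rownames(proteome_phyla), rownames(sixteen_s_phyla))
  only <- c(setdiff(rownames(proteome_phyla), phyla),
            setdiff(rownames(sixteen_s_phyla), phyla))
  only <- setdiff(only, "unassigned")
  if (length(only))
    warning("phylum present on one platform only, excluded: ",
            paste(only, collapse = ", "), call. = FALSE)
  samples <- intersect(colnames(proteome_phyla),
                       colnames(sixteen_s_phyla))
  if (length(samples) < 3L) stop("need at least 3 shared samples")
  P <- unclass(proteome_phyla)[phyla, samples, drop = FALSE]
  S <- unclass(sixteen_s_phyla)[phyla, samples, drop = FALSE]
  n <- length(samples)
  r <- vapply(phyla, function(f) cor(P[f, ], S[f, ]), 0)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- pmin(2 * pt(tt, df = n - 2, lower.tail = FALSE), 1)
  q <- qvalues(p, "bh")
  correlations <- data.frame(phylum = phyla, r = r, p_value = p,
                             q_value = q, n = n,
                             stringsAsFactors = FALSE)
  rownames(correlations) <- NULL
  summ <- do.call(rbind, lapply(phyla, function(f)
    do.call(rbind, lapply(c("proteome", "16S"), function(pl) {
      x <- if (pl == "proteome") P[f, ] else S[f, ]
      data.frame(phylum = f, platform = pl,
                 median = median(x),
                 q25 = unname(quantile(x, 0.25)),
                 q75 = unname(quantile(x, 0.75)),
                 stringsAsFactors = FALSE)
    }))))
  rownames(summ) <- NULL
  list(correlations = correlations, summary = summ)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same
#' items; 1 for identical partitions, approximately 0 for independent
#' ones.
#'
#' @param a,b vectors of cluster labels of equal length
#' @return the adjusted Rand index
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
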