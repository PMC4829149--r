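#' Score one gut metabolic module against a sample's KO counts
#'
#' A module is a set of alternative pathways; each pathway an ordered
#' list of steps; each step a set of interchangeable KOs. For each
#' pathway, the abundance of a step is the maximum count over its
#' alternative KOs (absent KOs count 0) and a step is detected when its
#' abundance is positive; pathway coverage is the fraction of detected
#' steps. The best pathway maximises coverage (ties broken by higher
#' median step abundance, then lower pathway index). The module is
#' detected iff best coverage strictly exceeds 2/3, and its abundance
#' is then the median of the best pathway's step abundances (zeros
#' included); otherwise abundance is 0.
#'
#' @param module a [module_definition()]
#' @param ko_counts named numeric vector of KO spectral counts for one
#'   sample; KOs absent from the vector count as 0
#' @return list with `module_id`, `best_pathway_index`, `coverage`,
#'   `detected`, `abundance`
#' @export
score_module <- function(module, ko_counts) {
  stopifnot(inherits(module, "module_definition"))
  if (any(ko_counts < 0)) stop("KO counts must be non-negative")
  best <- list(idx = 1L, coverage = -1, abundance = -1)
  for (j in seq_along(module$pathways)) {
    steps <- module$pathways[[j]]
    step_ab <- vapply(steps, function(kos) {
      v <- ko_counts[kos]
      v[is.na(v)] <- 0
      max(v)
    }, 0)
    coverage <- mean(step_ab > 0)
    med <- median(step_ab)
    if (coverage > best$coverage ||
        (coverage == best$coverage && med > best$abundance)) {
      best <- list(idx = j, coverage = coverage, abundance = med)
    }
  }
  detected <- best$coverage > 2 / 3
  list(module_id = module$module_id,
       best_pathway_index = best$idx,
       coverage = best$coverage,
       detected = detected,
       abundance = if (detected) best$abundance else 0)
}

#' Score all modules over a KO count matrix
#'
#' Applies [score_module()] to every (module, sample) pair of a
#' post-filter bacterial KO matrix.
#'
#' @param modules list of [module_definition()] objects
#' @param ko_matrix an [abundance_matrix()] of KO counts (KOs in rows)
#' @return list with module x sample matrices `coverage`, `abundance`
#'   and `detected`, and a `summary` data.frame with, per module, the
#'   number of samples in which it was detected
#' @export
score_gmm <- function(modules, ko_matrix) {
  stopifnot(inherits(ko_matrix, "abundance_matrix"))
  if (am_scale(ko_matrix) != "counts")
    stop("score_gmm expects a counts matrix")
  mids <- vapply(modules, function(m) m$module_id, "")
  samples <- colnames(ko_matrix)
  coverage <- abundance <- matrix(0, length(modules), length(samples),
                                  dimnames = list(mids, samples))
  detected <- matrix(FALSE, length(modules), length(samples),
                     dimnames = list(mids, samples))
  for (s in samples) {
    counts <- setNames(unclass(ko_matrix)[, s], rownames(ko_matrix))
    for (i in seq_along(modules)) {
      res <- score_module(modules[[i]], counts)
      coverage[i, s] <- res$coverage
      abundance[i, s] <- res$abundance
      detected[i, s] <- res$detected
    }
  }
  list(coverage = coverage, abundance = abundance, detected = detected,
       summary = data.frame(module_id = mids,
                            n_samples_detected = rowSums(detected),
                            stringsAsFactors = FALSE))
}
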