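#' Per-individual KO presence sets
#'
#' All samples of a subject are combined: the subject's KO set is the
#' union of KOs with positive count in any of the subject's samples.
#' Computed on the unfiltered KO matrix at the terminal (fourth) KO
#' level.
#'
#' @param ko_matrix an [abundance_matrix()] of KO counts
#' @param meta sample metadata (see [read_sample_meta()]); every
#'   subject must own at least one column of `ko_matrix`
#' @return named list: subject id -> character vector of KOs
#' @export
per_individual_ko_sets <- function(ko_matrix, meta) {
  stopifnot(inherits(ko_matrix, "abundance_matrix"))
  subjects <- sort(unique(meta$subject_id))
  kos <- rownames(ko_matrix)
  out <- lapply(subjects, function(sub) {
    samp <- intersect(meta$sample_id[meta$subject_id == sub],
                      colnames(ko_matrix))
    if (length(samp) == 0L)
      stop("subject ", sub, " has no samples in the KO matrix")
    m <- unclass(ko_matrix)[, samp, drop = FALSE]
    kos[rowSums(m) > 0]
  })
  names(out) <- subjects
  out
}

#' Bootstrap rarefaction of accumulated and core KOs
#'
#' At each interval n, `replicates` bootstrap draws of n subjects are
#' taken uniformly *without replacement* (combination sampling); the
#' accumulation statistic counts KOs present in at least one drawn
#' subject (union) and the core statistic counts KOs present in every
#' drawn subject (intersection).
#'
#' @param ko_sets named list of per-subject KO sets (see
#'   [per_individual_ko_sets()])
#' @param intervals integer vector of subset sizes (default 2 up to
#'   the number of subjects)
#' @param replicates bootstrap replicates per interval (default 1000)
#' @param seed integer seed for reproducibility
#' @return object of class `rarefaction_curves`: list with integer
#'   matrices `accumulation` and `core` (replicates x intervals) and a
#'   `summary` data.frame of means and 2.5%/97.5% quantiles
#' @export
rarefy_ko_sets <- function(ko_sets, intervals = NULL, replicates = 1000,
                           seed = 1L) {
  K <- length(ko_sets)
  if (K < 1L) stop("no subjects")
  if (is.null(intervals)) intervals <- seq(2L, K)
  intervals <- as.integer(intervals)
  if (any(intervals < 1L) || any(intervals > K))
    stop("intervals must lie in 1..", K)
  if (replicates < 1L) stop("replicates must be >= 1")
  kos <- sort(unique(unlist(ko_sets, use.names = FALSE)))
  ## subjects x KOs presence matrix
  pres <- t(vapply(ko_sets, function(s) kos %in% s,
                   logical(length(kos))))
  set.seed(seed)
  acc <- core <- matrix(0L, replicates, length(intervals),
                        dimnames = list(NULL, as.character(intervals)))
  for (j in seq_along(intervals)) {
    n <- intervals[j]
    for (r in seq_len(replicates)) {
      idx <- sample.int(K, n, replace = FALSE)
      hits <- colSums(pres[idx, , drop = FALSE])
      acc[r, j] <- sum(hits > 0L)
      core[r, j] <- sum(hits == n)
    }
  }
  summ <- do.call(rbind, lapply(c("accumulation", "core"), function(st) {
    m <- if (st == "accumulation") acc else core
    data.frame(statistic = st, n = intervals,
               mean = colMeans(m),
               q025 = apply(m, 2L, quantile, 0.025),
               q975 = apply(m, 2L, quantile, 0.975),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(accumulation = acc, core = core, summary = summ,
                 intervals = intervals, n_kos = length(kos)),
            class = "rarefaction_curves")
}

#' @export
print.rarefaction_curves <- function(x, ...) {
  cat("rarefaction_curves over", ncol(x$accumulation), "intervals,",
      nrow(x$accumulation), "bootstrap replicates,",
      x$n_kos, "KOs total\n")
  print(x$summary)
  invisible(x)
}
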