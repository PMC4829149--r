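## Spectral-count functional and taxonomic profiling: spectra per
## peptide per class are summed into feature x sample count matrices.

## Normalise peptides and merge rows that collide after I/L equating.
normalize_observations <- function(observations) {
  obs <- observations
  obs$peptide <- normalize_peptide(obs$peptide)
  key <- paste(obs$sample_id, obs$peptide, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(obs$spectral_count, key, sum)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    obs <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                      peptide = vapply(parts, `[`, "", 2L),
                      spectral_count = as.numeric(agg),
                      stringsAsFactors = FALSE)
  }
  obs[order(obs$sample_id, obs$peptide), , drop = FALSE]
}

counts_matrix <- function(feature, sample, weight, samples) {
  features <- sort(unique(feature))
  tab <- tapply(weight, list(factor(feature, levels = features),
                             factor(sample, levels = samples)),
                sum, default = 0)
  tab <- matrix(tab, nrow = length(features), ncol = length(samples),
                dimnames = list(features, samples))
  abundance_matrix(tab, "counts")
}

#' Aggregate spectral counts per functional or taxonomic class
#'
#' Sums spectra per feature per sample. Supported levels:
#' \describe{
#'   \item{`peptide`}{each normalised peptide is its own feature.}
#'   \item{`ko`, `cog`}{features are the KO / COG ids a peptide maps
#'     to. A peptide mapping to k > 1 features contributes its full
#'     count to each under `share = "full"` (the default, mirroring
#'     winner-set style assignment) or `count/k` under
#'     `share = "fractional"`.}
#'   \item{`taxon`}{features are taxa at `rank`; a peptide contributes
#'     to rank r iff its LCA is at or below r (its LCA's ancestor at
#'     rank r); peptides whose LCA sits above r are excluded at that
#'     rank (counted as `unassigned`).}
#' }
#' With `restrict_taxon`, only peptides whose LCA is the given taxon or
#' a descendant contribute — a taxon-restricted functional profile
#' (e.g. KOs of *Faecalibacterium prausnitzii* only).
#'
#' When `include_unassigned = TRUE` an explicit `unassigned` feature
#' row collects the spectra of peptides with no mapping at the chosen
#' level, so that (under fractional sharing, or when mappings are
#' single-valued) feature counts plus unassigned equal the per-sample
#' spectral totals.
#'
#' @param observations peptide observations (`sample_id`, `peptide`,
#'   `spectral_count`)
#' @param level `"peptide"`, `"ko"`, `"cog"` or `"taxon"`
#' @param maps an [annotation_maps()] (required for `ko`/`cog`)
#' @param assignments output of [assign_lca()] (required for `taxon`
#'   or `restrict_taxon`)
#' @param tree a [taxonomy_tree()] (required for `taxon` or
#'   `restrict_taxon`)
#' @param rank taxonomic rank for `level = "taxon"`
#' @param restrict_taxon taxon id or name restricting the profile to
#'   one clade
#' @param share `"full"` or `"fractional"` count sharing for
#'   multi-mapped peptides
#' @param include_unassigned keep an explicit `unassigned` feature row
#' @param taxon_label label taxon features by scientific `"name"`
#'   (default, matching 16S tables) or by `"id"`
#' @return an [abundance_matrix()] on the counts scale
#' @export
aggregate_profile <- function(observations,
                              level = c("ko", "cog", "peptide", "taxon"),
                              maps = NULL, assignments = NULL, tree = NULL,
                              rank = NULL, restrict_taxon = NULL,
                              share = c("full", "fractional"),
                              include_unassigned = TRUE,
                              taxon_label = c("name", "id")) {
  level <- match.arg(level)
  share <- match.arg(share)
  obs <- normalize_observations(observations)
  samples <- sort(unique(obs$sample_id))

  if (!is.null(restrict_taxon)) {
    if (is.null(assignments) || is.null(tree))
      stop("restrict_taxon requires assignments and tree")
    tid <- if (restrict_taxon %in% names(tree$parent)) restrict_taxon
           else find_taxon(tree, restrict_taxon)[1]
    if (is.na(tid) || length(tid) == 0L)
      stop("restrict_taxon '", restrict_taxon, "' not found in the tree")
    lca <- setNames(assignments$lca_taxon, assignments$peptide)
    in_clade <- vapply(lca[obs$peptide], function(t)
      !is.na(t) && t != "unassigned" && is_in_clade(tree, t, tid), TRUE)
    obs <- obs[in_clade, , drop = FALSE]
    if (nrow(obs) == 0L)
      stop("no peptides assigned at or below taxon ", tid)
  }

  if (level == "peptide") {
    return(counts_matrix(obs$peptide, obs$sample_id, obs$spectral_count,
                         samples))
  }

  if (level %in% c("ko", "cog")) {
    if (is.null(maps)) stop("level '", level, "' requires maps")
    lookup <- if (level == "ko") maps$peptide_to_kos else maps$peptide_to_cogs
    feats <- lookup[obs$peptide]
    k <- lengths(feats)
    mapped <- k > 0L
    feature <- unlist(feats[mapped], use.names = FALSE)
    sample <- rep(obs$sample_id[mapped], k[mapped])
    weight <- rep(obs$spectral_count[mapped], k[mapped])
    if (share == "fractional") weight <- weight / rep(k[mapped], k[mapped])
    if (include_unassigned && any(!mapped)) {
      feature <- c(feature, rep("unassigned", sum(!mapped)))
      sample <- c(sample, obs$sample_id[!mapped])
      weight <- c(weight, obs$spectral_count[!mapped])
    }
    return(counts_matrix(feature, sample, weight, samples))
  }

  ## level == "taxon"
  if (is.null(assignments) || is.null(tree))
    stop("level 'taxon' requires assignments and tree")
  if (is.null(rank) || !rank %in% TAXON_RANKS)
    stop("level 'taxon' requires a valid rank")
  lca <- setNames(assignments$lca_taxon, assignments$peptide)
  peps <- unique(obs$peptide)
  at_rank <- vapply(peps, function(p) {
    t <- lca[[p]]
    if (is.null(t) || is.na(t) || t == "unassigned") return(NA_character_)
    chain <- ancestors(tree, t)
    hit <- chain[tree$rank[chain] == rank]
    if (length(hit)) hit[1] else NA_character_
  }, "")
  taxon_label <- match.arg(taxon_label)
  if (taxon_label == "name")
    at_rank[!is.na(at_rank)] <- tree$name[at_rank[!is.na(at_rank)]]
  feature <- at_rank[obs$peptide]
  keep <- !is.na(feature)
  f <- feature[keep]; s <- obs$sample_id[keep]
  w <- obs$spectral_count[keep]
  if (include_unassigned && any(!keep)) {
    f <- c(f, rep("unassigned", sum(!keep)))
    s <- c(s, obs$sample_id[!keep])
    w <- c(w, obs$spectral_count[!keep])
  }
  counts_matrix(f, s, w, samples)
}

#' Relative COG family distribution per sample
#'
#' Spectra are summed per one-letter COG functional family. A peptide
#' whose COG annotations span more than one family letter is counted
#' under `ambiguous`; a peptide with no COG annotation under
#' `unassigned`. Each sample column sums to 100.
#'
#' @param observations peptide observations
#' @param maps an [annotation_maps()] with COG annotations
#' @return an [abundance_matrix()] on the percent scale
#' @export
cog_family_profile <- function(observations, maps) {
  stopifnot(inherits(maps, "annotation_maps"))
  obs <- normalize_observations(observations)
  samples <- sort(unique(obs$sample_id))
  peps <- unique(obs$peptide)
  fam_of <- vapply(peps, function(p) {
    cogs <- maps$peptide_to_cogs[[p]]
    if (is.null(cogs) || length(cogs) == 0L) return("unassigned")
    letters <- unique(unlist(strsplit(
      unname(maps$cog_families[cogs]), "")))
    letters <- letters[!is.na(letters)]
    if (length(letters) == 0L) "unassigned"
    else if (length(letters) > 1L) "ambiguous"
    else letters
  }, "")
  counts <- counts_matrix(fam_of[obs$peptide], obs$sample_id,
                          obs$spectral_count, samples)
  to_percent(counts)
}

#' Per-sample peptide presence sets
#'
#' @param observations peptide observations
#' @return named list: sample id -> character vector of distinct
#'   normalised peptides
#' @export
peptide_presence_sets <- function(observations) {
  obs <- normalize_observations(observations)
  split(obs$peptide, obs$sample_id)
}
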