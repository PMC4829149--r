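#' Isoleucine/leucine peptide normalisation
#'
#' Mass spectrometry cannot distinguish isoleucine from leucine, so
#' every `I` is replaced by `L` before any peptide matching. The same
#' normalisation is applied to query peptides and to map keys (see
#' [annotation_maps()]). Idempotent.
#'
#' @param peptide character vector of uppercase amino-acid strings
#' @return the normalised peptide strings
#' @export
normalize_peptide <- function(peptide) {
  ok <- grepl(paste0("^[", paste(AA_VALID, collapse = ""), "]+$"),
              peptide)
  if (!all(ok))
    stop("non-standard residue in peptide '", peptide[which(!ok)[1]], "'")
  gsub("I", "L", peptide, fixed = TRUE)
}

#' Fully tryptic fragments of a peptide
#'
#' Trypsin cleaves after lysine (K) or arginine (R) except when the
#' next residue is proline (P). A peptide carrying internal cleavage
#' sites (missed cleavages) is split into its fully tryptic fragments;
#' the fragments concatenate back to the input. A peptide with no
#' internal site returns itself.
#'
#' @param peptide a single peptide string
#' @return character vector of fragments, in order
#' @export
tryptic_fragments <- function(peptide) {
  stopifnot(length(peptide) == 1L, nchar(peptide) >= 1L)
  marked <- gsub("(?<=[KR])(?!P)", "\x01", peptide, perl = TRUE)
  frags <- strsplit(marked, "\x01", fixed = TRUE)[[1]]
  frags[nzchar(frags)]
}

#' Lowest-common-ancestor taxonomic assignment of peptides
#'
#' Each peptide is I/L-normalised and split into its fully tryptic
#' fragments; each fragment is looked up in the peptide-to-taxon map
#' (duplicate taxa within a fragment collapse to one). Under the
#' default `combine = "intersection"` semantics every fragment must
#' match, and the peptide's taxon set is the intersection of the
#' fragment sets — the conservative reading of combining results per
#' miss-cleaved peptide; `combine = "union"` instead unions the sets of
#' the fragments that matched. The reported taxon is the lowest common
#' ancestor (LCA) of the resulting set. The domain class is derived
#' from the domain-rank ancestor of the LCA; a peptide whose matched
#' taxa span two or more domains (LCA at or above the domain level) is
#' `ambiguous`, and a peptide with no (or an empty) taxon set is
#' `unassigned`.
#'
#' @param peptides character vector of peptides (need not be
#'   normalised or unique)
#' @param maps an [annotation_maps()]; taxa must exist in `tree` (see
#'   [validate_annotation_taxa()])
#' @param tree a [taxonomy_tree()]
#' @param combine `"intersection"` (all fragments must match) or
#'   `"union"`
#' @return data.frame with one row per distinct normalised peptide:
#'   `peptide`, `lca_taxon` (taxon id or `"unassigned"`),
#'   `domain_class` (`bacterial`, `archaeal`, `eukaryotic`,
#'   `ambiguous`, or `unassigned`)
#' @export
assign_lca <- function(peptides, maps, tree,
                       combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  stopifnot(inherits(maps, "annotation_maps"),
            inherits(tree, "taxonomy_tree"))
  peps <- unique(normalize_peptide(peptides))
  lca <- character(length(peps))
  cls <- character(length(peps))
  for (i in seq_along(peps)) {
    frags <- tryptic_fragments(peps[i])
    sets <- maps$peptide_to_taxa[frags]
    matched <- !vapply(sets, is.null, TRUE)
    if (combine == "intersection") {
      taxa <- if (all(matched)) Reduce(intersect, sets) else character()
    } else {
      taxa <- unique(unlist(sets[matched], use.names = FALSE))
    }
    if (length(taxa) == 0L) {
      lca[i] <- "unassigned"; cls[i] <- "unassigned"
    } else {
      node <- lca_taxa(tree, taxa)
      lca[i] <- node
      dn <- tree$domain_name[[node]]
      cls[i] <- if (!is.na(dn) && !is.na(domain_name_to_class(dn)))
        domain_name_to_class(dn) else "ambiguous"
    }
  }
  data.frame(peptide = peps, lca_taxon = lca, domain_class = cls,
             stringsAsFactors = FALSE)
}

#' Per-sample domain composition
#'
#' Percentages of `bacterial`, `archaeal`, `eukaryotic` and
#' `ambiguous` assignments per sample, computed over taxonomically
#' assigned peptides only (the denominator excludes `unassigned`), so
#' the four classes sum to 100. Weighting is by distinct peptide
#' (default) or by spectral count.
#'
#' @param assignments output of [assign_lca()]
#' @param observations peptide observation data.frame (`sample_id`,
#'   `peptide`, `spectral_count`)
#' @param weight `"peptide"` or `"spectrum"`
#' @return 4 x samples `abundance_matrix` on the percent scale
#' @export
domain_fractions <- function(assignments, observations,
                             weight = c("peptide", "spectrum")) {
  weight <- match.arg(weight)
  obs <- observations
  obs$peptide <- normalize_peptide(obs$peptide)
  cls <- setNames(assignments$domain_class, assignments$peptide)
  obs$class <- cls[obs$peptide]
  if (anyNA(obs$class))
    stop("assignments do not cover peptide '",
         obs$peptide[which(is.na(obs$class))[1]], "'")
  obs <- obs[obs$class != "unassigned", , drop = FALSE]
  samples <- sort(unique(observations$sample_id))
  empty <- setdiff(samples, unique(obs$sample_id))
  if (length(empty))
    stop("sample ", empty[1], " has no taxonomically assigned peptides")
  w <- if (weight == "spectrum") obs$spectral_count else rep(1, nrow(obs))
  tab <- tapply(w, list(factor(obs$class, levels = DOMAIN_CLASSES),
                        factor(obs$sample_id, levels = samples)),
                sum, default = 0)
  pct <- sweep(tab, 2L, colSums(tab), "/") * 100
  abundance_matrix(pct, "percent")
}

#' Peptides of host (Chordata) origin
#'
#' Selects peptides whose LCA is the named host clade or one of its
#' descendants — peptides with "at least" a Chordata-level assignment.
#' Peptides whose LCA is an ancestor of the clade (e.g. Eukaryota) are
#' excluded.
#'
#' @param assignments output of [assign_lca()]
#' @param tree a [taxonomy_tree()]
#' @param clade name of the host clade node (default `"Chordata"`)
#' @return character vector of normalised peptides
#' @export
chordata_subset <- function(assignments, tree, clade = "Chordata") {
  ids <- find_taxon(tree, clade)
  if (length(ids) == 0L)
    stop("taxon named '", clade, "' not found in the tree; ",
         "name the host clade via the clade argument (or host_clade ",
         "in the configuration)")
  clade_id <- ids[1]
  keep <- vapply(assignments$lca_taxon, function(t)
    t != "unassigned" && is_in_clade(tree, t, clade_id), TRUE)
  assignments$peptide[keep]
}
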