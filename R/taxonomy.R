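#' Construct and validate a taxonomy tree
#'
#' A taxonomy tree is a rooted tree of taxa with ranks, used as the
#' substrate for lowest-common-ancestor (LCA) assignment and for
#' partitioning spectra into domains of life. The root points to itself;
#' every other node must be reachable from the root.
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`
#'   and `name`. Ranks must be one of `root`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`, `no_rank`.
#' @return An object of class `taxonomy_tree` with per-node lookup
#'   vectors (`parent`, `rank`, `name`, `depth`, `domain_name`) indexed
#'   by `taxon_id`, plus the `nodes` table and the `root` id.
#' @export
taxonomy_tree <- function(nodes) {
  required <- c("taxon_id", "parent_id", "rank", "name")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stop("taxonomy nodes must be a data.frame with columns ",
         paste(required, collapse = ", "))
  nodes <- nodes[required]
  for (cl in required) nodes[[cl]] <- as.character(nodes[[cl]])
  if (anyDuplicated(nodes$taxon_id))
    stop("duplicated taxon_id: ",
         nodes$taxon_id[duplicated(nodes$taxon_id)][1])
  bad_rank <- setdiff(unique(nodes$rank), TAXON_RANKS)
  if (length(bad_rank))
    stop("unknown rank(s): ", paste(bad_rank, collapse = ", "))

  roots <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(roots) == 0L)
    stop("taxonomy has no root (no self-parented node)")
  if (length(roots) > 1L)
    stop("taxonomy has multiple roots: ", paste(roots, collapse = ", "))
  orphan <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(orphan))
    stop("orphan node(s): parent(s) ", paste(orphan, collapse = ", "),
         " absent from the tree (child ",
         nodes$taxon_id[match(orphan[1], nodes$parent_id)], ")")

  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  rank <- setNames(nodes$rank, nodes$taxon_id)
  name <- setNames(nodes$name, nodes$taxon_id)

  ## Depth by breadth-first propagation from the root; any node never
  ## reached sits on a cycle disconnected from the root.
  depth <- setNames(rep(NA_integer_, nrow(nodes)), nodes$taxon_id)
  depth[roots] <- 0L
  frontier <- roots
  while (length(frontier)) {
    children <- nodes$taxon_id[nodes$parent_id %in% frontier &
                                 is.na(depth[nodes$taxon_id])]
    depth[children] <- depth[parent[children]] + 1L
    frontier <- children
  }
  if (anyNA(depth))
    stop("cycle detected: taxon ", names(depth)[is.na(depth)][1],
         " is not reachable from the root")

  ## Domain-rank ancestor name per node, propagated root-down.
  domain_name <- setNames(rep(NA_character_, nrow(nodes)), nodes$taxon_id)
  ord <- names(sort(depth))
  for (id in ord) {
    if (rank[[id]] == "domain") domain_name[[id]] <- name[[id]]
    else if (id != roots) domain_name[[id]] <- domain_name[[parent[[id]]]]
  }

  structure(list(nodes = nodes, parent = parent, rank = rank,
                 name = name, depth = depth, domain_name = domain_name,
                 root = roots),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root =", x$root,
      "(max depth", max(x$depth), ")\n")
  print(table(x$rank))
  invisible(x)
}

#' Ancestor chain of a taxon
#'
#' @param tree a `taxonomy_tree`
#' @param taxon_id a single taxon id present in the tree
#' @return character vector from the taxon itself up to the root
#'   (inclusive).
#' @export
ancestors <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (is.na(match(taxon_id, names(tree$parent))))
    stop("unknown taxon_id: ", taxon_id)
  chain <- taxon_id
  while (taxon_id != tree$root) {
    taxon_id <- tree$parent[[taxon_id]]
    chain <- c(chain, taxon_id)
  }
  chain
}

## TRUE if `taxon_id` is `clade` or one of its descendants.
is_in_clade <- function(tree, taxon_id, clade) {
  clade %in% ancestors(tree, taxon_id)
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is ancestral to (or equal to) every taxon in
#' the set. Computed by depth-equalised pairwise ascent.
#'
#' @param tree a `taxonomy_tree`
#' @param taxon_ids non-empty character vector of taxon ids
#' @return a single taxon_id
#' @export
lca_taxa <- function(tree, taxon_ids) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxon_ids <- unique(taxon_ids)
  if (length(taxon_ids) == 0L) stop("empty taxon set")
  unknown <- setdiff(taxon_ids, names(tree$parent))
  if (length(unknown))
    stop("taxon absent from tree: ", paste(unknown, collapse = ", "))
  Reduce(function(a, b) lca2(tree, a, b), taxon_ids)
}

lca2 <- function(tree, a, b) {
  da <- tree$depth[[a]]; db <- tree$depth[[b]]
  while (da > db) { a <- tree$parent[[a]]; da <- da - 1L }
  while (db > da) { b <- tree$parent[[b]]; db <- db - 1L }
  while (a != b) { a <- tree$parent[[a]]; b <- tree$parent[[b]] }
  a
}

#' Find taxa by name
#'
#' @param tree a `taxonomy_tree`
#' @param name scientific name to look up (exact match)
#' @return character vector of matching taxon ids (possibly empty)
#' @export
find_taxon <- function(tree, name) {
  names(tree$name)[tree$name == name]
}
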