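#' Peptide annotation maps
#'
#' Bundles the peptide-to-taxon and peptide-to-function lookups used
#' throughout the pipeline. Peptide keys are isoleucine/leucine
#' normalised on construction (see [normalize_peptide()]); keys that
#' collide after normalisation are merged by set union. An unmapped
#' peptide is simply absent, which is allowed.
#'
#' @param peptide_to_taxa named list: peptide -> character vector of
#'   taxon ids
#' @param peptide_to_kos named list: peptide -> character vector of KO
#'   ids (`K` + 5 digits)
#' @param peptide_to_cogs named list: peptide -> character vector of
#'   COG ids
#' @param cog_families named character vector: COG id -> string of
#'   one-letter COG family codes (more than one letter marks the COG,
#'   and any peptide carrying it, as `ambiguous`)
#' @param ko_domain named character vector: KO id -> `"bacterial"` or
#'   `"human"`
#' @return an object of class `annotation_maps`
#' @export
annotation_maps <- function(peptide_to_taxa = list(),
                            peptide_to_kos = list(),
                            peptide_to_cogs = list(),
                            cog_families = character(),
                            ko_domain = character()) {
  norm_keys <- function(lst) {
    if (length(lst) == 0L) return(lst)
    keys <- normalize_peptide(names(lst))
    if (anyDuplicated(keys)) {
      merged <- tapply(lst, keys, function(x)
        sort(unique(unlist(x, use.names = FALSE))))
      lst <- lapply(merged, identity)
    } else {
      lst <- lapply(lst, function(x) sort(unique(x)))
      names(lst) <- keys
    }
    lst
  }
  peptide_to_taxa <- norm_keys(peptide_to_taxa)
  peptide_to_kos <- norm_keys(peptide_to_kos)
  peptide_to_cogs <- norm_keys(peptide_to_cogs)

  all_kos <- unlist(peptide_to_kos, use.names = FALSE)
  bad <- all_kos[!grepl("^K[0-9]{5}$", all_kos)]
  if (length(bad)) stop("malformed KO id: ", bad[1])
  if (length(cog_families)) {
    letters_used <- unlist(strsplit(unname(cog_families), ""))
    bad <- setdiff(letters_used, COG_FAMILY_ALPHABET)
    if (length(bad))
      stop("unknown COG family letter(s): ", paste(bad, collapse = ", "))
  }
  if (length(ko_domain) && !all(ko_domain %in% c("bacterial", "human")))
    stop("ko_domain values must be 'bacterial' or 'human'")

  structure(list(peptide_to_taxa = peptide_to_taxa,
                 peptide_to_kos = peptide_to_kos,
                 peptide_to_cogs = peptide_to_cogs,
                 cog_families = cog_families,
                 ko_domain = ko_domain),
            class = "annotation_maps")
}

#' @export
print.annotation_maps <- function(x, ...) {
  cat("annotation_maps:", length(x$peptide_to_taxa), "peptide->taxa,",
      length(x$peptide_to_kos), "peptide->KO,",
      length(x$peptide_to_cogs), "peptide->COG,",
      length(x$ko_domain), "KO domains\n")
  invisible(x)
}

#' Check that all mapped taxa exist in a taxonomy tree
#'
#' @param maps an `annotation_maps`
#' @param tree a `taxonomy_tree`
#' @return `maps`, invisibly, or an error naming the offending taxon
#' @export
validate_annotation_taxa <- function(maps, tree) {
  stopifnot(inherits(maps, "annotation_maps"),
            inherits(tree, "taxonomy_tree"))
  taxa <- unique(unlist(maps$peptide_to_taxa, use.names = FALSE))
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown))
    stop("annotation map references taxa absent from the tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  invisible(maps)
}

#' Read / write annotation maps as TSV
#'
#' `read_annotation_maps` expects up to four files: a peptide-taxon
#' table (`peptide`, `taxon_id`; one row per pair), a peptide-function
#' table (`peptide`, `ko`, `cog`; empty cells allowed), a COG family
#' table (`cog`, `families`) and a KO domain table (`ko`, `domain`).
#' Any path may be `NULL`.
#'
#' @param taxa_path,functions_path,cog_family_path,ko_domain_path file
#'   paths (or `NULL`)
#' @return an `annotation_maps`
#' @export
read_annotation_maps <- function(taxa_path = NULL, functions_path = NULL,
                                 cog_family_path = NULL,
                                 ko_domain_path = NULL) {
  p2t <- list(); p2k <- list(); p2c <- list()
  fam <- character(); kod <- character()
  if (!is.null(taxa_path)) {
    df <- read_tsv_checked(taxa_path, c("peptide", "taxon_id"))
    p2t <- split(df$taxon_id, df$peptide)
  }
  if (!is.null(functions_path)) {
    df <- read_tsv_checked(functions_path, c("peptide", "ko", "cog"))
    kk <- df[df$ko != "", c("peptide", "ko")]
    cc <- df[df$cog != "", c("peptide", "cog")]
    if (nrow(kk)) p2k <- split(kk$ko, kk$peptide)
    if (nrow(cc)) p2c <- split(cc$cog, cc$peptide)
  }
  if (!is.null(cog_family_path)) {
    df <- read_tsv_checked(cog_family_path, c("cog", "families"))
    fam <- setNames(df$families, df$cog)
  }
  if (!is.null(ko_domain_path)) {
    df <- read_tsv_checked(ko_domain_path, c("ko", "domain"))
    kod <- setNames(df$domain, df$ko)
  }
  annotation_maps(p2t, p2k, p2c, fam, kod)
}

#' @rdname read_annotation_maps
#' @param maps an `annotation_maps`
#' @param dir directory receiving `peptide_taxa.tsv`,
#'   `peptide_functions.tsv`, `cog_families.tsv`, `ko_domain.tsv`
#' @export
write_annotation_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "annotation_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  unroll <- function(lst, value_col) {
    data.frame(peptide = rep(names(lst), lengths(lst)),
               value = unlist(lst, use.names = FALSE),
               stringsAsFactors = FALSE) |>
      setNames(c("peptide", value_col))
  }
  write_tsv(unroll(maps$peptide_to_taxa, "taxon_id"),
            file.path(dir, "peptide_taxa.tsv"))
  kos <- unroll(maps$peptide_to_kos, "ko")
  cogs <- unroll(maps$peptide_to_cogs, "cog")
  fn <- merge(kos, cogs, by = "peptide", all = TRUE)
  fn$ko[is.na(fn$ko)] <- ""; fn$cog[is.na(fn$cog)] <- ""
  write_tsv(fn[order(fn$peptide), ], file.path(dir, "peptide_functions.tsv"))
  write_tsv(data.frame(cog = names(maps$cog_families),
                       families = unname(maps$cog_families)),
            file.path(dir, "cog_families.tsv"))
  write_tsv(data.frame(ko = names(maps$ko_domain),
                       domain = unname(maps$ko_domain)),
            file.path(dir, "ko_domain.tsv"))
  invisible(dir)
}
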