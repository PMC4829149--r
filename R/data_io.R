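## Tabular I/O. All tables are tab-separated with a mandatory header;
## readers validate and return deterministically ordered objects.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-sample peptide identification table
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `peptide` and `spectral_count`. Duplicate (sample, peptide) rows are
#' summed with a warning (upstream exports commonly split counts by
#' charge state). Isoleucine/leucine normalisation is *not* applied
#' here; it is an explicit step (see [normalize_peptide()]).
#'
#' @param path path to a TSV file
#' @return data.frame with columns `sample_id`, `peptide`,
#'   `spectral_count`, sorted by sample then peptide.
#' @seealso [write_peptide_table()]
#' @export
read_peptide_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "peptide", "spectral_count"))
  validate_peptide_observations(
    data.frame(sample_id = df$sample_id,
               peptide = df$peptide,
               spectral_count = df$spectral_count,
               stringsAsFactors = FALSE),
    where = path)
}

validate_peptide_observations <- function(df, where = "peptide table") {
  n <- nrow(df)
  if (n == 0L) stop(where, ": no observations")
  count <- suppressWarnings(as.numeric(df$spectral_count))
  bad <- which(is.na(count) | count != round(count) | count < 1)
  if (length(bad))
    stop(where, ": row ", bad[1] + 1L,  # +1 for the header line
         ": spectral_count must be an integer >= 1 (got '",
         df$spectral_count[bad[1]], "')")
  ok_pep <- grepl(paste0("^[", paste(AA_VALID, collapse = ""), "]+$"),
                  df$peptide)
  if (!all(ok_pep))
    stop(where, ": row ", which(!ok_pep)[1] + 1L,
         ": peptide '", df$peptide[which(!ok_pep)[1]],
         "' contains a non-amino-acid character")
  df$spectral_count <- as.integer(count)
  key <- paste(df$sample_id, df$peptide, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(where, ": ", ndup,
            " duplicate (sample, peptide) row(s) summed", call. = FALSE)
    agg <- tapply(df$spectral_count, key, sum)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    df <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                     peptide = vapply(parts, `[`, "", 2L),
                     spectral_count = as.integer(agg),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$sample_id, df$peptide), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_peptide_table
#' @param observations data.frame of peptide observations
#' @export
write_peptide_table <- function(observations, path) {
  write_tsv(observations[c("sample_id", "peptide", "spectral_count")], path)
}

#' Read sample metadata
#'
#' Tab-separated with columns `sample_id`, `subject_id`, `time_point`
#' (1-3) and `group` (`placebo` or `probiotic`). Validates that sample
#' ids are unique, that each subject has at most one sample per time
#' point, and that group is constant within subject.
#'
#' @param path path to a TSV file
#' @return data.frame sorted by subject then time point
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "subject_id",
                                 "time_point", "group"))
  validate_sample_meta(df, where = path)
}

validate_sample_meta <- function(df, where = "sample metadata") {
  df$time_point <- suppressWarnings(as.integer(df$time_point))
  if (anyNA(df$time_point) || !all(df$time_point %in% 1:3))
    stop(where, ": time_point must be an integer in 1..3")
  if (!all(df$group %in% c("placebo", "probiotic")))
    stop(where, ": group must be 'placebo' or 'probiotic'")
  if (anyDuplicated(df$sample_id))
    stop(where, ": duplicated sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  key <- paste(df$subject_id, df$time_point)
  if (anyDuplicated(key))
    stop(where, ": subject with more than one sample per time point: ",
         key[duplicated(key)][1])
  gps <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(gps > 1))
    stop(where, ": group not constant within subject ",
         names(gps)[gps > 1][1])
  df <- df[order(df$subject_id, df$time_point), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_sample_meta
#' @param meta data.frame of sample metadata
#' @export
write_sample_meta <- function(meta, path) {
  write_tsv(meta[c("sample_id", "subject_id", "time_point", "group")], path)
}

#' Read a taxonomy
#'
#' Two dialects are auto-detected: (1) a tab-separated child/parent
#' table with header columns `taxon_id`, `parent_id`, `rank`, `name`;
#' (2) an NCBI taxdump — pass the directory containing `nodes.dmp` and
#' `names.dmp`, or the path to `nodes.dmp` itself. NCBI's `superkingdom`
#' rank is mapped to `domain` and unrecognised ranks to `no_rank`.
#'
#' @param path a TSV file, a `nodes.dmp` file, or a taxdump directory
#' @return a [taxonomy_tree()]
#' @export
read_taxonomy <- function(path) {
  if (dir.exists(path)) return(read_taxdump(file.path(path, "nodes.dmp")))
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (basename(path) == "nodes.dmp" || grepl("\t\\|", first))
    return(read_taxdump(path))
  nodes <- read_tsv_checked(path, c("taxon_id", "parent_id", "rank", "name"))
  taxonomy_tree(nodes)
}

read_taxdump <- function(nodes_path) {
  names_path <- file.path(dirname(nodes_path), "names.dmp")
  if (!file.exists(nodes_path)) stop("file not found: ", nodes_path)
  if (!file.exists(names_path)) stop("file not found: ", names_path)
  parse_dmp <- function(p) {
    lines <- readLines(p)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  nd <- parse_dmp(nodes_path)
  rank_map <- c(superkingdom = "domain", domain = "domain",
                phylum = "phylum", class = "class", order = "order",
                family = "family", genus = "genus", species = "species")
  taxon_id <- vapply(nd, `[`, "", 1L)
  parent_id <- vapply(nd, `[`, "", 2L)
  rank_raw <- vapply(nd, `[`, "", 3L)
  rank <- unname(rank_map[rank_raw])
  rank[is.na(rank)] <- "no_rank"
  rank[taxon_id == parent_id] <- "root"
  nm <- parse_dmp(names_path)
  sci <- vapply(nm, function(x) length(x) >= 4 &&
                  trimws(x[4]) == "scientific name", TRUE)
  name <- setNames(vapply(nm[sci], `[`, "", 2L),
                   vapply(nm[sci], `[`, "", 1L))
  taxonomy_tree(data.frame(
    taxon_id = taxon_id, parent_id = parent_id, rank = rank,
    name = ifelse(is.na(name[taxon_id]), taxon_id, name[taxon_id]),
    stringsAsFactors = FALSE))
}

#' @rdname read_taxonomy
#' @param tree a `taxonomy_tree`
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  write_tsv(tree$nodes, path)
}

#' Read gut metabolic module (GMM) definitions
#'
#' Plain-text dialect: a module starts with a header line
#' `<module_id>\t<name>`, followed by step lines of comma-separated
#' alternative KO identifiers (`K` + 5 digits). A line containing only
#' `//` separates alternative pathways within a module; a line `///`
#' terminates the module.
#'
#' @param path path to a module definition file
#' @return list of `module_definition` objects
#' @export
read_module_definitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  modules <- list()
  header <- NULL; pathways <- list(); steps <- list()
  flush_pathway <- function(lineno) {
    if (length(steps) == 0L)
      stop(path, ": line ", lineno, ": empty pathway in module ",
           header[1])
    pathways[[length(pathways) + 1L]] <<- steps
    steps <<- list()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (line == "///") {
      if (is.null(header)) stop(path, ": line ", i, ": '///' with no module")
      flush_pathway(i)
      modules[[length(modules) + 1L]] <-
        module_definition(header[1], header[2], pathways)
      header <- NULL; pathways <- list()
    } else if (line == "//") {
      if (is.null(header)) stop(path, ": line ", i, ": '//' with no module")
      flush_pathway(i)
    } else if (is.null(header)) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      header <- c(parts[1], if (length(parts) > 1) parts[2] else parts[1])
    } else {
      kos <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
      bad <- kos[!grepl("^K[0-9]{5}$", kos)]
      if (length(bad))
        stop(path, ": line ", i, ": malformed KO token '", bad[1], "'")
      steps[[length(steps) + 1L]] <- unique(kos)
    }
  }
  if (!is.null(header))
    stop(path, ": module ", header[1], " not terminated by '///'")
  modules
}

#' Define a gut metabolic module
#'
#' @param module_id,name module identifier and human-readable name
#' @param pathways non-empty list of alternative pathways; each pathway
#'   a non-empty ordered list of steps; each step a non-empty character
#'   vector of interchangeable KO ids.
#' @return an object of class `module_definition`
#' @export
module_definition <- function(module_id, name, pathways) {
  if (length(pathways) == 0L)
    stop("module ", module_id, " has no pathway")
  for (pw in pathways) {
    if (length(pw) == 0L) stop("module ", module_id, " has an empty pathway")
    for (st in pw) {
      if (length(st) == 0L) stop("module ", module_id, " has an empty step")
      bad <- st[!grepl("^K[0-9]{5}$", st)]
      if (length(bad))
        stop("module ", module_id, ": malformed KO token '", bad[1], "'")
    }
  }
  structure(list(module_id = module_id, name = name, pathways = pathways),
            class = "module_definition")
}

#' @rdname read_module_definitions
#' @param modules list of `module_definition` objects
#' @export
write_module_definitions <- function(modules, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in modules) {
    writeLines(paste(m$module_id, m$name, sep = "\t"), con)
    for (j in seq_along(m$pathways)) {
      if (j > 1L) writeLines("//", con)
      for (st in m$pathways[[j]])
        writeLines(paste(st, collapse = ","), con)
    }
    writeLines("///", con)
  }
  invisible(path)
}
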