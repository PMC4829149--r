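#' Feature-by-sample abundance matrix
#'
#' A thin wrapper around a numeric matrix (features in rows, samples in
#' columns) carrying a `scale` attribute: `"counts"` for raw spectral
#' counts or `"percent"` for per-sample relative percentages (columns
#' sum to 100, possibly including an explicit `unassigned` feature).
#'
#' @param values numeric matrix with feature rownames and sample
#'   colnames
#' @param scale `"counts"` or `"percent"`
#' @return an `abundance_matrix`
#' @export
abundance_matrix <- function(values, scale = c("counts", "percent")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs feature rownames and sample colnames")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (scale == "percent") {
    tot <- colSums(values)
    if (any(abs(tot - 100) > 1e-9))
      stop("percent columns must sum to 100; sample ",
           colnames(values)[which(abs(tot - 100) > 1e-9)[1]],
           " sums to ", tot[which(abs(tot - 100) > 1e-9)[1]])
  }
  structure(values, scale = scale, class = c("abundance_matrix", "matrix",
                                             "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix [", attr(x, "scale"), "]: ",
      nrow(x), " features x ", ncol(x), " samples\n", sep = "")
  print(head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

am_scale <- function(m) attr(m, "scale")

## Subsetting keeps the class and scale when the result is a matrix.
#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    structure(out, scale = attr(x, "scale"),
              class = c("abundance_matrix", "matrix", "array"))
  else out
}

#' Convert spectral counts to per-sample relative percentages
#'
#' Each sample column is scaled by 100 / its total so that columns sum
#' to 100.
#'
#' @param m an `abundance_matrix` on the counts scale
#' @return an `abundance_matrix` on the percent scale
#' @export
to_percent <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (am_scale(m) != "counts") stop("to_percent expects a counts matrix")
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("sample ", colnames(m)[which(tot <= 0)[1]],
         " has zero total count")
  abundance_matrix(sweep(unclass(m), 2L, tot, "/") * 100, "percent")
}

#' Minimum-maximum spectral count filter
#'
#' Keeps a feature iff its count reaches `min_max_count` in at least
#' one sample — the abundance filter used to retain, e.g., bacterial
#' KOs with at least five spectra in one sample and human KOs with at
#' least two.
#'
#' @param m an `abundance_matrix` on the counts scale
#' @param min_max_count integer >= 1
#' @return the filtered `abundance_matrix`
#' @export
abundance_filter <- function(m, min_max_count) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (am_scale(m) != "counts")
    stop("abundance_filter expects a counts matrix")
  if (length(min_max_count) != 1L || is.na(min_max_count) ||
      min_max_count < 1)
    stop("min_max_count must be an integer >= 1")
  keep <- apply(unclass(m), 1L, max) >= min_max_count
  m[keep, , drop = FALSE]
}

#' Read / write an abundance matrix as TSV
#'
#' The first column (`feature_id`) holds feature names; remaining
#' columns are samples.
#'
#' @param path file path
#' @param scale scale of the stored values
#' @return an `abundance_matrix` (reader) or `path` invisibly (writer)
#' @export
read_abundance_matrix <- function(path, scale = c("counts", "percent")) {
  scale <- match.arg(scale)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop(path, ": first column must be feature_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$feature_id
  abundance_matrix(values, scale)
}

#' @rdname read_abundance_matrix
#' @param m an `abundance_matrix`
#' @export
write_abundance_matrix <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  df <- data.frame(feature_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
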