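#' Construct an abundance table
#'
#' An abundance table is a samples x taxa numeric matrix of relative
#' abundances (fractions in `[0, 1]`), with unique sample ids as row names and
#' clade strings (or plain taxon labels) as column names. All analyses in the
#' package operate on species-rank fractions that sum to at most 1 per sample.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @return an `abund_table` (a classed numeric matrix).
#' @export
abundance_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) {
    if (ncol(values) > 0) stop("abundance table needs taxon column names")
    colnames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate taxon ids")
  if (any(values < 0)) stop("negative abundance values")
  sp <- species_rank(colnames(values))
  sums <- if (any(sp)) rowSums(values[, sp, drop = FALSE]) else rowSums(values)
  if (any(sums > 1 + 1e-6)) stop("per-sample abundance sums exceed 1")
  structure(values, class = c("abund_table", class(values)))
}

#' Construct a metadata table with declared variable kinds
#'
#' @param df data.frame of host variables, samples in rows (row names are
#'   sample ids); values may be `NA`.
#' @param kinds named character vector mapping every column of `df` to one of
#'   `"binary"`, `"ordinal"`, `"nominal"`, `"continuous"`.
#' @return a `meta_table` (a data.frame carrying a `kinds` attribute).
#' @export
metadata_table <- function(df, kinds) {
  df <- as.data.frame(df)
  if (anyDuplicated(rownames(df))) stop("duplicate sample ids")
  kinds <- unlist(kinds)
  missing_kind <- setdiff(names(df), names(kinds))
  if (length(missing_kind))
    stop("variables without a declared kind: ", paste(missing_kind, collapse = ", "))
  bad <- setdiff(kinds[names(df)], c("binary", "ordinal", "nominal", "continuous"))
  if (length(bad)) stop("unknown variable kind: ", paste(unique(bad), collapse = ", "))
  structure(df, kinds = kinds[names(df)], class = c("meta_table", "data.frame"))
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("<abund_table> %d samples x %d taxa\n", nrow(x), ncol(x)))
  invisible(x)
}

var_kinds <- function(meta) attr(meta, "kinds")

species_rank <- function(clades) {
  grepl("s__", clades, fixed = TRUE) & !grepl("t__", clades, fixed = TRUE)
}

#' Read a MetaPhlAn-style profile table
#'
#' Parses a TSV whose first column holds pipe-delimited clade strings
#' (`k__...|p__...|...|s__...`) and whose remaining columns hold one sample
#' each. By default only species-rank rows (`s__` present, no strain suffix)
#' are kept; `UNKNOWN`/unclassified rows are dropped with a message. Values
#' are auto-detected as percentages when per-sample species sums exceed 1.5
#' and divided by 100.
#'
#' @param path TSV file path.
#' @param rank clade rank to retain; `"species"` (default) or `"all"`.
#' @param percent `NA` (default) to auto-detect percent vs fraction scaling,
#'   or `TRUE`/`FALSE` to force it.
#' @return an [abundance_table()] with samples in rows.
#' @export
read_profile_table <- function(path, rank = c("species", "all"), percent = NA) {
  rank <- match.arg(rank)
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 2) stop("profile table needs a clade column plus sample columns")
  clades <- as.character(raw[[1]])
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample column in profile table")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) stop("non-numeric abundance values")
  if (any(vals < 0)) stop("negative abundance values")

  unknown <- grepl("^UNKNOWN$|unclassified", clades, ignore.case = TRUE)
  if (any(unknown)) {
    message(sum(unknown), " UNKNOWN/unclassified row(s) dropped")
    clades <- clades[!unknown]
    vals <- vals[!unknown, , drop = FALSE]
  }
  if (rank == "species") {
    keep <- species_rank(clades)
    clades <- clades[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  if (is.na(percent)) percent <- any(colSums(vals) > 1.5)
  if (percent) vals <- vals / 100
  out <- t(vals)
  colnames(out) <- clades
  rownames(out) <- samples
  abundance_table(out)
}

#' Write a profile table in MetaPhlAn-style TSV
#'
#' Inverse of [read_profile_table()]: taxa in rows as clade strings, one
#' column per sample, values as percentages.
#'
#' @param table an [abundance_table()].
#' @param path output TSV path.
#' @export
write_profile_table <- function(table, path) {
  df <- data.frame(clade_name = colnames(table), t(table) * 100,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a metadata table with its kind-declaration sidecar
#'
#' Metadata travel as a CSV (first column `sample_id`) plus a JSON sidecar
#' mapping each variable to its declared kind.
#'
#' @param path CSV path; the sidecar is `<path>.kinds.json` unless given.
#' @param kinds_path optional explicit sidecar path.
#' @return a [metadata_table()].
#' @export
read_metadata_table <- function(path, kinds_path = paste0(path, ".kinds.json")) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1]]
  df[[1]] <- NULL
  kinds <- unlist(jsonlite::read_json(kinds_path))
  metadata_table(df, kinds)
}

#' @rdname read_metadata_table
#' @param meta a [metadata_table()].
#' @export
write_metadata_table <- function(meta, path, kinds_path = paste0(path, ".kinds.json")) {
  df <- data.frame(sample_id = rownames(meta), meta, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(var_kinds(meta)), kinds_path, auto_unbox = TRUE)
  invisible(path)
}

#' Filter taxa by prevalence
#'
#' Retains taxa observed (strictly positive abundance) in at least
#' `ceiling(min_prevalence * n_samples)` samples; the sample set is unchanged.
#' The boundary is inclusive: a taxon present in exactly 10% of samples
#' survives the default threshold.
#'
#' @param table an [abundance_table()].
#' @param min_prevalence required fraction of samples, in `(0, 1]`.
#' @return the filtered [abundance_table()].
#' @export
prevalence_filter <- function(table, min_prevalence = 0.10) {
  stopifnot(min_prevalence > 0, min_prevalence <= 1)
  need <- ceiling(min_prevalence * nrow(table))
  keep <- colSums(table > 0) >= need
  if (!any(keep)) warning("prevalence filter removed every taxon")
  abundance_table(unclass(table)[, keep, drop = FALSE])
}

#' Arcsine square root transformation
#'
#' The variance-stabilizing transform `asin(sqrt(x))` applied elementwise to
#' fractional abundances, mapping `[0, 1]` onto `[0, pi/2]` and reducing the
#' right skew of compositional profiles before linear modelling.
#'
#' @param x numeric vector or matrix of fractions in `[0, 1]`; values in
#'   `(1, 1 + 1e-9]` are clamped to 1, anything further outside is an error.
#' @return transformed object of the same shape.
#' @export
arcsine_sqrt <- function(x) {
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE))
    stop("values outside [0, 1]")
  x <- pmin(pmax(x, 0), 1)
  out <- asin(sqrt(x))
  if (is.matrix(x)) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}
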