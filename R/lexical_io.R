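#' Read a collection of wordlists from a long-format TSV file
#'
#' The file is tab-separated with a header row naming at least the columns
#' `variety`, `concept` and `form`, and optionally `cognate`; one row per
#' (variety, concept, form). This is the row-wise dialect used by the large
#' lexical databases. Duplicate (variety, concept) rows are stored as
#' synonyms under that concept. Row order never affects the result: rows
#' are grouped by variety (first-appearance order of varieties is kept as
#' the collection order) and concepts sorted within each variety.
#'
#' Cognate coding must be all-or-none per variety: a variety whose rows
#' carry a cognate class on only some rows is rejected.
#'
#' @param path path to the TSV file.
#' @param format input dialect; only `"long_tsv"` is supported.
#' @return named list of [wordlist] objects (names = variety ids, in order
#'   of first appearance).
#' @export
read_wordlists <- function(path, format = "long_tsv") {
  format <- match.arg(format, "long_tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, colClasses = "character", quote = "",
                    check.names = FALSE, fileEncoding = "UTF-8",
                    na.strings = character())
  need <- c("variety", "concept", "form")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("wordlist file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) stop("wordlist file has no data rows: ", path)
  bad <- which(!nzchar(tab$form))
  if (length(bad))
    stop("empty form at data row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  has_cog <- "cognate" %in% names(tab)
  out <- list()
  for (v in unique(tab$variety)) {
    rows <- tab[tab$variety == v, , drop = FALSE]
    rows <- rows[order(rows$concept, rows$form), , drop = FALSE]
    forms <- split(rows$form, factor(rows$concept, unique(rows$concept)))
    cog <- NULL
    if (has_cog) {
      coded <- nzchar(rows$cognate)
      if (any(coded) && !all(coded))
        stop("variety '", v, "' mixes cognate-coded and uncoded rows; ",
             "cognate coding must be all-or-none per variety")
      if (all(coded))
        cog <- split(rows$cognate,
                     factor(rows$concept, unique(rows$concept)))
    }
    out[[v]] <- wordlist(v, forms, cog)
  }
  out
}

#' Write a collection of wordlists as long-format TSV
#'
#' Inverse of [read_wordlists]: one row per (variety, concept, form), with
#' a `cognate` column when any wordlist is cognate-coded.
#'
#' @param wordlists named list of [wordlist] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wordlists <- function(wordlists, path) {
  stopifnot(length(wordlists) >= 1L)
  any_cog <- any(vapply(wordlists, has_cognates, logical(1)))
  rows <- lapply(wordlists, function(w) {
    n <- lengths(w$forms)
    data.frame(variety = w$variety_id,
               concept = rep(names(w$forms), n),
               form = unlist(w$forms, use.names = FALSE),
               cognate = if (has_cognates(w))
                 unlist(w$cognates, use.names = FALSE)
               else rep("", sum(n)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!any_cog) tab$cognate <- NULL
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a variety-to-group (province) mapping
#'
#' Tab-separated, header row `variety` and `group`; one row per variety.
#'
#' @param path path to the TSV file.
#' @return named character vector: names are variety ids, values group ids.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, colClasses = "character", quote = "",
                    check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("variety", "group"), names(tab))
  if (length(miss))
    stop("group map is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) stop("group map has no data rows: ", path)
  if (anyDuplicated(tab$variety))
    stop("duplicate variety id(s) in group map: ",
         paste(unique(tab$variety[duplicated(tab$variety)]), collapse = ", "))
  stats::setNames(tab$group, tab$variety)
}

#' Write a variety-to-group mapping as TSV
#' @param group_map named character vector (variety -> group).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(group_map, path) {
  write.table(data.frame(variety = names(group_map),
                         group = unname(group_map)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a group trait table
#'
#' Two columns, `group,value` (comma- or tab-separated, detected from the
#' first line; no header row), giving one bounded trait value per group —
#' e.g. the proportion of cultivated land devoted to rice per province.
#' Values must lie in \[0, 1\]; duplicate groups and empty files are
#' errors.
#'
#' @param path path to the CSV/TSV file.
#' @return named numeric vector in \[0, 1\] (names = group ids).
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("trait table is empty: ", path)
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("trait table must have exactly two columns (group", sep,
         "value): ", path)
  groups <- trimws(vapply(parts, `[[`, character(1), 1L))
  vals <- suppressWarnings(
    as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(vals)) stop("non-numeric trait value(s) in ", path)
  validate_trait_table(stats::setNames(vals, groups))
}

validate_trait_table <- function(traits) {
  if (is.null(names(traits)) || any(!nzchar(names(traits))))
    stop("trait table must have a group id for every value")
  if (anyDuplicated(names(traits)))
    stop("duplicate group id(s) in trait table: ",
         paste(unique(names(traits)[duplicated(names(traits))]),
               collapse = ", "))
  if (any(traits < 0 | traits > 1))
    stop("trait value(s) outside [0, 1] for group(s): ",
         paste(names(traits)[traits < 0 | traits > 1], collapse = ", "))
  traits
}

#' Write a group trait table as headerless CSV
#' @param traits named numeric vector in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  validate_trait_table(traits)
  writeLines(paste(names(traits), format(unname(traits), digits = 15,
                                         trim = TRUE, scientific = FALSE),
                   sep = ","), path)
  invisible(path)
}

#' Write / read a labeled distance matrix
#'
#' Square tab-separated layout: header row of labels with a leading empty
#' cell, leading label column, numeric body. Labels containing whitespace
#' or quotes are quoted. Values are written to full double precision, so
#' `read_matrix(write_matrix(m))` reproduces `m` to at least 12 significant
#' digits. On read the matrix must be square with matching row/column
#' labels, symmetric to 1e-9 and zero on the diagonal; tiny asymmetries
#' within tolerance are symmetrized away.
#'
#' @param m symmetric numeric matrix with identical row and column names,
#'   zero diagonal, non-negative entries.
#' @param path file path.
#' @return `write_matrix`: `path`, invisibly. `read_matrix`: the matrix.
#' @export
write_matrix <- function(m, path) {
  m <- validate_dist_matrix(m)
  df <- as.data.frame(m, check.names = FALSE, optional = TRUE)
  op <- options(digits = 15); on.exit(options(op))
  write.table(df, path, sep = "\t", quote = TRUE, col.names = NA,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, row.names = 1L,
                    fileEncoding = "UTF-8")
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric entries in matrix file ", path)
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square (", nrow(m), " x ",
         ncol(m), ")")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ in ", path)
  if (max(abs(m - t(m))) > 1e-9)
    stop("matrix in ", path, " is asymmetric beyond tolerance 1e-9")
  m <- (m + t(m)) / 2
  validate_dist_matrix(m)
}

#' Validate a labeled distance matrix
#'
#' Checks the invariants every dissimilarity matrix in this package obeys:
#' square, numeric, labeled identically on rows and columns, exactly
#' symmetric, zero diagonal, non-negative entries.
#'
#' @param m matrix to validate.
#' @param what name used in error messages.
#' @return the matrix, invisibly unchanged.
#' @export
validate_dist_matrix <- function(m, what = "distance matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(what, " must be a square numeric matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)) ||
      anyDuplicated(rownames(m)))
    stop(what, " must carry identical, unique row and column labels")
  if (any(m < 0)) stop(what, " has negative entries")
  if (any(diag(m) != 0)) stop(what, " has a nonzero diagonal")
  if (!isSymmetric(unname(m), tol = 0))
    stop(what, " is not symmetric")
  m
}
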