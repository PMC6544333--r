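#' Genus-level abundance time-series table
#'
#' Container for one body site's genus x day abundance matrix: non-negative
#' abundances (counts or proportions), one row per genus, one column per
#' sampling day. Day indices are integers and strictly increasing; gaps are
#' permitted but downstream lag operators treat columns as consecutive
#' observations (a warning is raised when gaps exist at read time).
#'
#' @param values numeric matrix, taxa in rows, days in columns; finite, >= 0.
#' @param taxa character vector of unique genus names, one per row.
#' @param days integer vector of strictly increasing day indices, one per
#'   column.
#' @param site free-text body-site label.
#'
#' @return An object of class `genus_table`: a list with fields `site`,
#'   `taxa`, `days` and `values` (the matrix carries taxa as rownames and
#'   days as colnames).
#' @export
genus_table <- function(values, taxa = rownames(values),
                        days = as.integer(colnames(values)),
                        site = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  x <- structure(
    list(site = as.character(site)[1], taxa = as.character(taxa),
         days = as.integer(days), values = values),
    class = "genus_table")
  dimnames(x$values) <- list(x$taxa, x$days)
  validate_genus_table(x)
}

#' @rdname genus_table
#' @param x object to validate.
#' @export
validate_genus_table <- function(x) {
  stopifnot(inherits(x, "genus_table"))
  if (nrow(x$values) != length(x$taxa))
    stop("row count (", nrow(x$values), ") != number of taxa (",
         length(x$taxa), ")")
  if (ncol(x$values) != length(x$days))
    stop("column count (", ncol(x$values), ") != number of days (",
         length(x$days), ")")
  dup <- x$taxa[duplicated(x$taxa)]
  if (length(dup))
    stop("duplicate taxon name(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(x$days))
    stop("duplicate day index(es): ",
         paste(unique(x$days[duplicated(x$days)]), collapse = ", "))
  if (is.unsorted(x$days, strictly = TRUE))
    stop("day indices must be strictly increasing")
  bad <- which(!is.finite(x$values) | x$values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite or negative abundance for taxon '",
         x$taxa[bad[1, 1]], "' on day ", x$days[bad[1, 2]])
  x
}

#' @export
print.genus_table <- function(x, ...) {
  cat("genus_table: site '", x$site, "', ", length(x$taxa), " taxa x ",
      length(x$days), " days (", x$days[1], "..", x$days[length(x$days)],
      ")\n", sep = "")
  invisible(x)
}

#' Read a genus abundance table
#'
#' TSV dialect: first column holds the taxon name, the header row holds
#' integer day indices. BIOM (JSON) tables are read through the
#' \pkg{biomformat} package when `format = "biom"`; observation ids become
#' taxa and sample ids are parsed as day indices.
#'
#' @param path file to read.
#' @param format `"tsv"` (canonical) or `"biom"`.
#' @param site body-site label to attach (defaults to the file name).
#' @return a validated [genus_table()].
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 site = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the 'biomformat' package is required for BIOM input")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    tab <- genus_table(m, taxa = rownames(m), days = as.integer(colnames(m)),
                       site = site)
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed table: need a taxon column plus days")
    day_lab <- colnames(df)[-1]
    days <- suppressWarnings(as.integer(day_lab))
    if (anyNA(days))
      stop("malformed header: non-integer day index '",
           day_lab[which(is.na(days))[1]], "'")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    tab <- genus_table(m, taxa = as.character(df[[1]]), days = days,
                       site = site)
  }
  if (length(tab$days) > 1 && any(diff(tab$days) != 1L))
    warning("day indices of '", tab$site, "' have gaps; lagged models ",
            "treat columns as consecutive observations")
  tab
}

#' Write a genus abundance table as TSV
#'
#' Inverse of [read_abundance_table()]: first column `taxon`, remaining
#' columns the day indices, row/column order preserved.
#'
#' @param table a [genus_table()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  validate_genus_table(table)
  df <- data.frame(taxon = table$taxa, table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("taxon", table$days)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
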