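#' Construct a validated spectra table
#'
#' The package's in-memory container for a set of absorbance spectra on a
#' shared wavenumber grid. Grids are normalised to descending wavenumber
#' order (spectroscopy convention); whether the input was ascending is
#' recorded in `original_order`.
#'
#' @param wavenumbers Strictly monotone numeric grid (cm^-1).
#' @param spectra Samples x wavenumbers numeric matrix, no missing values.
#' @param sample_ids Unique sample identifiers (default from row names).
#' @return Object of class `spectra_table`.
#' @export
spectra_table <- function(wavenumbers, spectra, sample_ids = rownames(spectra)) {
  spectra <- as.matrix(spectra)
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(spectra)))
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicated sample ID(s): ", paste(dup, collapse = ", "))
  }
  if (ncol(spectra) != length(wavenumbers))
    stop("spectra column count must equal wavenumber grid length")
  if (!is.numeric(spectra) || anyNA(spectra) || any(!is.finite(spectra)))
    stop("spectra must be finite numeric values with no missing cells")
  d <- diff(wavenumbers)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  original_order <- if (d[1] > 0) "ascending" else "descending"
  if (original_order == "ascending") {
    wavenumbers <- rev(wavenumbers)
    spectra <- spectra[, rev(seq_len(ncol(spectra))), drop = FALSE]
  }
  rownames(spectra) <- sample_ids
  colnames(spectra) <- format_wavenumber(wavenumbers)
  structure(list(wavenumbers = wavenumbers, spectra = spectra,
                 sample_ids = sample_ids, original_order = original_order),
            class = "spectra_table")
}

#' Coerce objects to a spectra table
#' @param x Object to coerce (a `synthetic_dataset`, matrix, or
#'   `spectra_table`).
#' @param ... Unused.
#' @return A [spectra_table].
#' @export
as_spectra_table <- function(x, ...) UseMethod("as_spectra_table")

#' @export
as_spectra_table.spectra_table <- function(x, ...) x

#' @export
as_spectra_table.synthetic_dataset <- function(x, ...)
  spectra_table(x$wavenumbers, x$spectra, x$sample_ids)

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("spectra_table: %d spectra x %d wavenumbers (%g-%g cm^-1, %s input)\n",
              nrow(x$spectra), length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers), x$original_order))
  invisible(x)
}

#' Read spectra from CSV
#'
#' Reads the CSV dialect written by [write_dataset]/[write_spectra]: first
#' column `wavenumber_cm-1`, one column per sample. The grid is validated
#' (strictly monotone, numeric, no duplicated sample IDs) and normalised to
#' descending order.
#'
#' @param path CSV file path.
#' @return A [spectra_table].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs a wavenumber column plus >= 1 sample")
  ids <- colnames(df)[-1]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric cells in spectra CSV: ", path)
  spectra_table(df[[1]], t(m), sample_ids = ids)
}

#' Write a spectra table to CSV
#'
#' @param table A [spectra_table] (or coercible object).
#' @param path Output CSV path.
#' @param digits Decimal digits retained (default 10; the round trip is
#'   lossless to this printed precision).
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(table, path, digits = 10) {
  table <- as_spectra_table(table)
  df <- data.frame(check.names = FALSE,
                   `wavenumber_cm-1` = table$wavenumbers)
  m <- signif(t(table$spectra), digits)
  colnames(m) <- table$sample_ids
  utils::write.csv(cbind(df, as.data.frame(m, check.names = FALSE)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Per-group mean spectra
#'
#' Averages spectra within groups (e.g. species), returning one mean
#' spectrum per group. The sample-size-weighted mean of the group means
#' equals the overall mean spectrum.
#'
#' @param table A [spectra_table] or coercible object.
#' @param group Vector/factor of group labels, one per sample.
#' @return A [spectra_table] with group names as sample IDs.
#' @export
mean_spectrum <- function(table, group) {
  table <- as_spectra_table(table)
  n <- nrow(table$spectra)
  if (length(group) != n) stop("every sample needs a group label")
  group <- factor(group)
  if (any(table(group) == 0) || anyNA(group)) stop("empty or missing group")
  means <- rowsum(table$spectra, group) / as.vector(table(group))
  spectra_table(table$wavenumbers, means, sample_ids = levels(group))
}
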