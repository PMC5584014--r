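#' Construct a spectra set
#'
#' A `spectra_set` bundles an absorbance matrix with its wavenumber axis and
#' sample identifiers. The axis must be strictly monotonic (FT-NIR exports are
#' conventionally descending, e.g. 10000 to 4000 cm^-1, but ascending axes are
#' accepted); the matrix must be fully numeric with one column per wavenumber.
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns.
#' @param wavenumbers numeric vector of wavenumber positions (cm^-1), strictly
#'   monotonic, one per column of `absorbance`.
#' @param sample_ids character vector of unique sample identifiers, one per row.
#' @return An object of class `spectra_set` with elements `absorbance`,
#'   `wavenumbers` and `sample_ids`.
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(absorbance))) rownames(absorbance)
                  else sprintf("S%03d", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance has ", ncol(absorbance), " columns but ",
         length(wavenumbers), " wavenumbers were supplied")
  if (nrow(absorbance) != length(sample_ids))
    stop("absorbance has ", nrow(absorbance), " rows but ",
         length(sample_ids), " sample ids were supplied")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  if (anyNA(absorbance))
    stop("absorbance matrix contains missing values")
  if (length(wavenumbers) >= 2) {
    d <- diff(wavenumbers)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumber axis must be strictly monotonic")
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format_wavenumber(wavenumbers)
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

format_wavenumber <- function(w) {
  # enough digits that write -> read restores the axis exactly
  formatC(w, format = "g", digits = 17)
}

#' @export
print.spectra_set <- function(x, ...) {
  n <- length(x$sample_ids); p <- length(x$wavenumbers)
  rng <- range(x$wavenumbers)
  cat(sprintf("spectra_set: %d samples x %d wavenumbers (%.1f-%.1f cm^-1)\n",
              n, p, rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample and/or wavenumber index
#'
#' @param x a `spectra_set`.
#' @param i sample (row) indices.
#' @param j wavenumber (column) indices.
#' @param ... ignored.
#' @return A `spectra_set` restricted to the requested samples and variables.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$wavenumbers)
  spectra_set(x$absorbance[i, j, drop = FALSE], x$wavenumbers[j],
              x$sample_ids[i])
}

#' Read a wide-format spectra CSV
#'
#' Expects the FT-NIR export convention: the first row holds the wavenumber
#' axis, the first column the sample ids, the body the absorbance values.
#'
#' @param path file path to a spectra CSV.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("spectra CSV '", path, "' must have an id column plus wavenumbers")
  wn <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wn))
    stop("non-numeric wavenumber in header of '", path, "' at column ",
         which(is.na(wn))[1] + 1L)
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) != length(wn) + 1L)
    stop("ragged spectra CSV '", path, "': ", ncol(tab) - 1L,
         " data columns for ", length(wn), " wavenumbers")
  if (nrow(tab) > 0) {
    m <- suppressWarnings(
      vapply(tab[-1], as.numeric, numeric(nrow(tab))))
    m <- matrix(m, nrow = nrow(tab))
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("non-numeric absorbance in '", path, "' at row ", idx[1] + 1L,
           ", column ", idx[2] + 1L)
    }
  } else {
    m <- matrix(numeric(0), nrow = 0, ncol = length(wn))
  }
  spectra_set(m, wn, if (nrow(tab)) tab[[1]] else character(0))
}

#' Write a spectra set as a wide-format CSV
#'
#' @param s a `spectra_set`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", format_wavenumber(s$wavenumbers)),
                   collapse = ","), con)
  if (length(s$sample_ids)) {
    body <- apply(s$absorbance, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = ","))
    writeLines(paste(s$sample_ids, body, sep = ","), con)
  }
  invisible(path)
}

# canonical property column order for reference tables
REFERENCE_PROPERTIES <- c("soluble_sugar", "cellulose", "hemicellulose",
                          "lignin", "ash", "tey")
PERCENT_PROPERTIES <- c("soluble_sugar", "cellulose", "hemicellulose",
                        "lignin", "ash")
FEEDSTOCK_CLASSES <- c("sweet", "biomass")

#' Construct a reference table
#'
#' Per-sample wet-chemistry reference values: feedstock class (sweet or biomass
#' sorghum), five compositional properties in percent of dry weight, and
#' theoretical ethanol yield (TEY) in g/kg dry matter.
#'
#' @param df data frame with columns `sample_id`, `class`, `soluble_sugar`,
#'   `cellulose`, `hemicellulose`, `lignin`, `ash`, `tey`.
#' @return A validated data frame of class `reference_table`.
#' @export
reference_table <- function(df) {
  need <- c("sample_id", "class", REFERENCE_PROPERTIES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$sample_id <- as.character(df$sample_id)
  df$class <- as.character(df$class)
  if (anyDuplicated(df$sample_id))
    stop("reference table sample ids must be unique")
  bad_class <- setdiff(unique(df$class), FEEDSTOCK_CLASSES)
  if (length(bad_class))
    stop("unknown feedstock class label(s): ", paste(bad_class, collapse = ", "),
         " (expected 'sweet' or 'biomass')")
  for (p in REFERENCE_PROPERTIES) {
    v <- as.numeric(df[[p]])
    if (anyNA(v)) stop("missing or non-numeric values in property '", p, "'")
    df[[p]] <- v
  }
  for (p in PERCENT_PROPERTIES)
    if (any(df[[p]] < 0 | df[[p]] > 100))
      stop("property '", p, "' must lie in [0, 100] percent dry weight")
  if (any(df$tey < 0)) stop("tey must be non-negative")
  rownames(df) <- NULL
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Read a reference-property CSV
#'
#' @param path file path.
#' @return A [reference_table()].
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_table(df)
}

#' Write a reference table as CSV
#'
#' @param ref a `reference_table`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_reference_csv <- function(ref, path) {
  df <- as.data.frame(ref)
  for (p in REFERENCE_PROPERTIES)
    df[[p]] <- formatC(df[[p]], format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a spectra set and reference table by sample id
#'
#' Reorders the reference table to match the spectra set's sample order.
#' Alignment is enforced rather than assumed: any id present in one input but
#' not the other is an error, because silent sample misalignment is the classic
#' chemometrics failure mode.
#'
#' @param spectra a `spectra_set`.
#' @param reference a `reference_table`.
#' @return A list with the untouched `spectra` and the reordered `reference`.
#' @export
align_samples <- function(spectra, reference) {
  ids_s <- spectra$sample_ids
  ids_r <- reference$sample_id
  only_s <- setdiff(ids_s, ids_r)
  only_r <- setdiff(ids_r, ids_s)
  if (length(only_s) || length(only_r))
    stop("sample ids do not match between spectra and reference table",
         if (length(only_s)) paste0("; spectra-only: ",
                                    paste(utils::head(only_s, 3), collapse = ", ")),
         if (length(only_r)) paste0("; reference-only: ",
                                    paste(utils::head(only_r, 3), collapse = ", ")))
  reference <- reference[match(ids_s, ids_r), , drop = FALSE]
  rownames(reference) <- NULL
  class(reference) <- c("reference_table", "data.frame")
  list(spectra = spectra, reference = reference)
}

#' Write a model-comparison report as JSON
#'
#' Serializes the per-model records (strategy, property, factor count, metrics,
#' retained-variable count) plus any consensus categorization tables with
#' stable key ordering so identical runs produce byte-identical files.
#'
#' @param report a report list as returned by [run_quantitative()], or any list
#'   with a `records` element (one record per strategy/property pair).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path file path.
#' @return The deserialized report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
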