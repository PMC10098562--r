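#' Spectra tables
#'
#' Throughout the package a spectral dataset is an ordinary wide tibble:
#' a `sample_id` character column followed by one numeric column per
#' wavelength, with column names equal to the wavelength in nanometres
#' (e.g. `"356"`, `"357"`, ...). Wavelengths must be strictly increasing
#' and reflectance values must be finite. These helpers convert between
#' the tibble form and the samples-by-wavelengths matrix used internally.
#'
#' @param x A spectra tibble.
#' @param mat A numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths Integer-valued wavelengths (nm), one per column of
#'   `mat`, strictly increasing.
#' @param sample_ids Optional character sample identifiers; defaults to
#'   `"s1", "s2", ...`.
#'
#' @return `as_spectra_tbl()` returns a spectra tibble; `spectra_matrix()`
#'   a numeric matrix with sample ids as row names; `spectra_wavelengths()`
#'   a numeric vector of wavelengths in nm.
#' @name spectra-tables
NULL

#' @rdname spectra-tables
#' @export
as_spectra_tbl <- function(mat, wavelengths, sample_ids = NULL) {
  mat <- as.matrix(mat)
  if (length(wavelengths) != ncol(mat)) {
    abort("`wavelengths` must have one entry per column of `mat`.")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(mat)))
  out <- as_tibble(mat, .name_repair = "minimal")
  names(out) <- as.character(wavelengths)
  out <- dplyr::bind_cols(tibble(sample_id = as.character(sample_ids)), out)
  validate_spectra(out)
  out
}

#' @rdname spectra-tables
#' @export
spectra_matrix <- function(x) {
  validate_spectra(x)
  mat <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  rownames(mat) <- x$sample_id
  storage.mode(mat) <- "double"
  mat
}

#' @rdname spectra-tables
#' @export
spectra_wavelengths <- function(x) {
  as.numeric(setdiff(names(x), "sample_id"))
}

validate_spectra <- function(x) {
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    abort("Spectra must be a data frame with a `sample_id` column.")
  }
  wl <- suppressWarnings(as.numeric(setdiff(names(x), "sample_id")))
  if (length(wl) == 0L) abort("Spectra contain no wavelength columns.")
  if (anyNA(wl)) abort("All non-id column names must be numeric wavelengths (nm).")
  if (any(diff(wl) <= 0)) abort("Wavelengths must be strictly increasing.")
  vals <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    abort("Reflectance values must be finite numbers with no missing entries.")
  }
  invisible(x)
}

#' Read and write spectra and label CSV files
#'
#' The on-disk dialect is plain CSV. Spectra files have a `sample_id`
#' column followed by integer-wavelength columns; label files have columns
#' `sample_id`, `nutrient` and `value_g_per_kg`.
#'
#' @param path File path.
#' @param x A spectra tibble (for `write_spectra()`) or labels tibble
#'   (for `write_labels()`).
#' @return A tibble (readers) or `path`, invisibly (writers).
#' @name spectra-io
NULL

#' @rdname spectra-io
#' @export
read_spectra <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sample_id = readr::col_character(),
                                                 .default = readr::col_double()))
  validate_spectra(out)
  out
}

#' @rdname spectra-io
#' @export
write_spectra <- function(x, path) {
  validate_spectra(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname spectra-io
#' @export
read_labels <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sample_id = readr::col_character(),
                                                 nutrient = readr::col_character(),
                                                 value_g_per_kg = readr::col_double()))
  if (!all(c("sample_id", "nutrient", "value_g_per_kg") %in% names(out))) {
    abort("Labels file must have columns sample_id, nutrient, value_g_per_kg.")
  }
  out
}

#' @rdname spectra-io
#' @export
write_labels <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
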