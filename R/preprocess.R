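#' Savitzky-Golay smoothing of a spectra table
#'
#' Applies a second-order (by default) Savitzky-Golay filter to every
#' spectrum. The filter fits a local polynomial of order `polyorder` in a
#' sliding window of `window` channels and replaces the centre value with
#' the fitted value, which smooths instrument noise while preserving peak
#' shape; polynomials up to `polyorder` pass through unchanged.
#'
#' @param spectra A spectra tibble (see [as_spectra_tbl()]).
#' @param window Odd window length in channels; must exceed `polyorder`.
#' @param polyorder Local polynomial order (default 2).
#' @return A spectra tibble of the same shape.
#' @export
sg_smooth <- function(spectra, window = 11, polyorder = 2) {
  validate_spectra(spectra)
  window <- assert_count(window, "window", min = 3L)
  polyorder <- assert_count(polyorder, "polyorder", min = 0L)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  if (window <= polyorder) abort("`window` must be greater than `polyorder`.")
  mat <- spectra_matrix(spectra)
  if (ncol(mat) < window) abort("`window` exceeds the number of channels.")
  sm <- t(apply(mat, 1L, function(row) {
    as.numeric(signal::sgolayfilt(row, p = polyorder, n = window))
  }))
  as_spectra_tbl(sm, spectra_wavelengths(spectra), spectra$sample_id)
}

#' Trim noisy edge bands from a spectra table
#'
#' Retains the wavelengths inside the closed interval `[low_nm, high_nm]`.
#' The short-wavelength edge of silicon-array Vis-NIR instruments has a low
#' signal-to-noise ratio, so the default keeps 356-1100 nm, which turns a
#' full 320-1100 nm grid at 1 nm into 745 channels.
#'
#' @inheritParams sg_smooth
#' @param low_nm,high_nm Closed retention interval in nm.
#' @return A spectra tibble with the retained wavelength columns.
#' @export
trim_edges <- function(spectra, low_nm = 356, high_nm = 1100) {
  validate_spectra(spectra)
  if (low_nm > high_nm) abort("`low_nm` must not exceed `high_nm`.")
  wl <- spectra_wavelengths(spectra)
  keep <- wl >= low_nm & wl <= high_nm
  if (!any(keep)) abort("No wavelengths fall inside [low_nm, high_nm].")
  spectra[, c("sample_id", as.character(wl[keep]))]
}

#' Min-max normalization of reflectance
#'
#' Linearly rescales reflectance to `[0, 1]` by `(x - min) / (max - min)`.
#' With `scope = "global"` (default) one min/max pair is taken over the
#' whole matrix, so relative brightness differences between samples
#' survive; `scope = "per_spectrum"` rescales each spectrum independently.
#' The returned parameters invert the transform exactly, which is how
#' generated spectra are mapped back to reflectance units.
#'
#' @inheritParams sg_smooth
#' @param scope `"global"` or `"per_spectrum"`.
#' @param params Normalization parameters as returned in `$params`.
#' @return `minmax_normalize()` returns `list(spectra, params)` where
#'   `params` has fields `min_value`, `max_value` and `scope`;
#'   `minmax_denormalize()` returns a spectra tibble in original units.
#' @export
minmax_normalize <- function(spectra, scope = c("global", "per_spectrum")) {
  validate_spectra(spectra)
  scope <- match.arg(scope)
  mat <- spectra_matrix(spectra)
  if (scope == "global") {
    lo <- min(mat); hi <- max(mat)
    if (hi - lo < 1e-12) abort("Degenerate range: all reflectance values are equal.")
    out <- (mat - lo) / (hi - lo)
  } else {
    lo <- apply(mat, 1L, min); hi <- apply(mat, 1L, max)
    if (any(hi - lo < 1e-12)) abort("Degenerate range: a spectrum is constant.")
    out <- (mat - lo) / (hi - lo)
  }
  params <- list(min_value = lo, max_value = hi, scope = scope)
  list(spectra = as_spectra_tbl(out, spectra_wavelengths(spectra), spectra$sample_id),
       params = params)
}

#' @rdname minmax_normalize
#' @export
minmax_denormalize <- function(spectra, params) {
  validate_spectra(spectra)
  mat <- spectra_matrix(spectra)
  lo <- params$min_value; hi <- params$max_value
  if (params$scope == "per_spectrum" && length(lo) != nrow(mat)) {
    abort("Per-spectrum parameters do not match the number of spectra.")
  }
  out <- mat * (hi - lo) + lo
  as_spectra_tbl(out, spectra_wavelengths(spectra), spectra$sample_id)
}

#' Nutrient label scaling
#'
#' Nutrient concentrations in g/kg are mapped into (0, 1) by dividing by a
#' fixed power of ten chosen per nutrient: 100 for TK2O and SOM, 10 for TN
#' and TP2O5. This puts the label on the same scale as normalized
#' reflectance so that one joint vector can carry both. Values at or above
#' the divisor cannot be represented in (0, 1) and are rejected rather
#' than clipped, because clipping would corrupt the inverse mapping of
#' generated labels.
#'
#' @param values Positive concentrations in g/kg (for `scale_labels()`) or
#'   scaled values in (0, 1) (for `unscale_labels()`).
#' @param nutrient One of `"TK2O"`, `"TN"`, `"TP2O5"`, `"SOM"`, or `NULL`
#'   when `divisor` is given directly.
#' @param divisor Positive scale factor; defaults to the nutrient's mapping.
#' @return A numeric vector.
#' @export
scale_labels <- function(values, nutrient = NULL, divisor = NULL) {
  divisor <- divisor %||% nutrient_divisor(nutrient)
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("Label values must be positive and finite.")
  }
  if (any(values >= divisor)) {
    abort(sprintf("Label value >= divisor (%g); cannot be scaled into (0,1).", divisor))
  }
  values / divisor
}

#' @rdname scale_labels
#' @export
unscale_labels <- function(values, nutrient = NULL, divisor = NULL) {
  divisor <- divisor %||% nutrient_divisor(nutrient)
  values * divisor
}

#' @rdname scale_labels
#' @export
nutrient_divisor <- function(nutrient) {
  if (is.null(nutrient)) abort("Supply either `nutrient` or `divisor`.")
  div <- c(TK2O = 100, SOM = 100, TN = 10, TP2O5 = 10)[[match.arg(nutrient, c("TK2O", "TN", "TP2O5", "SOM"))]]
  div
}

#' Joint spectrum-plus-label matrices
#'
#' A joint table holds, per sample, the normalized spectrum followed by one
#' scaled nutrient label in a final `label_scaled` column, so a generative
#' model can produce spectra and labels simultaneously. All entries lie in
#' `[0, 1]`; the width is `n_bands + 1` (746 for a 745-channel grid).
#' Normalization parameters, the nutrient tag and its divisor travel as
#' attributes so generated rows can be mapped back to physical units.
#'
#' @param spectra01 A spectra tibble with all values in `[0, 1]`.
#' @param labels01 Scaled labels in `[0, 1]`, one per sample.
#' @param nutrient Nutrient tag.
#' @param norm_params Normalization parameters from [minmax_normalize()].
#' @param divisor Label divisor; defaults to the nutrient's mapping.
#' @param joint A joint tibble created by `combine_joint()`.
#' @return `combine_joint()` returns a `joint_tbl`;
#'   `split_joint()` returns `list(spectra, labels)`.
#' @export
combine_joint <- function(spectra01, labels01, nutrient = NULL,
                          norm_params = NULL, divisor = NULL) {
  validate_spectra(spectra01)
  mat <- spectra_matrix(spectra01)
  if (length(labels01) != nrow(mat)) {
    abort("Number of labels must equal number of spectra.")
  }
  if (any(mat < -1e-9) || any(mat > 1 + 1e-9) ||
      any(labels01 < -1e-9) || any(labels01 > 1 + 1e-9)) {
    abort("All joint-matrix entries must lie in [0, 1]; normalize/scale first.")
  }
  divisor <- divisor %||% if (!is.null(nutrient)) nutrient_divisor(nutrient) else NULL
  out <- dplyr::bind_cols(spectra01, tibble(label_scaled = as.numeric(labels01)))
  new_joint_tbl(out, nutrient = nutrient, divisor = divisor,
                norm_params = norm_params,
                wavelengths = spectra_wavelengths(spectra01))
}

new_joint_tbl <- function(data, nutrient, divisor, norm_params, wavelengths) {
  stopifnot(is.data.frame(data), "label_scaled" %in% names(data))
  structure(as_tibble(data),
            nutrient = nutrient, divisor = divisor,
            norm_params = norm_params, wavelengths = wavelengths,
            class = c("joint_tbl", class(as_tibble(data))))
}

#' @rdname combine_joint
#' @export
split_joint <- function(joint) {
  spec_cols <- setdiff(names(joint), c("sample_id", "label_scaled"))
  spectra <- as_tibble(joint)[, c("sample_id", spec_cols)]
  class(spectra) <- class(tibble())
  list(spectra = spectra, labels = joint$label_scaled)
}

#' @rdname combine_joint
#' @export
joint_matrix <- function(joint) {
  mat <- as.matrix(as_tibble(joint)[, setdiff(names(joint), "sample_id"), drop = FALSE])
  rownames(mat) <- joint$sample_id
  storage.mode(mat) <- "double"
  mat
}

#' @rdname combine_joint
#' @export
joint_meta <- function(joint) {
  list(nutrient = attr(joint, "nutrient"),
       divisor = attr(joint, "divisor"),
       norm_params = attr(joint, "norm_params"),
       wavelengths = attr(joint, "wavelengths"))
}

#' Persist a joint table as CSV plus a JSON sidecar
#'
#' The CSV holds `sample_id`, the wavelength columns and `label_scaled`;
#' the sidecar (`<path>.json`) stores the nutrient tag, divisor,
#' normalization parameters and wavelength list needed to invert the
#' preprocessing.
#'
#' @param joint A `joint_tbl`.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly (writer); a `joint_tbl` (reader).
#' @export
write_joint <- function(joint, path) {
  readr::write_csv(as_tibble(joint), path)
  meta <- joint_meta(joint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_joint
#' @export
read_joint <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(sample_id = readr::col_character(),
                                                  .default = readr::col_double()))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  np <- meta$norm_params
  new_joint_tbl(data, nutrient = meta$nutrient, divisor = meta$divisor,
                norm_params = np,
                wavelengths = meta$wavelengths %||%
                  as.numeric(setdiff(names(data), c("sample_id", "label_scaled"))))
}

#' Reproducible train/validation split
#'
#' Partitions `n_samples` indices into a training and a validation set by
#' a uniform random permutation under a mandatory seed. The training size
#' is `ceiling(ratio * n_samples)`, so 42 samples at the default 7:3 ratio
#' give 30 training and 12 validation samples.
#'
#' @param n_samples Number of samples (>= 2).
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed (required for reproducibility).
#' @return `list(train = , val = )` of disjoint, exhaustive integer indices.
#' @export
train_val_split <- function(n_samples, ratio = 0.7, seed) {
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    abort("`ratio` must lie strictly between 0 and 1.")
  }
  if (missing(seed)) abort("`seed` is required.")
  n_train <- as.integer(ceiling(ratio * n_samples))
  perm <- with_seed(seed, sample.int(n_samples))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[seq.int(n_train + 1L, n_samples)]))
}

#' One-call preprocessing pipeline
#'
#' Runs the standard chain: Savitzky-Golay smoothing, edge trimming,
#' min-max normalization, label scaling, and assembly of the joint table.
#'
#' @inheritParams sg_smooth
#' @inheritParams trim_edges
#' @inheritParams minmax_normalize
#' @param labels_g_per_kg Nutrient concentrations in g/kg, one per sample.
#' @param nutrient Nutrient tag (sets the label divisor).
#' @return A `joint_tbl` carrying the normalization parameters.
#' @export
preprocess_joint <- function(spectra, labels_g_per_kg, nutrient,
                             window = 11, polyorder = 2,
                             low_nm = 356, high_nm = 1100,
                             scope = "global") {
  sm <- sg_smooth(spectra, window = window, polyorder = polyorder)
  tr <- trim_edges(sm, low_nm = low_nm, high_nm = high_nm)
  nm <- minmax_normalize(tr, scope = scope)
  lab <- scale_labels(labels_g_per_kg, nutrient = nutrient)
  combine_joint(nm$spectra, lab, nutrient = nutrient, norm_params = nm$params)
}
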