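#' Synthetic soil-spectra configuration
#'
#' Describes a simulated Vis-NIR soil dataset with known
#' spectrum-nutrient structure. Each clean spectrum is a slowly rising
#' sigmoid-plus-slope base curve (the typical soil reflectance shape in
#' the visible to near-infrared) minus Gaussian absorption features whose
#' depths are proportional to the sample's nutrient content; per-sample
#' baseline offsets, multiplicative factors and polynomial tilt emulate
#' the physical distortions that multiplicative signal correction
#' targets, plus white measurement noise.
#'
#' Label distributions default to a truncated normal matching the
#' small-sample statistics reported for real alpine-meadow soils:
#' TK2O 13.790-21.610 (mean 18.995, sd 2.167), TN 0.450-3.760
#' (2.085, 0.754), TP2O5 1.020-1.590 (1.254, 0.147) and SOM 4.070-71.090
#' (34.467, 15.201) g/kg. Feature centres default to 450, 600, 850 and
#' 1000 nm. This is a test-structure generator, not a claim of
#' spectroscopic fidelity to any particular soil.
#'
#' @param nutrient One of `"TK2O"`, `"TN"`, `"TP2O5"`, `"SOM"`.
#' @param n_samples Number of samples (default 42, the study's size).
#' @param wavelengths Wavelength grid in nm (default 320:1100, 1 nm).
#' @param label_min,label_max,label_mean,label_sd Label moments in g/kg;
#'   default to the nutrient's table above.
#' @param features List of `c(center_nm, width_nm, sensitivity)` triples;
#'   a feature removes `sensitivity * label` reflectance units at its
#'   centre per g/kg of nutrient. Default sensitivities scale with the
#'   nutrient's maximum so total feature depth stays in a plausible
#'   reflectance range.
#' @param baseline_sd,mult_sd Std. dev. of the per-sample additive offset
#'   `a ~ N(0, baseline_sd)` and multiplicative factor
#'   `b ~ N(1, mult_sd)`.
#' @param tilt_sd Std. dev. per polynomial tilt coefficient (linear,
#'   quadratic) on the normalized axis.
#' @param noise_sd White-noise standard deviation (reflectance units).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(nutrient = "TK2O", n_samples = 42,
                             wavelengths = 320:1100,
                             label_min = NULL, label_max = NULL,
                             label_mean = NULL, label_sd = NULL,
                             features = NULL,
                             baseline_sd = 0.02, mult_sd = 0.05,
                             tilt_sd = c(0.02, 0.01), noise_sd = 0.002,
                             seed = 1L) {
  nutrient <- match.arg(nutrient, c("TK2O", "TN", "TP2O5", "SOM"))
  ref <- nutrient_reference_moments(nutrient)
  label_min <- label_min %||% ref$min
  label_max <- label_max %||% ref$max
  label_mean <- label_mean %||% ref$mean
  label_sd <- label_sd %||% ref$sd
  if (label_min <= 0 || label_max <= label_min) abort("Label range must be positive with max > min.")
  if (label_max >= nutrient_divisor(nutrient)) {
    abort("Label range must stay below the nutrient's divisor.")
  }
  if (label_mean < label_min || label_mean > label_max) {
    abort("Infeasible label moments: mean outside [min, max].")
  }
  if (label_sd <= 0 || label_sd > (label_max - label_min)) {
    abort("Infeasible label moments: sd must be positive and within the range width.")
  }
  if (is.null(features)) {
    sens <- 0.06 / label_max        # ~0.06 reflectance units at max content
    features <- list(c(450, 25, sens), c(600, 40, 0.8 * sens),
                     c(850, 50, 1.2 * sens), c(1000, 35, sens))
  }
  if (any(vapply(features, function(f) f[2] <= 0, logical(1)))) {
    abort("Feature widths must be positive.")
  }
  if (baseline_sd < 0 || mult_sd < 0 || any(tilt_sd < 0) || noise_sd < 0) {
    abort("All standard deviations must be >= 0.")
  }
  structure(list(nutrient = nutrient,
                 n_samples = assert_count(n_samples, "n_samples", min = 1L),
                 wavelengths = as.numeric(wavelengths),
                 label_min = label_min, label_max = label_max,
                 label_mean = label_mean, label_sd = label_sd,
                 features = features,
                 baseline_sd = baseline_sd, mult_sd = mult_sd,
                 tilt_sd = as.numeric(tilt_sd), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

nutrient_reference_moments <- function(nutrient) {
  switch(nutrient,
         TK2O = list(min = 13.790, max = 21.610, mean = 18.995, sd = 2.167),
         TN = list(min = 0.450, max = 3.760, mean = 2.085, sd = 0.754),
         TP2O5 = list(min = 1.020, max = 1.590, mean = 1.254, sd = 0.147),
         SOM = list(min = 4.070, max = 71.090, mean = 34.467, sd = 15.201))
}

soil_base_curve <- function(wavelengths) {
  # slowly rising sigmoid plus gentle slope, ~0.10 at 320 nm to ~0.45 at 1100 nm
  u <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  0.10 + 0.28 / (1 + exp(-6 * (u - 0.45))) + 0.08 * u
}

#' Simulate a soil spectra dataset with known ground truth
#'
#' Draws labels from a truncated normal, builds clean spectra whose
#' absorption-feature depths are deterministically linked to the label,
#' applies per-sample baseline/multiplicative/tilt distortions
#' (`b * clean + a + tilt(v)`), and adds white noise. Everything is
#' reproducible from the config seed, and all true quantities are
#' returned for oracle-style testing.
#'
#' @param config A [synthetic_config()].
#' @return A list: `spectra` (tibble, reflectance), `labels` (tibble
#'   `sample_id`, `nutrient`, `value_g_per_kg`) and `truth` (list with
#'   `labels`, `params` tibble of true `a`, `b`, `d1`, `d2`, and the
#'   `clean` spectra matrix before distortion and noise).
#' @export
simulate_dataset <- function(config) {
  cfg <- config
  wl <- cfg$wavelengths
  m <- length(wl)
  n <- cfg$n_samples
  base <- soil_base_curve(wl)
  axis <- seq(0, 1, length.out = m)

  with_seed(cfg$seed, {
    labels <- rtrunc_norm(n, cfg$label_mean, cfg$label_sd, cfg$label_min, cfg$label_max)
    feat <- matrix(0, n, m)
    for (f in cfg$features) {
      shape <- exp(-0.5 * ((wl - f[1]) / f[2])^2)
      feat <- feat + outer(labels * f[3], shape)
    }
    clean <- matrix(base, n, m, byrow = TRUE) - feat
    a <- rnorm(n, 0, cfg$baseline_sd)
    b <- rnorm(n, 1, cfg$mult_sd)
    d1 <- rnorm(n, 0, cfg$tilt_sd[1])
    d2 <- rnorm(n, 0, if (length(cfg$tilt_sd) > 1L) cfg$tilt_sd[2] else 0)
    distorted <- clean * b + a + outer(d1, axis) + outer(d2, axis^2)
    noisy <- distorted + matrix(rnorm(n * m, 0, cfg$noise_sd), n, m)

    ids <- sprintf("sim%03d", seq_len(n))
    list(spectra = as_spectra_tbl(noisy, wl, ids),
         labels = tibble(sample_id = ids, nutrient = cfg$nutrient,
                         value_g_per_kg = labels),
         truth = list(labels = labels,
                      params = tibble(sample_id = ids, a = a, b = b, d1 = d1, d2 = d2),
                      clean = clean))
  })
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Apply known EMSC-style distortions to clean spectra
#'
#' Applies the forward distortion model exactly -
#' `A = a + b * clean + d1 * v + d2 * v^2 + ...` on the normalized channel
#' axis - so that an EMSC fit against the clean reference must recover
#' the injected parameters.
#'
#' @param clean A spectra tibble or numeric matrix of clean spectra.
#' @param params Data frame with one row per spectrum and columns `a`,
#'   `b`, and `d1..dn` (any `n >= 0` of them); `b` must be non-zero.
#' @return Distorted spectra in the same form as `clean` (tibble in,
#'   tibble out).
#' @export
inject_known_distortions <- function(clean, params) {
  tib <- !is.matrix(clean)
  mat <- if (tib) spectra_matrix(clean) else clean
  if (nrow(mat) != nrow(params)) abort("`params` must have one row per spectrum.")
  if (any(params$b == 0)) abort("Multiplicative factors must be non-zero.")
  d_cols <- grep("^d[0-9]+$", names(params), value = TRUE)
  axis <- seq(0, 1, length.out = ncol(mat))
  out <- mat * params$b + params$a
  for (col in d_cols) {
    pw <- as.integer(sub("^d", "", col))
    out <- out + outer(as.numeric(params[[col]]), axis^pw)
  }
  if (tib) as_spectra_tbl(out, spectra_wavelengths(clean), clean$sample_id) else out
}
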