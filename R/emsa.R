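#' Extended multiplicative signal correction (EMSC) model
#'
#' An EMSC model decomposes a measured spectrum `A` against a reference
#' spectrum `m` (by default the mean of the training spectra) as
#'
#'   `A = a + b * m + d1 * v + d2 * v^2 + ... + dn * v^n + e`
#'
#' where `a` is a baseline offset, `b` a multiplicative (path-length /
#' particle-size) factor, the `d_i` capture polynomial tilt from
#' wavelength-dependent scattering, and `e` is the residual. The abscissa
#' `v` is the normalized channel position in `[0, 1]`, which keeps the
#' design numerically well conditioned and independent of wavelength
#' units.
#'
#' @param x A spectra tibble, `joint_tbl`, or numeric matrix whose column
#'   means form the reference, or a numeric vector used directly as the
#'   reference.
#' @param degree Polynomial order `n >= 1` (default 2: baseline, linear,
#'   quadratic).
#' @return An `emsc_model`: list with `reference`, `axis`, `degree` and
#'   the fixed design matrix `M = [1, m, v, v^2, ...]`.
#' @export
emsc_model <- function(x, degree = 2) {
  degree <- assert_count(degree, "degree", min = 1L)
  reference <-
    if (is.numeric(x) && is.null(dim(x))) as.numeric(x)
    else if (inherits(x, "joint_tbl")) colMeans(joint_matrix(x))
    else if (is.matrix(x)) colMeans(x)
    else colMeans(spectra_matrix(x))
  m <- length(reference)
  if (m < degree + 2L) abort("Reference is too short for the requested degree.")
  axis <- seq(0, 1, length.out = m)
  M <- cbind(1, reference, outer(axis, seq_len(degree), `^`))
  colnames(M) <- c("a", "b", paste0("d", seq_len(degree)))
  if (qr(M)$rank < ncol(M)) {
    abort("Rank-deficient EMSC design: the reference spectrum is collinear with the polynomial columns.")
  }
  structure(list(reference = reference, axis = axis, degree = degree, M = M),
            class = "emsc_model")
}

#' Fit EMSC distortion parameters to spectra
#'
#' Solves the least-squares problem `p = (M'M)^-1 M' A` per spectrum,
#' yielding the baseline `a`, multiplicative factor `b`, polynomial
#' coefficients `d1..dn` and the residual `e = A - M p`. The
#' reconstruction `M p + e` reproduces the input exactly.
#'
#' @param spectra A numeric vector (one spectrum), matrix (rows are
#'   spectra), spectra tibble or `joint_tbl`.
#' @param model An [emsc_model()].
#' @return A tibble with one row per spectrum: columns `a`, `b`,
#'   `d1..dn`, and a list-column `residual`.
#' @export
emsc_fit <- function(spectra, model) {
  mat <- emsc_as_matrix(spectra, model)
  fit <- qr.coef(qr(model$M), t(mat))          # (2 + degree) x n
  resid <- t(mat) - model$M %*% fit
  out <- as_tibble(as.data.frame(t(fit)))
  names(out) <- colnames(model$M)
  out$residual <- lapply(seq_len(ncol(resid)), function(i) as.numeric(resid[, i]))
  out
}

emsc_as_matrix <- function(spectra, model) {
  mat <-
    if (is.numeric(spectra) && is.null(dim(spectra))) matrix(spectra, nrow = 1L)
    else if (inherits(spectra, "joint_tbl")) joint_matrix(spectra)
    else if (is.matrix(spectra)) spectra
    else spectra_matrix(spectra)
  if (ncol(mat) != length(model$reference)) {
    abort("Spectrum length does not match the EMSC model.")
  }
  mat
}

#' Apply an EMSC correction
#'
#' Computes `(A - a - d1*v - ... - dn*v^n) / b`, which equals
#' `m + e / b`: the corrected spectrum is the reference plus the scaled
#' residual.
#'
#' @param spectrum Numeric vector.
#' @param params One row of [emsc_fit()] output (or a list with fields
#'   `a`, `b`, `d1..dn`).
#' @param model The [emsc_model()] used for the fit.
#' @param tol Smallest `|b|` accepted before the division is refused.
#' @return The corrected spectrum (numeric vector).
#' @export
emsc_correct <- function(spectrum, params, model, tol = 1e-12) {
  b <- as.numeric(params$b)
  if (!is.finite(b) || abs(b) < tol) {
    abort("Multiplicative factor `b` is (near) zero; spectrum is not correctable.")
  }
  d <- as.numeric(unlist(params[paste0("d", seq_len(model$degree))]))
  poly <- as.numeric(outer(model$axis, seq_len(model$degree), `^`) %*% d)
  (as.numeric(spectrum) - as.numeric(params$a) - poly) / b
}

#' EMSA: augment spectra by perturbing EMSC parameters
#'
#' Extended multiplicative signal augmentation fits EMSC parameters to
#' every training row, measures their standard deviations across the
#' training set (`sigma_a`, `sigma_b`, `sigma_d1`, ...), then builds each
#' new row from a source row (cycled round-robin) by adding zero-mean
#' Gaussian deviations to its parameters and re-synthesizing
#'
#'   `A_new = a' + b' * m + d1' * v + ... + dn' * v^n + e * b'/b`
#'
#' with the source residual `e` rescaled by `b'/b`. With all deviations
#' zero this reduces to the source row exactly. By default the model is
#' fitted over the full joint vector (spectral channels plus the scaled
#' label slot), so labels are perturbed together with their spectra; with
#' `spectra_only = TRUE` the fit covers only the spectral channels and
#' each generated row copies its source label unchanged.
#'
#' Generated values are not clipped to `[0, 1]`: clipping would break the
#' property that refitting EMSC on a generated row recovers its perturbed
#' parameters. Set `clip = TRUE` to clamp for downstream models that
#' require `[0, 1]` inputs.
#'
#' @param joint A `joint_tbl` with >= 2 rows.
#' @param n_new Number of rows to generate (>= 0).
#' @param degree Polynomial order of the EMSC model.
#' @param seed Integer seed; generation is deterministic given
#'   `(joint, seed)`.
#' @param spectra_only Fit and perturb only the spectral channels.
#' @param clip Clamp generated values into `[0, 1]`.
#' @param sigma_scale Multiplier on all parameter standard deviations
#'   (0 forces exact copies of the source rows).
#' @return A `joint_tbl` with `n_new` rows and the same width/metadata.
#' @export
emsa_generate <- function(joint, n_new, degree = 2, seed = 1L,
                          spectra_only = FALSE, clip = FALSE,
                          sigma_scale = 1) {
  if (length(n_new) != 1L || !is.finite(n_new) || n_new < 0 || n_new != trunc(n_new)) {
    abort("`n_new` must be a single non-negative integer.")
  }
  mat <- joint_matrix(joint)
  if (nrow(mat) < 2L) abort("EMSA needs at least 2 source rows to measure parameter deviations.")
  fit_mat <- if (spectra_only) mat[, -ncol(mat), drop = FALSE] else mat
  model <- emsc_model(colMeans(fit_mat), degree = degree)
  params <- emsc_fit(fit_mat, model)
  if (any(abs(params$b) < 1e-12)) {
    abort("A source spectrum has multiplicative factor b = 0; cannot augment it.")
  }
  par_cols <- c("a", "b", paste0("d", seq_len(degree)))
  sigma <- vapply(params[par_cols], sd, numeric(1)) * sigma_scale

  n_src <- nrow(mat)
  src <- rep_len(seq_len(n_src), n_new)          # round-robin source cycling
  poly_basis <- outer(model$axis, seq_len(degree), `^`)

  new_rows <- with_seed(seed, {
    dev <- sweep(matrix(rnorm(n_new * length(par_cols)), n_new, length(par_cols)),
                 2L, sigma, "*")
    out <- matrix(0, n_new, ncol(fit_mat))
    for (i in seq_len(max(n_new, 0L))) {
      s <- src[i]
      p0 <- as.numeric(unlist(params[s, par_cols]))
      p1 <- p0 + dev[i, ]
      e <- params$residual[[s]]
      out[i, ] <- p1[1] + model$reference * p1[2] +
        as.numeric(poly_basis %*% p1[-(1:2)]) + e * p1[2] / p0[2]
    }
    out
  })
  if (spectra_only && n_new > 0) {
    new_rows <- cbind(new_rows, mat[src, ncol(mat)])
  } else if (spectra_only) {
    new_rows <- cbind(new_rows, numeric(0))
  }
  if (clip) new_rows <- pmin(pmax(new_rows, 0), 1)

  meta <- joint_meta(joint)
  nb <- ncol(mat) - 1L
  data <- as_tibble(as.data.frame(new_rows), .name_repair = "minimal")
  names(data) <- c(as.character(meta$wavelengths %||% seq_len(nb)), "label_scaled")
  data <- dplyr::bind_cols(tibble(sample_id = if (n_new > 0) paste0("emsa_", seq_len(n_new)) else character(0)),
                           data)
  new_joint_tbl(data, nutrient = meta$nutrient, divisor = meta$divisor,
                norm_params = meta$norm_params, wavelengths = meta$wavelengths)
}
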