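# Savitzky-Golay oracle: fit a polynomial in each sliding window by least
# squares and evaluate at the window centre (interior points only).
sg_oracle <- function(x, window, polyorder = 2) {
  h <- (window - 1L) / 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq.int(h + 1L, n - h)) {
    t <- seq.int(-h, h)
    fit <- stats::lm.fit(outer(t, 0:polyorder, `^`), x[(i - h):(i + h)])
    out[i] <- fit$coefficients[1L]
  }
  out
}

test_that("SG smoothing preserves polynomials up to its order and matches a sliding least-squares oracle", {
  wl <- 400:479
  const <- as_spectra_tbl(matrix(0.5, 1, 80), wl)
  expect_equal(spectra_matrix(sg_smooth(const, window = 11)),
               spectra_matrix(const), tolerance = 1e-12)

  quad <- matrix(2e-6 * wl^2 - 1e-3 * wl + 0.4, 1)
  quad_tbl <- as_spectra_tbl(quad, wl)
  expect_equal(spectra_matrix(sg_smooth(quad_tbl, window = 11, polyorder = 2)),
               quad, ignore_attr = TRUE, tolerance = 1e-9)

  set.seed(5)
  noisy <- sin(seq(0, 6, length.out = 80)) + rnorm(80, sd = 0.05)
  sm <- spectra_matrix(sg_smooth(as_spectra_tbl(matrix(noisy, 1), wl), window = 9))[1, ]
  orc <- sg_oracle(noisy, window = 9)
  interior <- which(!is.na(orc))
  expect_equal(unname(sm[interior]), orc[interior], tolerance = 1e-10)
})

test_that("SG filtering is linear on interior points", {
  wl <- 400:459
  set.seed(11)
  x <- runif(60); y <- runif(60)
  f <- function(v) spectra_matrix(sg_smooth(as_spectra_tbl(matrix(v, 1), wl), window = 9))[1, ]
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  interior <- 5:56
  expect_equal(unname(lhs[interior]), unname(rhs[interior]), tolerance = 1e-9)
})

test_that("SG smoothing rejects invalid windows", {
  s <- tiny_spectra()
  expect_error(sg_smooth(s, window = 8), "odd")
  expect_error(sg_smooth(s, window = 3, polyorder = 3), "greater")
  expect_error(sg_smooth(s, window = 2), "odd|>=")
})

test_that("edge trimming keeps the closed interval and yields 745 channels from a full grid", {
  full <- as_spectra_tbl(matrix(0.3, 2, 781), 320:1100)
  tr <- trim_edges(full)
  expect_identical(ncol(tr) - 1L, 745L)
  expect_identical(spectra_wavelengths(tr), as.numeric(356:1100))

  # interval wider than the grid: identity
  expect_identical(trim_edges(full, 100, 2000), full)
  # already satisfied
  pre <- as_spectra_tbl(matrix(0.3, 2, 745), 356:1100)
  expect_identical(trim_edges(pre), pre)
  expect_identical(ncol(trim_edges(pre)) - 1L, 745L)
  expect_error(trim_edges(full, 2000, 3000), "No wavelengths|exceed")
})

test_that("min-max normalization matches the elementwise formula and round-trips", {
  row <- as_spectra_tbl(matrix(c(2, 4, 6), 1), c(500, 501, 502))
  nm <- minmax_normalize(row, scope = "per_spectrum")
  expect_equal(unname(spectra_matrix(nm$spectra)[1, ]), c(0, 0.5, 1))

  set.seed(3)
  mat <- matrix(runif(60, 0.1, 0.9), 5, 12)
  tbl <- as_spectra_tbl(mat, 400:411)
  glob <- minmax_normalize(tbl, scope = "global")
  expect_equal(spectra_matrix(glob$spectra),
               (mat - min(mat)) / (max(mat) - min(mat)), ignore_attr = TRUE)
  expect_true(all(spectra_matrix(glob$spectra) >= 0 & spectra_matrix(glob$spectra) <= 1))
  back <- minmax_denormalize(glob$spectra, glob$params)
  expect_equal(spectra_matrix(back), mat, ignore_attr = TRUE, tolerance = 1e-10)

  per <- minmax_normalize(tbl, scope = "per_spectrum")
  expect_equal(spectra_matrix(minmax_denormalize(per$spectra, per$params)),
               mat, ignore_attr = TRUE, tolerance = 1e-10)

  expect_error(minmax_normalize(as_spectra_tbl(matrix(1, 2, 4), 1:4)), "Degenerate")
})

test_that("label scaling uses the nutrient divisor mapping and inverts exactly", {
  expect_equal(scale_labels(19.570, "TK2O"), 0.1957)
  expect_equal(scale_labels(2.150, "TN"), 0.2150)
  expect_identical(nutrient_divisor("TK2O"), 100)
  expect_identical(nutrient_divisor("SOM"), 100)
  expect_identical(nutrient_divisor("TN"), 10)
  expect_identical(nutrient_divisor("TP2O5"), 10)

  set.seed(9)
  v <- runif(20, 0.01, 9.99)
  expect_equal(unscale_labels(scale_labels(v, "TN"), "TN"), v, tolerance = 1e-12)

  expect_error(scale_labels(10, "TN"), "divisor")
  expect_error(scale_labels(-1, "TN"), "positive")
})

test_that("combine and split are inverse and enforce the [0,1] joint contract", {
  set.seed(21)
  mat <- matrix(runif(30 * 745), 30, 745)
  tbl <- as_spectra_tbl(mat, 356:1100)
  labs <- runif(30)
  joint <- combine_joint(tbl, labs, nutrient = "TK2O")
  expect_identical(ncol(joint_matrix(joint)), 746L)
  expect_identical(nrow(joint_matrix(joint)), 30L)

  parts <- split_joint(joint)
  expect_equal(spectra_matrix(parts$spectra), mat, ignore_attr = TRUE)
  expect_identical(parts$labels, labs)

  expect_error(combine_joint(tbl, labs[-1]), "equal")
  bad <- tbl; bad[[5]][2] <- 1.5
  expect_error(combine_joint(bad, labs), "\\[0, 1\\]")
})

test_that("train/validation split is exhaustive, seeded and reproduces the 30/12 partition", {
  sp <- train_val_split(42, 0.7, seed = 4)
  expect_length(sp$train, 30L)
  expect_length(sp$val, 12L)
  expect_setequal(c(sp$train, sp$val), 1:42)
  expect_length(intersect(sp$train, sp$val), 0L)

  expect_identical(train_val_split(42, 0.7, seed = 4), sp)
  expect_false(identical(train_val_split(42, 0.7, seed = 5), sp))

  sp2 <- train_val_split(10, 0.5, seed = 1)
  expect_length(sp2$train, 5L)
  expect_length(sp2$val, 5L)

  expect_error(train_val_split(1, 0.7, seed = 1), ">= 2")
  expect_error(train_val_split(10, 1.2, seed = 1), "between")
})

test_that("joint tables persist through CSV plus sidecar and invert preprocessing", {
  joint <- small_joint(n = 8)
  tmp <- tempfile(fileext = ".csv")
  write_joint(joint, tmp)
  back <- read_joint(tmp)
  expect_equal(joint_matrix(back), joint_matrix(joint), tolerance = 1e-12)
  expect_identical(attr(back, "nutrient"), attr(joint, "nutrient"))
  expect_equal(attr(back, "divisor"), attr(joint, "divisor"))
  expect_equal(attr(back, "norm_params")$min_value,
               attr(joint, "norm_params")$min_value)
  file.remove(tmp, paste0(tmp, ".json"))
})
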