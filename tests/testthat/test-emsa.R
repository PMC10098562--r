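test_that("EMSC fit recovers exact parameters on constructed spectra", {
  # fitting the reference itself
  ref <- c(0.2, 0.5, 0.6, 0.4, 0.3)
  model <- emsc_model(ref, degree = 2)
  fit <- emsc_fit(ref, model)
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_equal(fit$d1, 0, tolerance = 1e-10)
  expect_equal(fit$d2, 0, tolerance = 1e-10)
  expect_equal(fit$residual[[1]], rep(0, 5), tolerance = 1e-10)

  # 3-point exact system, degree 1: A = 0.1 + 2 m + 0.3 v
  m3 <- c(0.2, 0.5, 0.6)
  model1 <- emsc_model(m3, degree = 1)
  A <- 0.1 + 2 * m3 + 0.3 * c(0, 0.5, 1)
  expect_equal(A, c(0.5, 1.25, 1.6))
  f3 <- emsc_fit(A, model1)
  expect_equal(f3$a, 0.1, tolerance = 1e-10)
  expect_equal(f3$b, 2, tolerance = 1e-10)
  expect_equal(f3$d1, 0.3, tolerance = 1e-10)
  expect_equal(f3$residual[[1]], rep(0, 3), tolerance = 1e-10)

  # random degree-2 construction recovered to 1e-8
  set.seed(31)
  ref2 <- 0.3 + 0.2 * sin(seq(0, 4, length.out = 50))
  model2 <- emsc_model(ref2, degree = 2)
  v <- model2$axis
  for (i in 1:5) {
    p <- c(a = rnorm(1, 0, 0.1), b = runif(1, 0.5, 2),
           d1 = rnorm(1, 0, 0.2), d2 = rnorm(1, 0, 0.2))
    A2 <- p["a"] + p["b"] * ref2 + p["d1"] * v + p["d2"] * v^2
    f <- emsc_fit(A2, model2)
    expect_equal(unname(unlist(f[c("a", "b", "d1", "d2")])), unname(p), tolerance = 1e-8)
  }
})

test_that("EMSC fit-reconstruct identity and scale equivariance hold", {
  set.seed(41)
  mat <- matrix(runif(6 * 30, 0.1, 0.8), 6, 30)
  model <- emsc_model(mat, degree = 2)
  fit <- emsc_fit(mat, model)
  for (i in 1:6) {
    p <- as.numeric(unlist(fit[i, c("a", "b", "d1", "d2")]))
    recon <- as.numeric(model$M %*% p) + fit$residual[[i]]
    expect_equal(recon, unname(mat[i, ]), tolerance = 1e-10)
  }
  # fitting c * A yields c * p and c * e
  cs <- 3.7
  fit_scaled <- emsc_fit(cs * mat, model)
  expect_equal(fit_scaled$a, cs * fit$a, tolerance = 1e-8)
  expect_equal(fit_scaled$b, cs * fit$b, tolerance = 1e-8)
  expect_equal(fit_scaled$residual[[2]], cs * fit$residual[[2]], tolerance = 1e-8)
})

test_that("EMSC correction returns the reference plus scaled residual", {
  ref <- 0.3 + 0.2 * sin(seq(0, 4, length.out = 40))
  model <- emsc_model(ref, degree = 2)

  fit_ref <- emsc_fit(ref, model)
  expect_equal(emsc_correct(ref, fit_ref[1, ], model), ref, tolerance = 1e-10)

  A <- 0.1 + 2 * ref
  fitA <- emsc_fit(A, model)
  expect_equal(emsc_correct(A, fitA[1, ], model), ref, tolerance = 1e-10)

  # identity m + e/b on random spectra
  set.seed(13)
  spec <- ref + rnorm(40, 0, 0.05)
  fit2 <- emsc_fit(spec, model)
  corr <- emsc_correct(spec, fit2[1, ], model)
  expect_equal(corr, ref + fit2$residual[[1]] / fit2$b, tolerance = 1e-10)

  fit2$b <- 0
  expect_error(emsc_correct(spec, fit2[1, ], model), "zero")
})

test_that("EMSC model rejects rank-deficient designs", {
  # reference collinear with the polynomial columns (an affine ramp)
  axis_like <- seq(0, 1, length.out = 20)
  expect_error(emsc_model(0.2 + 0.5 * axis_like, degree = 1), "collinear|Rank")
})

test_that("EMSA with zero deviations reproduces source rows exactly, round-robin", {
  joint <- small_joint(n = 7)
  gen <- emsa_generate(joint, n_new = 10, seed = 5, sigma_scale = 0)
  src <- joint_matrix(joint)
  out <- joint_matrix(gen)
  expect_identical(dim(out), c(10L, ncol(src)))
  for (i in 1:10) {
    expect_equal(unname(out[i, ]), unname(src[((i - 1) %% 7) + 1, ]), tolerance = 1e-10)
  }
})

test_that("EMSA is seeded, deterministic and produces the requested shape", {
  joint <- small_joint(n = 9)
  g1 <- emsa_generate(joint, 25, seed = 8)
  g2 <- emsa_generate(joint, 25, seed = 8)
  g3 <- emsa_generate(joint, 25, seed = 9)
  expect_equal(joint_matrix(g1), joint_matrix(g2))
  expect_false(isTRUE(all.equal(joint_matrix(g1), joint_matrix(g3))))
  expect_identical(dim(joint_matrix(g1)), c(25L, ncol(joint_matrix(joint))))

  g0 <- emsa_generate(joint, 0, seed = 1)
  expect_identical(nrow(joint_matrix(g0)), 0L)
  expect_identical(ncol(joint_matrix(g0)), ncol(joint_matrix(joint)))
  expect_error(emsa_generate(joint, -1), "non-negative")
  expect_error(emsa_generate(joint[1, ], 5), "at least 2")
})

test_that("refitting EMSC on EMSA output recovers the perturbed parameters", {
  joint <- small_joint(n = 6)
  mat <- joint_matrix(joint)
  model <- emsc_model(colMeans(mat), degree = 2)
  src_fit <- emsc_fit(mat, model)
  gen <- emsa_generate(joint, 12, seed = 3)
  gen_fit <- emsc_fit(joint_matrix(gen), model)
  # the generated row is exactly a' + b' m + poly(d') + e * b'/b, and e is
  # orthogonal to the design, so the refit residual must equal e * b_hat/b_src
  for (i in 1:12) {
    s <- ((i - 1) %% 6) + 1
    expect_equal(gen_fit$residual[[i]],
                 src_fit$residual[[s]] * gen_fit$b[i] / src_fit$b[s],
                 tolerance = 1e-8)
  }
})

test_that("spectra-only EMSA copies source labels unchanged", {
  joint <- small_joint(n = 6)
  gen <- emsa_generate(joint, 9, seed = 2, spectra_only = TRUE)
  src_labs <- joint_matrix(joint)[, ncol(joint_matrix(joint))]
  out <- joint_matrix(gen)
  expect_equal(unname(out[, ncol(out)]), unname(src_labs[((1:9 - 1) %% 6) + 1]))
})

test_that("EMSA parameter means stay near the source means (zero-mean deviations)", {
  joint <- small_joint(n = 10)
  mat <- joint_matrix(joint)
  model <- emsc_model(colMeans(mat), degree = 2)
  src_fit <- emsc_fit(mat, model)
  cols <- c("a", "b", "d1", "d2")
  src_mean <- vapply(src_fit[cols], mean, numeric(1))
  src_sd <- vapply(src_fit[cols], sd, numeric(1))
  n_new <- 200
  gen_fit <- emsc_fit(joint_matrix(emsa_generate(joint, n_new, seed = 17)), model)
  gen_mean <- vapply(gen_fit[cols], mean, numeric(1))
  # source means repeat round-robin; deviations are zero-mean with sd sigma,
  # so the generated mean is within ~3 sigma/sqrt(n) of the source mean
  se <- src_sd / sqrt(n_new)
  expect_true(all(abs(gen_mean - src_mean) <= 3 * se + 1e-12))
})
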