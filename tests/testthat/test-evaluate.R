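test_that("PC1 reduction matches an SVD/prcomp oracle up to sign and fixes the loading sign", {
  set.seed(61)
  mat <- matrix(rnorm(6 * 9), 6, 9)
  p <- pc1_reduce(mat)

  orc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  expect_equal(abs(p$scores), abs(unname(orc$x[, 1])), tolerance = 1e-10)
  expect_equal(p$contribution,
               orc$sdev[1]^2 / sum(orc$sdev^2), tolerance = 1e-12)
  # sign convention: largest-magnitude loading element is positive
  expect_gt(p$loading[which.max(abs(p$loading))], 0)
  # scores centred
  expect_equal(mean(p$scores), 0, tolerance = 1e-10)
})

test_that("PC1 contribution is 1 for collinear rows and errors on zero variance", {
  base <- c(1, 2, 3, 4)
  mat <- rbind(base, 2 * base, 3.5 * base, -1 * base)
  expect_equal(pc1_reduce(mat)$contribution, 1, tolerance = 1e-12)
  expect_error(pc1_reduce(rbind(base, base)), "Zero total variance")
  expect_error(pc1_reduce(matrix(1, 1, 4)), "at least 2")
})

test_that("PC1 scores are invariant (up to the fixed sign) under orthogonal rotation of samples", {
  set.seed(62)
  mat <- matrix(rnorm(8 * 5), 8, 5)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  p1 <- pc1_reduce(mat)
  p2 <- pc1_reduce(mat %*% q)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
  expect_equal(p1$contribution, p2$contribution, tolerance = 1e-10)
})

test_that("label summaries match sort-based order statistics and the IQR rule", {
  s <- label_summary(c(7, 1, 3))
  expect_equal(s$length, 6)
  expect_equal(s$min, 1)
  expect_equal(s$max, 7)

  const <- label_summary(rep(4.2, 5))
  expect_equal(const$sd, 0)
  expect_equal(const$min, const$max)
  expect_equal(const$mean, const$median)

  # hand IQR computation: quartiles of 1,2,3,4,100 are 2 and 4 (linear
  # interpolation), so the fence is [-1, 7] and 100 is removed
  out <- label_summary(c(1, 2, 3, 4, 100), remove_outliers = TRUE)
  expect_identical(out$n, 4L)
  expect_identical(out$n_removed, 1L)
  expect_equal(out$mean, 2.5)
  expect_equal(out$max, 4)

  # even-length median = mean of the two central order statistics
  expect_equal(label_summary(c(9, 1, 5, 3))$median, 4)

  # no removal: classical order statistics against a sort oracle
  set.seed(71)
  v <- rnorm(27)
  s2 <- label_summary(v)
  sv <- sort(v)
  expect_equal(s2$min, sv[1])
  expect_equal(s2$max, sv[27])
  expect_equal(s2$median, sv[14])
  expect_equal(s2$q1, unname(quantile(v, 0.25)))
  expect_equal(s2$q3, unname(quantile(v, 0.75)))

  expect_error(label_summary(numeric(0)), "non-empty")
})

test_that("distribution comparison uses the score range as the diversity verdict", {
  same <- compare_distributions(c(1, 3, 7), c(1, 3, 7))
  expect_equal(same$real$length, same$gen$length)
  expect_identical(same$verdict, "diverse-and-real")

  sup <- compare_distributions(c(2, 3), c(1, 5))
  expect_gte(sup$gen$length, sup$real$length)
  expect_identical(sup$verdict, "diverse-and-real")

  under <- compare_distributions(c(0, 10), c(4, 5))
  expect_identical(under$verdict, "under-dispersed")
})

test_that("epoch selection minimizes the normalized label distance with ties to the smallest epoch", {
  real <- c(13.8, 15.2, 17.4, 18.8, 19.5, 20.3, 21.1, 16.6)
  exact <- real
  off <- real + 2

  arch <- stub_archive(list(`100` = off, `200` = exact, `300` = off), divisor = 1)
  sel <- select_epoch(arch, real, remove_outliers = FALSE)
  expect_identical(sel$chosen, 200L)
  expect_equal(min(sel$table$distance), 0, tolerance = 1e-12)

  # tie between identical checkpoints resolves to the smaller epoch
  arch2 <- stub_archive(list(`1400` = exact, `1800` = exact), divisor = 1)
  expect_identical(select_epoch(arch2, real, remove_outliers = FALSE)$chosen, 1400L)

  # adding a strictly worse checkpoint never changes the selection
  arch3 <- stub_archive(list(`100` = exact, `500` = real + 50), divisor = 1)
  expect_identical(select_epoch(arch3, real, remove_outliers = FALSE)$chosen, 100L)

  # listing order does not matter
  arch4 <- stub_archive(list(`300` = off, `200` = exact, `100` = off), divisor = 1)
  expect_identical(select_epoch(arch4, real, remove_outliers = FALSE)$chosen, 200L)

  expect_error(select_epoch(arch, real, candidate_epochs = integer(0)), "No candidate")
  expect_error(select_epoch(arch, numeric(0)), "non-empty")
  expect_error(select_epoch(arch, real, candidate_epochs = 999), "No checkpoint")
})

test_that("epoch selection unscales generated labels with the archive divisor", {
  real <- c(1.1, 1.3, 1.2, 1.45, 1.5, 1.02)
  arch <- stub_archive(list(`100` = real, `200` = real + 0.4), divisor = 10)
  sel <- select_epoch(arch, real, remove_outliers = FALSE)
  expect_identical(sel$chosen, 100L)
  expect_equal(sel$table$mean[sel$table$epoch == 100], mean(real), tolerance = 1e-12)
})

test_that("archive evaluation reports per-epoch diversity and the chosen epoch", {
  joint <- small_joint(n = 8)
  arch <- train_gan(joint, fast_gan_config())
  ev <- evaluate_archive(arch, joint)
  expect_identical(nrow(ev), 3L)
  expect_true(all(c("epoch", "pc1_contribution_gen", "real_length",
                    "gen_length", "verdict", "distance") %in% names(ev)))
  expect_true(attr(ev, "chosen_epoch") %in% ev$epoch)
  expect_true(attr(ev, "pc1_contribution_real") > 0 &&
              attr(ev, "pc1_contribution_real") <= 1)
})
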