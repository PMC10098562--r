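#' Build a training-set expansion plan
#'
#' For each requested count `n` in `n_list`, the plan samples `n`
#' generated rows uniformly without replacement from a pool of
#' `pool_size` rows, to be appended to the `n_real` real training rows.
#' The default `n_list` reproduces the study's expansion ladder
#' (30, 45, 60, 90, 150, 270 total training samples from
#' `n = 0, 15, 30, 60, 120, 240`). Sampling is reproducible under `seed`.
#'
#' @param n_real Number of real training rows (default 30).
#' @param pool_size Number of rows available in the generated pool.
#' @param n_list Counts of generated rows to add.
#' @param seed Integer seed.
#' @return An `expansion_plan`: list with `entries` (tibble of `n_added`,
#'   `train_size` and list-column `pool_rows`) and the inputs.
#' @export
build_expansion_plan <- function(n_real = 30, pool_size,
                                 n_list = c(0, 15, 30, 60, 120, 240),
                                 seed = 1L) {
  n_real <- assert_count(n_real, "n_real", min = 1L)
  pool_size <- assert_count(pool_size, "pool_size", min = 0L)
  if (any(n_list < 0) || any(n_list != trunc(n_list))) {
    abort("`n_list` must contain non-negative integers.")
  }
  if (max(n_list) > pool_size) {
    abort(sprintf("Cannot draw %d rows from a pool of %d.", max(n_list), pool_size))
  }
  seeds <- derive_seeds(seed, length(n_list))
  entries <- tibble(
    n_added = as.integer(n_list),
    train_size = n_real + as.integer(n_list),
    pool_rows = purrr::map2(n_list, seeds, function(n, s) {
      if (n == 0) integer(0) else sort(with_seed(s, sample.int(pool_size, n)))
    }))
  structure(list(entries = entries, n_real = n_real,
                 pool_size = pool_size, seed = as.integer(seed)),
            class = "expansion_plan")
}

#' @export
print.expansion_plan <- function(x, ...) {
  cat(sprintf("<expansion_plan> %d real + n in {%s} from a pool of %d\n",
              x$n_real, paste(x$entries$n_added, collapse = ", "), x$pool_size))
  invisible(x)
}

#' Run the training-set expansion experiment
#'
#' For every plan entry and every augmentation pool, trains a fresh CNN on
#' the real training rows plus the sampled generated rows and evaluates it
#' on the fixed validation set. With `repeats > 1`, each configuration is
#' retrained under distinct derived seeds and the metrics are reported as
#' mean and standard deviation; the validation set is identical (checked
#' by digest) across all entries.
#'
#' @param plan An [build_expansion_plan()] result.
#' @param real_x,real_y Real training spectra (matrix/tibble) and labels
#'   in g/kg.
#' @param val_x,val_y Fixed validation spectra and labels in g/kg.
#' @param pools Named list of augmentation pools, e.g.
#'   `list(GAN = list(x = , y = ), EMSA = list(x = , y = ))`; `x` rows are
#'   spectra (same width as `real_x`) and `y` labels in g/kg.
#' @param config A [cnn_config()]; its seed is re-derived per repeat.
#' @param divisor Label divisor passed to [train_regressor()] so the CNN
#'   trains on the scaled representation (metrics stay in g/kg).
#' @param repeats Training repetitions per configuration.
#' @param variant R^2 variant for [compute_metrics()].
#' @return An `expansion_result`: tibble of per-entry metrics with the
#'   best entry recorded in attributes.
#' @export
run_expansion <- function(plan, real_x, real_y, val_x, val_y, pools,
                          config = cnn_config(), divisor = NULL,
                          repeats = 1L, variant = "standard") {
  repeats <- assert_count(repeats, "repeats", min = 1L)
  if (is.null(names(pools)) || any(names(pools) == "")) {
    abort("`pools` must be a named list (e.g. GAN, EMSA).")
  }
  real_x <- regressor_matrix(real_x); val_x <- regressor_matrix(val_x)
  if (nrow(real_x) != plan$n_real) {
    abort(sprintf("`real_x` has %d rows; plan expects %d.", nrow(real_x), plan$n_real))
  }
  val_digest <- digest_matrix(cbind(val_x, as.numeric(val_y)))
  rep_seeds <- derive_seeds(plan$seed + 1L, repeats)

  rows <- list()
  for (aug in names(pools)) {
    pool <- pools[[aug]]
    pool_x <- regressor_matrix(pool$x)
    if (ncol(pool_x) != ncol(real_x)) abort("Pool width does not match real data width.")
    if (nrow(pool_x) < plan$pool_size) {
      abort(sprintf("Pool `%s` has %d rows; plan expects at least %d.",
                    aug, nrow(pool_x), plan$pool_size))
    }
    for (i in seq_len(nrow(plan$entries))) {
      entry <- plan$entries[i, ]
      idx <- entry$pool_rows[[1L]]
      tx <- rbind(real_x, pool_x[idx, , drop = FALSE])
      ty <- c(as.numeric(real_y), as.numeric(pool$y)[idx])
      per_rep <- purrr::map_dfr(rep_seeds, function(s) {
        cfg <- config; cfg$seed <- s
        fit <- train_regressor(tx, ty, config = cfg, divisor = divisor)
        compute_metrics(as.numeric(val_y), predict(fit, val_x), variant = variant)
      })
      rows[[length(rows) + 1L]] <- tibble(
        augmenter = aug, n_added = entry$n_added, train_size = entry$train_size,
        r2_mean = mean(per_rep$r2), r2_sd = if (repeats > 1L) sd(per_rep$r2) else 0,
        rmse_mean = mean(per_rep$rmse), rmse_sd = if (repeats > 1L) sd(per_rep$rmse) else 0,
        repeats = repeats, val_digest = val_digest)
    }
  }
  out <- dplyr::bind_rows(rows)
  best <- out[order(-out$r2_mean, out$rmse_mean, out$n_added,
                    match(out$augmenter, names(pools))), ][1L, ]
  structure(out,
            best = best, variant = variant,
            class = c("expansion_result", class(out)))
}

#' @describeIn run_expansion The result table as a plain tibble.
#' @param x An `expansion_result`.
#' @param ... Unused.
#' @exportS3Method
tidy.expansion_result <- function(x, ...) {
  out <- x
  attr(out, "best") <- NULL
  attr(out, "variant") <- NULL
  class(out) <- class(tibble())
  out
}

#' @describeIn run_expansion One-row summary: the best configuration
#'   (highest mean validation R^2; ties broken by lower RMSE, then
#'   smaller n).
#' @exportS3Method
glance.expansion_result <- function(x, ...) {
  best <- attr(x, "best")
  tibble(best_augmenter = best$augmenter, best_n_added = best$n_added,
         best_train_size = best$train_size,
         best_r2 = best$r2_mean, best_rmse = best$rmse_mean,
         variant = attr(x, "variant"))
}

#' Refine the augmentation interval around a promising count
#'
#' After the coarse expansion ladder identifies the best count of added
#' generated samples, the interval is narrowed: by default the candidates
#' are `center - step, center, center + step, center + 2*step,
#' center + 3*step`, clipped at 0 (step 5 around 30 gives
#' 25, 30, 35, 40, 45; step 10 around 60 gives 50, 60, 70, 80, 90).
#'
#' @param center_n The promising count from the coarse run.
#' @param step Step size (5 or 10 in the study design).
#' @return Sorted unique non-negative counts.
#' @export
refine_interval <- function(center_n, step = 5) {
  center_n <- assert_count(center_n, "center_n", min = 0L)
  step <- assert_count(step, "step", min = 1L)
  sort(unique(pmax(0L, center_n + step * c(-1L, 0L, 1L, 2L, 3L))))
}
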