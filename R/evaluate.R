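#' First-principal-component reduction
#'
#' Centers the data and projects it onto the leading eigenvector of the
#' covariance matrix. The contribution rate is the fraction of total
#' variance carried by that component, `lambda_1 / sum(lambda)` - the
#' quantity used to compare generated and real spectra. The loading sign
#' is fixed so that its largest-magnitude element is positive, making
#' scores reproducible across linear-algebra backends.
#'
#' @param x A numeric matrix (rows are samples), spectra tibble or
#'   `joint_tbl`.
#' @return A `pc1_summary`: list with `scores` (zero-mean, one per
#'   sample), `contribution` (in (0, 1]), and the unit `loading` vector.
#' @export
pc1_reduce <- function(x) {
  mat <-
    if (is.matrix(x)) x
    else if (inherits(x, "joint_tbl")) joint_matrix(x)
    else spectra_matrix(x)
  if (nrow(mat) < 2L) abort("PCA needs at least 2 samples.")
  centered <- sweep(mat, 2L, colMeans(mat), "-")
  sv <- svd(centered, nu = 1L, nv = 1L)
  if (sum(sv$d^2) < 1e-24) abort("Zero total variance: all samples identical.")
  loading <- sv$v[, 1L]
  flip <- sign(loading[which.max(abs(loading))])
  if (flip == 0) flip <- 1
  loading <- loading * flip
  scores <- as.numeric(centered %*% loading)
  structure(list(scores = scores,
                 contribution = sv$d[1L]^2 / sum(sv$d^2),
                 loading = loading),
            class = "pc1_summary")
}

#' @export
print.pc1_summary <- function(x, ...) {
  cat(sprintf("<pc1_summary> %d scores, PC1 contribution %.2f%%\n",
              length(x$scores), 100 * x$contribution))
  invisible(x)
}

#' @describeIn pc1_reduce Scores as a tibble.
#' @param x A `pc1_summary`.
#' @param ... Unused.
#' @exportS3Method
tidy.pc1_summary <- function(x, ...) {
  tibble(sample = seq_along(x$scores), score = x$scores)
}

#' @describeIn pc1_reduce One-row summary with the contribution rate and
#'   score range (the "violin length" diversity proxy).
#' @exportS3Method
glance.pc1_summary <- function(x, ...) {
  tibble(contribution = x$contribution,
         score_min = min(x$scores), score_max = max(x$scores),
         length = diff(range(x$scores)))
}

#' Distribution summary of a score or label set
#'
#' Order statistics (minimum, linear-interpolation quartiles, median,
#' maximum), mean, standard deviation and the range (`length`, the
#' diversity proxy: a generated set whose score range covers the real
#' range is at least as diverse). Optionally removes outliers outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` before summarizing, as done when
#' comparing generated nutrient labels with real ones.
#'
#' @param values Non-empty numeric vector.
#' @param remove_outliers Apply the 1.5 x IQR rule first.
#' @return A one-row tibble: `n`, `n_removed`, `min`, `q1`, `median`,
#'   `mean`, `q3`, `max`, `sd`, `length`.
#' @export
label_summary <- function(values, remove_outliers = FALSE) {
  if (length(values) == 0L || anyNA(values)) abort("`values` must be non-empty with no NA.")
  n0 <- length(values)
  if (remove_outliers) {
    q <- quantile(values, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
    values <- values[keep]
    if (length(values) == 0L) abort("All values removed as outliers.")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  tibble(n = length(values), n_removed = n0 - length(values),
         min = min(values), q1 = q[1], median = q[2], mean = mean(values),
         q3 = q[3], max = max(values),
         sd = if (length(values) > 1L) sd(values) else 0,
         length = max(values) - min(values))
}

#' Compare real and generated score distributions
#'
#' Computes [label_summary()] rows for both sets and a diversity verdict:
#' `"diverse-and-real"` when the generated range (max - min) is at least
#' as long as the real one, `"under-dispersed"` otherwise.
#'
#' @param real_scores,gen_scores Non-empty numeric vectors (e.g. PC1
#'   scores from a joint PCA fit).
#' @return A list with tibbles `real`, `gen`, and `verdict`.
#' @export
compare_distributions <- function(real_scores, gen_scores) {
  real <- label_summary(real_scores)
  gen <- label_summary(gen_scores)
  list(real = real, gen = gen,
       verdict = if (gen$length >= real$length) "diverse-and-real" else "under-dispersed")
}

#' Select the GAN checkpoint closest to the real label distribution
#'
#' For each candidate checkpoint the generated labels are unscaled to
#' g/kg (outliers optionally removed by the 1.5 x IQR rule) and compared
#' with the real labels through a normalized L1 distance over the three
#' summary statistics mean, median and standard deviation:
#'
#'   `distance = sum_stat |stat_gen - stat_real| / sd(real)`
#'
#' The checkpoint minimizing the distance is chosen; ties go to the
#' smallest epoch. This formalizes the visual boxplot comparison used to
#' pick the best epoch per nutrient.
#'
#' @param archive A `gan_archive`.
#' @param real_labels Real nutrient values in g/kg.
#' @param candidate_epochs Epochs to consider (default: all non-zero
#'   checkpoints).
#' @param remove_outliers Apply the IQR rule to generated labels first.
#' @return An `epoch_selection`: list with `table` (per-epoch tibble of
#'   statistics and distance) and `chosen` epoch.
#' @export
select_epoch <- function(archive, real_labels, candidate_epochs = NULL,
                         remove_outliers = TRUE) {
  if (length(real_labels) == 0L) abort("`real_labels` must be non-empty.")
  eps <- candidate_epochs %||% archive_epochs(archive)
  if (length(eps) == 0L) abort("No candidate epochs.")
  eps <- sort(as.integer(eps))
  missing <- setdiff(as.character(eps), names(archive$checkpoints))
  if (length(missing)) abort(sprintf("No checkpoint at epoch(s): %s", paste(missing, collapse = ", ")))
  real_stats <- label_summary(real_labels)
  scale <- real_stats$sd
  if (scale <= 0) abort("Real labels have zero spread; distance is undefined.")
  tab <- purrr::map_dfr(eps, function(ep) {
    mat <- archive$checkpoints[[as.character(ep)]]
    labs <- unscale_labels(mat[, ncol(mat)], divisor = archive$divisor %||% 1)
    s <- label_summary(labs, remove_outliers = remove_outliers)
    dplyr::mutate(s, epoch = ep,
                  distance = (abs(mean - real_stats$mean) +
                              abs(median - real_stats$median) +
                              abs(sd - real_stats$sd)) / scale,
                  .before = 1L)
  })
  chosen <- tab$epoch[order(tab$distance, tab$epoch)][1L]
  structure(list(table = tab, chosen = chosen, real = real_stats),
            class = "epoch_selection")
}

#' @export
print.epoch_selection <- function(x, ...) {
  cat(sprintf("<epoch_selection> chosen epoch %d (distance %.4f) of %d candidates\n",
              x$chosen, x$table$distance[x$table$epoch == x$chosen][1L],
              nrow(x$table)))
  invisible(x)
}

#' @describeIn select_epoch Per-epoch statistics and distances.
#' @param x An `epoch_selection`.
#' @param ... Unused.
#' @exportS3Method
tidy.epoch_selection <- function(x, ...) x$table

#' @describeIn select_epoch One-row summary with the chosen epoch.
#' @exportS3Method
glance.epoch_selection <- function(x, ...) {
  best <- x$table[x$table$epoch == x$chosen, ]
  tibble(chosen_epoch = x$chosen, distance = best$distance[1L],
         n_candidates = nrow(x$table))
}

#' Evaluate every checkpoint of an archive against real data
#'
#' Produces the per-epoch evaluation table: PC1 contribution of the
#' generated spectra (fitted per dataset), the generated and real score
#' ranges from a joint PCA fit (shared coordinate system), the diversity
#' verdict, and the label-distance used for epoch selection.
#'
#' @param archive A `gan_archive`.
#' @param real_joint The real `joint_tbl` the GAN was trained on.
#' @param remove_outliers Apply the IQR rule to generated labels.
#' @return A tibble with one row per non-zero checkpoint.
#' @export
evaluate_archive <- function(archive, real_joint, remove_outliers = TRUE) {
  real_mat <- joint_matrix(real_joint)[, -archive$width, drop = FALSE]
  real_pc1 <- pc1_reduce(real_mat)
  meta <- joint_meta(real_joint)
  real_labels <- unscale_labels(split_joint(real_joint)$labels,
                                divisor = meta$divisor %||% archive$divisor %||% 1)
  sel <- select_epoch(archive, real_labels, remove_outliers = remove_outliers)
  diversity <- purrr::map_dfr(archive_epochs(archive), function(ep) {
    gen_mat <- archive$checkpoints[[as.character(ep)]][, -archive$width, drop = FALSE]
    pooled <- pc1_reduce(rbind(real_mat, gen_mat))
    r_scores <- pooled$scores[seq_len(nrow(real_mat))]
    g_scores <- pooled$scores[-seq_len(nrow(real_mat))]
    cmp <- compare_distributions(r_scores, g_scores)
    tibble(epoch = ep,
           pc1_contribution_gen = pc1_reduce(gen_mat)$contribution,
           real_length = cmp$real$length, gen_length = cmp$gen$length,
           verdict = cmp$verdict)
  })
  out <- dplyr::left_join(diversity,
                          dplyr::select(sel$table, "epoch", "distance",
                                        label_mean = "mean", label_median = "median",
                                        label_sd = "sd"),
                          by = "epoch")
  attr(out, "chosen_epoch") <- sel$chosen
  attr(out, "pc1_contribution_real") <- real_pc1$contribution
  out
}
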