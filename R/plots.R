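#' Plot spectra
#'
#' Line plot of reflectance against wavelength, one line per sample.
#'
#' @param spectra A spectra tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, alpha = 0.5) {
  validate_spectra(spectra)
  long <- tidyr::pivot_longer(spectra, -"sample_id",
                              names_to = "wavelength", values_to = "reflectance")
  long$wavelength <- as.numeric(long$wavelength)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength, y = .data$reflectance,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' Violin comparison of real and generated PC1 scores
#'
#' Fits one PCA on the concatenation of real and generated spectra so the
#' scores share a coordinate system, then draws side-by-side violins. The
#' violin length (score range) is the diversity proxy: generated data at
#' least as long as the real data indicate sufficient diversity.
#'
#' @param real,generated Numeric matrices or spectra tibbles.
#' @return A ggplot object.
#' @export
plot_score_violin <- function(real, generated) {
  real_mat <- if (is.matrix(real)) real else spectra_matrix(real)
  gen_mat <- if (is.matrix(generated)) generated else spectra_matrix(generated)
  pooled <- pc1_reduce(rbind(real_mat, gen_mat))
  df <- tibble(set = rep(c("real", "generated"), c(nrow(real_mat), nrow(gen_mat))),
               score = pooled$scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$score, fill = .data$set)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "PC1 score") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @describeIn select_epoch Line plot of the label distance per epoch
#'   with the chosen epoch marked.
#' @param object An `epoch_selection`.
#' @exportS3Method
autoplot.epoch_selection <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$epoch, y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "normalized label distance") +
    ggplot2::theme_minimal()
}

#' @describeIn run_expansion Validation metrics against the number of
#'   added generated samples, one line per augmenter.
#' @param object An `expansion_result`.
#' @exportS3Method
autoplot.expansion_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("r2_mean", "rmse_mean"),
                            names_to = "metric", values_to = "value")
  df$metric <- ifelse(df$metric == "r2_mean", "validation R²", "validation RMSE")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_added, y = .data$value,
                                   colour = .data$augmenter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "generated samples added", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn train_gan Adversarial loss traces over training.
#' @param object A `gan_archive`.
#' @exportS3Method
autoplot.gan_archive <- function(object, ...) {
  df <- tidyr::pivot_longer(object$loss, c("loss_d", "loss_g"),
                            names_to = "network", values_to = "loss")
  df$network <- ifelse(df$network == "loss_d", "discriminator", "generator")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$network)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "epoch", y = "least-squares loss", colour = NULL) +
    ggplot2::theme_minimal()
}
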