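#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-taxon association evidence
#'
#' Manhattan-style plot of `-log10` adjusted p-values per taxon for the
#' combined (or single) test of an [ldm_surv()] fit, with detected taxa
#' highlighted.
#'
#' @param object An `ldm_surv_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ldm_surv_fit
#' @export
autoplot.ldm_surv_fit <- function(object, ...) {
  taxa <- if (!is.null(object$combined)) object$combined$taxa else
    object$tests[[1]]$taxa
  df <- dplyr::mutate(taxa, index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p_adj),
                                   colour = .data$detected)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(object$fdr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "taxon", y = expression(-log[10]~adjusted~italic(p)),
                  colour = sprintf("detected (q = %g)", object$fdr)) +
    ggplot2::theme_minimal()
}

#' Plot the Cox-model residuals used as regressors
#'
#' Side-by-side histograms of the Martingale and deviance residuals, the
#' two candidate regressors of the survival LDM.  The deviance transform
#' symmetrizes the left-skewed Martingale residual.
#'
#' @param fit An `ldm_surv_fit` or `survldm_coxfit`-bearing object with a
#'   `residuals` tibble.
#' @return A ggplot object.
#' @export
plot_residuals <- function(fit) {
  stopifnot(!is.null(fit$residuals))
  df <- tidyr::pivot_longer(fit$residuals, dplyr::everything(),
                            names_to = "residual", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~ .data$residual, scales = "free_x") +
    ggplot2::labs(x = "residual", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report
#'
#' Bar chart of rejection fractions (type I error or power) or of
#' sensitivity / empirical FDR per method, with Monte-Carlo error bars.
#'
#' @param object An `experiment_report` from [run_type1()],
#'   [run_power()] or [run_fdr_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if ("rejection" %in% names(df)) {
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$rejection)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rejection - .data$se,
                                          ymax = .data$rejection + .data$se),
                             width = 0.2) +
      ggplot2::geom_hline(yintercept = df$alpha[1], linetype = "dashed") +
      ggplot2::labs(y = "rejection fraction")
  } else {
    long <- tidyr::pivot_longer(df, c("sensitivity", "fdr"),
                                names_to = "measure", values_to = "value")
    gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::facet_wrap(~ .data$measure) +
      ggplot2::geom_hline(data = data.frame(measure = "fdr", q = df$q[1]),
                          ggplot2::aes(yintercept = .data$q), linetype = "dashed")
  }
  gg + ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
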