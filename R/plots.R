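#' Channel-mean log-power spectra of the study conditions
#'
#' @param report A [study_report()].
#' @param xlim Frequency range shown, Hz.
#' @return A ggplot object.
#' @export
plot_condition_spectra <- function(report, xlim = c(0, 15)) {
  df <- report$spectra
  df <- df[df$freq >= xlim[1] & df$freq <= xlim[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$log10_power,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(log[10] ~ "power (T"^2 * "/Hz)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Band RMSE across a parameter sweep
#'
#' Bar chart of the three band RMSEs per parameter value, with the
#' uncleaned DSMW baseline as a dashed reference line per band.
#'
#' @param sweep A [sweep_method()] result.
#' @return A ggplot object.
#' @export
plot_rmse_sweep <- function(sweep) {
  df <- tibble::tibble(
    value = factor(rep(sweep$values, each = 3), levels = sweep$values),
    band = rep(rownames(sweep$rmse), length(sweep$values)),
    rmse = as.vector(sweep$rmse)
  )
  base <- tibble::tibble(band = rownames(sweep$rmse),
                         baseline = sweep$baseline)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$baseline),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = sprintf("%s (%s)", sweep$parameter_name,
                              sweep$method),
                  y = "RMSE vs reference") +
    ggplot2::theme_minimal()
}
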