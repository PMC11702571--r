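#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_ribbon geom_hline labs position_dodge
#'   scale_x_continuous theme_minimal
NULL

#' Plot a power study as grouped bars with binomial error bars
#'
#' @param object A `power_study` tibble from [run_power_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_study <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object)),
    cols = c("power_prs", "power_pprs", "power_npprs"),
    names_to = "test", names_prefix = "power_", values_to = "power")
  long$se <- dplyr::case_when(
    long$test == "prs" ~ long$se_prs,
    long$test == "pprs" ~ long$se_pprs,
    TRUE ~ long$se_npprs)
  long$test <- factor(long$test, levels = c("pprs", "prs", "npprs"),
                      labels = c("pPRS x E", "PRS x E", "npPRS x E"))
  ggplot(long, aes(x = factor(.data$scenario_id), y = .data$power,
                   fill = .data$test)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$power - .data$se,
                      ymax = .data$power + .data$se),
                  position = position_dodge(width = 0.8), width = 0.25) +
    labs(x = "Scenario", y = "Rejection proportion", fill = NULL) +
    theme_minimal()
}

#' Plot the exposure odds ratio across score percentiles
#'
#' @param object An `or_profile` tibble from [exposure_or_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.or_profile <- function(object, ...) {
  has_ci <- all(is.finite(object$conf.low))
  p <- ggplot(object, aes(x = .data$percentile, y = .data$or)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    geom_line() + geom_point() +
    scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    labs(x = "Score percentile", y = "Exposure odds ratio") +
    theme_minimal()
  if (has_ci) {
    p <- p + geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         alpha = 0.2)
  }
  p
}

#' Manhattan-style plot of a marginal scan
#'
#' @param scan A tibble from [marginal_scan()].
#' @param threshold Discovery threshold drawn as a horizontal line.
#' @return A ggplot.
#' @export
plot_scan <- function(scan, threshold = 5e-5) {
  scan$index <- seq_len(nrow(scan))
  ggplot(scan, aes(x = .data$index, y = -log10(.data$p.value))) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = -log10(threshold), colour = "red",
               linetype = "dashed") +
    labs(x = "SNP index", y = expression(-log[10](p))) +
    theme_minimal()
}
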