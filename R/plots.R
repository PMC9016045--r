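#' Diagnostic plots
#'
#' ggplot2 renderings of the four standard result views: AUROC as a function
#' of SUV percentile, the ROC curve with its Youden operating point, patient
#' maximum SUV_OPT\% dichotomized by irAE status, and a longitudinal series
#' against the normative grey band with the clinical detection date.
#'
#' @param selection a [BiomarkerSelection-class].
#' @param curve a data.frame from [rocCurve()].
#' @param cutoff a [CutoffResult-class].
#' @param scores dichotomized scores from [scoresAtOptimum()].
#' @param series data.frame (scan_day, value).
#' @param range a [NormalRange-class].
#' @param clinical_day optional clinical detection day.
#' @param organ organ name used in titles.
#' @param p_value optional Wilcoxon p-value to annotate the strip plot.
#' @return A ggplot object.
#' @name result-plots
NULL

#' @rdname result-plots
#' @export
plotAurocByPercentile <- function(selection) {
  df <- selection@scan
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile, y = .data$auroc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = selection@opt_percentile,
                        linetype = "dashed") +
    ggplot2::labs(x = "SUV percentile (%)", y = "AUROC",
                  title = sprintf("%s: optimum SUV_%g%% (AUROC %.2f)",
                                  selection@organ, selection@opt_percentile,
                                  selection@auroc)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_bw()
}

#' @rdname result-plots
#' @export
plotRocCurve <- function(curve, cutoff, organ = cutoff@organ) {
  df <- curve[order(1 - curve$specificity, curve$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = 1 - cutoff@specificity,
                      y = cutoff@sensitivity, colour = "red", size = 3) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("%s ROC: T_opt %.2f g/mL (J = %.2f)",
                                  organ, cutoff@t_opt, cutoff@j)) +
    ggplot2::theme_bw()
}

#' @rdname result-plots
#' @export
plotDichotomized <- function(scores, organ, p_value = NA_real_) {
  scores$status <- factor(ifelse(scores$irae == 1, "AE", "NC"),
                          levels = c("NC", "AE"))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$status, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "max SUV_OPT% (g/mL)",
                  title = sprintf("%s%s", organ,
                                  if (is.na(p_value)) "" else
                                    sprintf(" (Wilcoxon p = %.3g)",
                                            p_value))) +
    ggplot2::theme_bw()
}

#' @rdname result-plots
#' @export
plotLongitudinal <- function(series, range, clinical_day = NA_real_,
                             organ = range@organ) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$scan_day,
                                            y = .data$value)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = range@lo,
                      ymax = range@hi, alpha = 0.25, fill = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Days from treatment start", y = "SUV_OPT% (g/mL)",
                  title = organ) +
    ggplot2::theme_bw()
  if (!is.na(clinical_day))
    p <- p + ggplot2::geom_vline(xintercept = clinical_day,
                                 linetype = "dashed")
  p
}
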