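# ggplot2 visualisations for trial results and the tilt sweep.

#' @describeIn run_trial Boxplots of the four deviation metrics by screw
#'   type, faceted per metric, with perforated screws highlighted.
#' @param object An `si_trial`.
#' @export
autoplot.si_trial <- function(object, ...) {
  long <- object$screws |>
    tidyr::pivot_longer(
      cols = c("mld_mm", "entry_dev_mm", "central_aim_dev_mm",
               "angular_dev_deg"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = factor(.data$metric, levels = c(
      "mld_mm", "entry_dev_mm", "central_aim_dev_mm", "angular_dev_deg"
    ), labels = c("MLD (mm)", "Entry deviation (mm)",
                  "Central-aim deviation (mm)", "Angular deviation (deg)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$screw_type, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$perforated),
                         width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Screw type", y = NULL, colour = "Perforated",
                  title = "In-silico screw placement deviations") +
    ggplot2::theme_minimal()
}

#' @describeIn symphysis_tilt_experiment Correct-placement rate of S1 and
#'   S2 screws as a function of the anterior symphysis marking bias.
#' @param object An `si_tilt`.
#' @export
autoplot.si_tilt <- function(object, ...) {
  long <- object$sweep |>
    dplyr::select("bias_mm", "s1_correct_rate", "s2_correct_rate") |>
    tidyr::pivot_longer(cols = c("s1_correct_rate", "s2_correct_rate"),
                        names_to = "screw_type", values_to = "correct_rate") |>
    dplyr::mutate(screw_type = ifelse(.data$screw_type == "s1_correct_rate",
                                      "S1", "S2"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bias_mm,
                                     y = .data$correct_rate,
                                     colour = .data$screw_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Anterior symphysis bias (mm)",
                  y = "Correct-placement rate", colour = "Screw",
                  title = "Registration-plane tilt: wide S1 tolerates more symphysis bias than narrow S2") +
    ggplot2::theme_minimal()
}
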