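# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_rect geom_point
#'   geom_vline facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated trial
#'
#' All channels against time, with ground-truth transition intervals shaded.
#'
#' @param object A `sensor_trial`.
#' @param channels Channels to show (default: knee, thigh gyro, heel force).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensor_trial <- function(object,
                                  channels = c("knee_deg", "thigh_gyro_p",
                                               "heel_n"), ...) {
  df <- as_tibble(object) %>% filter(.data$channel %in% channels)
  tr <- object$transitions
  p <- ggplot(df, aes(x = .data$time_s, y = .data$value))
  if (nrow(tr)) {
    shade <- tibble::tibble(xmin = tr$onset / object$sample_rate,
                            xmax = tr$offset / object$sample_rate,
                            direction = tr$direction)
    p <- p + geom_rect(data = shade,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -Inf, ymax = Inf, fill = .data$direction),
                       alpha = 0.2, inherit.aes = FALSE)
  }
  p + geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time [s]", y = NULL,
         title = sprintf("subject %d, activity %d", object$subject_id,
                         object$activity_id)) +
    theme_minimal()
}

#' Plot a detection outcome
#'
#' Stage-1 sitting decisions, gated stage-2 scores and emitted detections
#' over trial time, with the true transition intervals shaded.
#'
#' @param object A `detection_outcome`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detection_outcome <- function(object, ...) {
  ep <- object$epochs
  df <- tibble::tibble(
    time_s = rep(ep$time_s, 2),
    value = c(as.numeric(ep$stage1_sit),
              ifelse(is.na(ep$stage2_score), NA, ep$stage2_score)),
    series = rep(c("stage 1: sitting", "stage 2: score"), each = nrow(ep)))
  p <- ggplot(df, aes(x = .data$time_s, y = .data$value))
  tr <- object$truth
  if (!is.null(tr) && nrow(tr)) {
    shade <- tibble::tibble(xmin = tr$onset / object$sample_rate,
                            xmax = tr$offset / object$sample_rate,
                            direction = tr$direction)
    p <- p + geom_rect(data = shade,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -Inf, ymax = Inf, fill = .data$direction),
                       alpha = 0.2, inherit.aes = FALSE)
  }
  if (nrow(object$detections))
    p <- p + geom_vline(xintercept = object$detections$time_s,
                        linetype = "dashed", colour = "red")
  p + geom_line(na.rm = TRUE) +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "time [s]", y = NULL) + theme_minimal()
}

#' Plot a leave-one-subject-out lag sweep
#'
#' Epoch-level rates against the number of lagged epochs.
#'
#' @param object A `loso_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loso_result <- function(object, ...) {
  df <- object$summary %>%
    select("lag", "tpr", "tnr", "accuracy", "f1") %>%
    tidyr::pivot_longer(-"lag", names_to = "metric")
  ggplot(df, aes(x = .data$lag, y = .data$value, colour = .data$metric)) +
    geom_line() + geom_point() +
    labs(x = "lagged epochs k", y = "rate",
         title = sprintf("LOSO evaluation (%s)", object$classifier)) +
    theme_minimal()
}
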