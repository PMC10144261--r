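# ggplot2 views of the result objects.

#' @describeIn threshold_sweep Autoplot method: retained unique variant
#'   peptides and variant sites against the score cutoff.
#' @param object An `sva_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.sva_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"cutoff",
                              names_to = "metric", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$n,
                                     colour = .data$metric)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Score cutoff", y = "Retained count", colour = NULL,
                  title = "Score-cutoff sweep") +
    ggplot2::theme_minimal()
}

#' @describeIn triage_run Autoplot method: how often each triage rule fired.
#' @param object An `sva_triage` object.
#' @param ... Unused.
#' @export
autoplot.sva_triage <- function(object, ...) {
  fired <- unlist(strsplit(object$annotations$triggered_rules, ";", fixed = TRUE))
  fired <- fired[nzchar(fired)]
  counts <- tibble(rule = factor(fired, levels = TRIAGE_RULES)) |>
    dplyr::count(.data$rule, .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$rule, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "PSMs flagged",
                  title = "Triage rule triggers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn simulate_acquisition Autoplot method: reported-intensity XIC
#'   traces per species, gated scans marked.
#' @param object An `sva_acquisition` tibble.
#' @param ... Unused.
#' @export
autoplot.sva_acquisition <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$intensity,
                               colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = function(d) d[d$gated, ], shape = 4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (s)", y = "Reported intensity (ions/s)",
                  colour = "Species",
                  title = "Simulated XIC traces (x = gated scan)") +
    ggplot2::theme_minimal()
}
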