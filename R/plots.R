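#' Plot a Q-mer pore model
#'
#' Median current per Q-mer, sorted by level, with the per-Q-mer standard
#' deviation as a ribbon when present. The near-continuous ramp and the large
#' overlap of neighbouring levels is what makes distinct Q-mers confusable and
#' motivates quantizing to a few levels.
#'
#' @param model A [qmer_model].
#' @param cfg Optional `quantizer_config`; thresholds are drawn as horizontal
#'   lines.
#' @return A ggplot.
#' @export
plot_qmer_model <- function(model, cfg = NULL) {
  d <- model |>
    arrange(.data$current) |>
    mutate(rank = row_number())
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$current))
  if (any(is.finite(d$sd))) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$current - .data$sd,
                   ymax = .data$current + .data$sd),
      fill = "grey80")
  }
  gg <- gg + ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%d-mers, sorted by median current", qmer_q(model)),
                  y = "median current (pA)")
  if (!is.null(cfg) && length(cfg$thresholds) > 0) {
    gg <- gg + ggplot2::geom_hline(yintercept = cfg$thresholds,
                                   linetype = "dashed", colour = "firebrick")
  }
  gg
}

#' Plot planted versus called SV positions
#'
#' @param benchmark An `sv_benchmark` from [evaluate_sv_calls()].
#' @return A ggplot of call and truth intervals by type; matched pairs share a
#'   connecting segment.
#' @export
plot_sv_benchmark <- function(benchmark) {
  calls <- mutate(benchmark$calls, set = "calls")
  truth <- mutate(benchmark$truth, set = "truth")
  d <- bind_rows(calls, truth)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start, xend = pmax(.data$end, .data$start + .data$length),
                                  y = .data$set, yend = .data$set,
                                  colour = .data$svtype)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = NULL)
}
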