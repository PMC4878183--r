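#' @export
autoplot.channel_stack <- function(object, channels = channel_names(object),
                                   downsample = 1, ...) {
  dfs <- purrr::map_dfr(channels, function(ch) {
    m <- get_channel(object, ch)
    if (downsample > 1) {
      m <- m[seq(1, nrow(m), by = downsample), seq(1, ncol(m), by = downsample)]
    }
    tibble::tibble(channel = ch,
                   row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   intensity = as.vector(m))
  })
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "AFU") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Condition comparison plot for per-cell measurements
#'
#' Jittered per-cell values by condition with median and interquartile bars —
#' the honest display for the heterogeneous, non-normal per-cell responses
#' these assays produce.
#'
#' @param table data frame with `value` and `condition` columns (e.g. the
#'   measurement table written by [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_measurements <- function(table) {
  ggplot2::ggplot(tibble::as_tibble(table),
                  ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = median, fun.min = function(x) quantile(x, 0.25),
                          fun.max = function(x) quantile(x, 0.75),
                          geom = "pointrange", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "per-cell signal (AFU)") +
    ggplot2::theme_minimal()
}
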