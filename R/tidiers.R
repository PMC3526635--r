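# broom-style tidiers and ggplot2 autoplot methods

#' @export
#' @method tidy structural_profile
tidy.structural_profile <- function(x, truncated = FALSE, ...) {
  tibble::tibble(k = x$k, p = profile_probabilities(x, truncated = truncated))
}

#' @export
#' @method glance structural_profile
glance.structural_profile <- function(x, ...) {
  meta <- profile_meta(x)
  stats <- profile_stats(x)
  tibble::tibble(
    seq_id = meta$seq_id, n = meta$n, model = meta$model,
    reference = meta$reference, Z = meta$Z,
    mean = stats$mean, sd = stats$sd, cv = stats$cv, support = stats$support,
    imag_residual = meta$imag_residual
  )
}

#' @export
#' @method tidy scan_track
tidy.scan_track <- function(x, ...) {
  tibble::tibble(offset = x$offset, expected_distance = x$expected_distance)
}

#' Plot a structural profile
#'
#' Bar chart of the Boltzmann probability `p(k)` against base-pair distance
#' `k`, trimmed at the distance bound.
#'
#' @param object A `structural_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot structural_profile
autoplot.structural_profile <- function(object, ...) {
  meta <- profile_meta(object)
  df <- tidy(object)
  df <- df[seq_len(min(nrow(df), meta$bound + 1L)), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "base-pair distance k from reference",
                  y = "Boltzmann probability p(k)",
                  title = sprintf("%s (%s model)", meta$seq_id, meta$model)) +
    ggplot2::theme_minimal()
}

#' Plot a moving-window scan track
#'
#' Expected base-pair distance to the target structure per window offset;
#' the minimum localizes the target.
#'
#' @param object A `scan_track` from [window_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot scan_track
autoplot.scan_track <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$offset, y = .data$expected_distance)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "window offset (nt)",
                  y = "expected base-pair distance to target") +
    ggplot2::theme_minimal()
}

#' Plot a prefix scan as a heat map
#'
#' @param object A `prefix_scan` from [prefix_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot prefix_scan
autoplot.prefix_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prefix_length, y = .data$k,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "prefix length (nt)", y = "base-pair distance k",
                  fill = "p(k)") +
    ggplot2::theme_minimal()
}
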