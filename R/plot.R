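#' Plot screen outcomes per MAG
#'
#' Stacked bar chart of candidates per bin, coloured by the stage at which
#' each candidate left the screen (or "pass" for full passers).
#'
#' @param object An `mco_screen` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mco_screen <- function(object, ...) {
  r <- object$report
  stage <- dplyr::case_when(
    r$final_call ~ "pass",
    !r$c1_pass ~ "fail: homology",
    !is.na(r$c2_pass) & !r$c2_pass ~ "fail: domain",
    !is.na(r$c3_pass) & !r$c3_pass ~ "fail: Cu sites",
    !is.na(r$c4_pass) & !r$c4_pass ~ "fail: clade",
    .default = "fail: domain"
  )
  df <- tibble(bin_id = r$bin_id,
               outcome = factor(stage, levels = c("pass", "fail: clade",
                                                  "fail: Cu sites",
                                                  "fail: domain",
                                                  "fail: homology")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_id, fill = .data$outcome)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "MAG", y = "candidates", fill = "screen outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.mco_screen
#' @export
plot_screen <- function(object, ...) autoplot.mco_screen(object, ...)

#' Plot the per-column information of a profile
#'
#' Maximum attainable log-odds score per retained anchor column — a quick
#' view of which parts of the reference family are informative.
#'
#' @param object An `mco_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mco_profile <- function(object, ...) {
  df <- tibble(position = object$positions,
               max_score = apply(object$scores, 2, max))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$max_score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "anchor position", y = "max column log-odds (nats)") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
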