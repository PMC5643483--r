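#' Plot a mass spectrum as a stick plot
#'
#' @param peaks A peak list tibble (`mz`, `intensity`).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(peaks) {
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                      y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Da)", y = "intensity")
}

#' Van Krevelen diagram of assigned formulas
#'
#' Plots H/C against O/C elemental ratios of the accepted formulas, the
#' field's standard overview of molecular formula space.
#'
#' @param assigned An assigned peak tibble from [assign_peaks()] (or any
#'   tibble with a `formula` column).
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(assigned) {
  f <- assigned$formula[!is.na(assigned$formula)]
  counts <- parse_formula(f)
  d <- tibble::tibble(hc = counts$H / counts$C, oc = counts$O / counts$C)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$oc, y = .data$hc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "O/C", y = "H/C")
}
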